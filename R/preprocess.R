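# Denoising and standardization of a motion-corrected 4D acquisition.
# Registration is deliberately not part of this package: input volumes are
# assumed motion-corrected upstream.

.asImageData <- function(image) {
  if (is(image, "DynamicPerfusionImage")) image@data
  else if (is.array(image) && length(dim(image)) == 4L) image
  else stop("expected a DynamicPerfusionImage or a 4D array")
}

.withImageData <- function(image, data, unit = NULL) {
  if (is(image, "DynamicPerfusionImage")) {
    image@data <- data
    if (!is.null(unit)) image@unit <- unit
    validObject(image)
    image
  } else data
}

#' Estimate the noise level from unenhanced baseline frames
#'
#' The intensity standard deviation sigma_range is the SD of masked voxel
#' intensities pooled over the pre-contrast baseline frames, after removing
#' each frame's mean over the mask (frame-level offsets such as slow
#' drift must not inflate the noise estimate).
#'
#' @param image DynamicPerfusionImage or 4D array.
#' @param mask 3D logical array (myocardium).
#' @param baselineFrames integer indices of frames acquired before contrast
#'   arrival.
#' @return a \linkS4class{NoiseEstimate}.
#' @export
estimateNoiseSigma <- function(image, mask, baselineFrames) {
  data <- .asImageData(image)
  if (length(baselineFrames) < 1)
    stop("'baselineFrames' must be non-empty")
  if (!is.logical(mask) || !any(mask))
    stop("'mask' must be a non-empty logical array")
  if (any(baselineFrames < 1 | baselineFrames > dim(data)[4]))
    stop("'baselineFrames' out of range")
  # pooled SD with per-frame mean removal and per-frame degrees of
  # freedom, so equal-noise frames reproduce the within-frame SD exactly
  ss <- 0
  df <- 0
  for (f in baselineFrames) {
    v <- data[, , , f][mask]
    ss <- ss + sum((v - mean(v))^2)
    df <- df + length(v) - 1
  }
  sigma <- if (df > 0) sqrt(ss / df) else 0
  if (!is.finite(sigma)) sigma <- 0
  if (sigma == 0)
    warning("sigma_range is 0 (constant baseline); the bilateral filter ",
            "will degrade to a pure spatial filter")
  new("NoiseEstimate", sigmaRange = sigma,
      sourceFrames = as.integer(baselineFrames),
      nVoxels = as.integer(sum(mask)))
}

# 3x3 in-plane median of every 2D slice via a Paeth median-of-9 exchange
# network (19 pmin/pmax pairs), edge-replicated. Much faster than a
# histogram-based filter at this kernel size.
.median3x3 <- function(data) {
  p <- vector("list", 9)
  i <- 0
  for (dx in -1:1) for (dy in -1:1) {
    i <- i + 1
    p[[i]] <- shiftArray(shiftArray(data, 1L, dx), 2L, dy)
  }
  sw <- function(a, b) {
    lo <- pmin(p[[a]], p[[b]])
    p[[b]] <<- pmax(p[[a]], p[[b]])
    p[[a]] <<- lo
  }
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6)
  sw(5, 8); sw(5, 3); sw(7, 5)
  sw(5, 3)
  out <- p[[5]]
  dim(out) <- dim(data)
  out
}

# Per-slice 2D median filter; EBImage::medianFilter (which needs values
# rescaled to [0, 1]) for radius >= 2, the exchange network for radius 1.
.medianFilter2d <- function(data, radius) {
  if (radius == 1) return(.median3x3(data))
  rng <- range(data)
  if (diff(rng) == 0) return(data)
  xm <- (data - rng[1]) / diff(rng)
  med <- EBImage::medianFilter(xm, radius)
  med * diff(rng) + rng[1]
}

# 2D bilateral filter applied to every (z, t) slice at once via in-plane
# shifts; kernel cut at 2 sigma_domain. sigmaRange <= 0 degrades to a pure
# Gaussian spatial filter.
.bilateral2d <- function(data, sigmaDomain, sigmaRange) {
  r <- max(1L, ceiling(2 * sigmaDomain))
  num <- array(0, dim(data))
  den <- array(0, dim(data))
  for (dx in -r:r) for (dy in -r:r) {
    ws <- exp(-(dx^2 + dy^2) / (2 * sigmaDomain^2))
    sh <- shiftArray(shiftArray(data, 1L, dx), 2L, dy)
    if (sigmaRange > 0) {
      w <- ws * exp(-(sh - data)^2 / (2 * sigmaRange^2))
    } else {
      w <- array(ws, dim(data))
    }
    num <- num + w * sh
    den <- den + w
  }
  num / den
}

#' Denoise a 4D acquisition (gated median + bilateral filtering)
#'
#' Per-frame, per-slice 2D processing in two stages: (a) a locally
#' constrained median filter -- a 3x3 median that replaces a voxel only
#' where it deviates from its local median by more than
#' \code{gateK * sigma_range}, so isolated outliers are removed while
#' genuine local signal variation is retained; (b) a 2D bilateral filter
#' with spatial sigma \code{sigmaDomain} (voxels) and range sigma equal to
#' the estimated noise level.
#'
#' @param image DynamicPerfusionImage or 4D array.
#' @param noise a \linkS4class{NoiseEstimate}.
#' @param sigmaDomain spatial standard deviation of the bilateral kernel in
#'   voxel units.
#' @param gateK gate width of the constrained median, in multiples of
#'   sigma_range.
#' @param medianRadius radius of the median kernel (1 = 3x3).
#' @return same type as \code{image}, same shape and unit.
#' @export
denoiseImage <- function(image, noise, sigmaDomain = 2, gateK = 3,
                         medianRadius = 1) {
  data <- .asImageData(image)
  stopifnot(is(noise, "NoiseEstimate"))
  sigma <- noise@sigmaRange
  med <- .medianFilter2d(data, medianRadius)
  gated <- ifelse(abs(data - med) > gateK * sigma, med, data)
  out <- .bilateral2d(gated, sigmaDomain, sigma)
  .withImageData(image, out)
}

#' Convert Hounsfield units to contrast agent concentration
#'
#' Image standardization for intersubject comparability: subtracts the
#' per-voxel baseline mean (pre-contrast frames) and divides by the
#' HU-per-(mg iodine/ml) enhancement factor of the acquisition tube
#' voltage. Negative outputs are permitted (noise); a warning is raised
#' when values below -3 sigma_range / factor occur in more than 1% of the
#' mask voxels, which indicates a baseline or registration problem.
#'
#' @param image DynamicPerfusionImage (unit "HU") or 4D array.
#' @param baselineFrames integer indices of pre-contrast frames.
#' @param huPerMgMl positive conversion factor; around 24 HU per mg
#'   iodine/ml at 80 kV and 30 at 70 kV.
#' @param mask optional 3D logical array used only for the negative-value
#'   check.
#' @param noise optional \linkS4class{NoiseEstimate} for the check.
#' @return same type as \code{image}, unit "mg_iodine_per_ml".
#' @export
huToConcentration <- function(image, baselineFrames, huPerMgMl = 24,
                              mask = NULL, noise = NULL) {
  data <- .asImageData(image)
  if (huPerMgMl <= 0) stop("'huPerMgMl' must be positive")
  if (length(baselineFrames) < 1 ||
      any(baselineFrames < 1 | baselineFrames > dim(data)[4]))
    stop("'baselineFrames' must be non-empty and in range")
  base <- apply(data[, , , baselineFrames, drop = FALSE], 1:3, mean)
  out <- sweep(data, 1:3, base, `-`) / huPerMgMl
  if (!is.null(mask) && !is.null(noise) && noise@sigmaRange > 0) {
    lim <- -3 * noise@sigmaRange / huPerMgMl
    frac <- mean(apply(out, 1:3, min)[mask] < lim)
    if (frac > 0.01)
      warning(sprintf(
        "%.1f%% of mask voxels fall below -3 sigma_range after conversion",
        100 * frac))
  }
  .withImageData(image, out, unit = "mg_iodine_per_ml")
}
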