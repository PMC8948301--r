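# Maximum-upslope (MUS) surrogate of myocardial blood flow:
# Perfusion = max(dS_myo/dt) / max(S_AIF), scaled to ml/min/100 ml.

#' Extract the arterial input function from an aortic ROI
#'
#' @param image \linkS4class{DynamicPerfusionImage} or 4D array.
#' @param roi 3D logical array or an n x 3 matrix of voxel indices inside
#'   the simulated/real aorta.
#' @param frameTimes required when \code{image} is a plain array.
#' @return a \linkS4class{PerfusionCurve} (per-frame mean over the ROI).
#' @export
extractAif <- function(image, roi, frameTimes = NULL) {
  data <- .asImageData(image)
  if (is(image, "DynamicPerfusionImage")) frameTimes <- image@frameTimes
  if (is.null(frameTimes)) stop("'frameTimes' required for array input")
  d <- dim(data)
  if (is.matrix(roi)) {
    if (ncol(roi) != 3) stop("index matrix ROI must have 3 columns")
    if (any(roi < 1) || any(sweep(roi, 2, d[1:3], `>`)))
      stop("ROI indices fall outside the image grid")
    m <- array(FALSE, d[1:3])
    m[roi] <- TRUE
    roi <- m
  }
  if (!identical(dim(roi), d[1:3])) stop("ROI shape does not match the grid")
  if (!any(roi)) stop("'roi' is empty")
  dim(data) <- c(prod(d[1:3]), d[4])
  vals <- colMeans(data[as.vector(roi), , drop = FALSE])
  new("PerfusionCurve", times = as.numeric(frameTimes),
      values = as.numeric(vals), provenance = "aif")
}

# OLS slope coefficients for a window of sample times.
.slopeCoefs <- function(t) {
  tc <- t - mean(t)
  tc / sum(tc^2)
}

#' Maximum upslope of a tissue curve
#'
#' The maximum over all contiguous windows of \code{fitWindow} samples of
#' the least-squares slope, restricted to windows ending at or before the
#' curve's global peak (the first-pass upslope). A curve with its maximum
#' at the first sample (non-increasing) returns 0 with attribute
#' \code{flagged = TRUE}.
#'
#' @param curve \linkS4class{PerfusionCurve} or numeric values.
#' @param fitWindow number of samples per fitted window (>= 2).
#' @param times sample times, required when \code{curve} is numeric.
#' @return the maximum slope in intensity units per second.
#' @export
maxUpslope <- function(curve, fitWindow = 3, times = NULL) {
  if (is(curve, "PerfusionCurve")) {
    v <- curve@values
    times <- curve@times
  } else {
    v <- as.numeric(curve)
    if (is.null(times)) stop("'times' required for numeric input")
  }
  n <- length(v)
  if (fitWindow < 2) stop("'fitWindow' must be >= 2")
  if (n < fitWindow + 1) stop("curve too short for the fit window")
  peak <- which.max(v)
  ends <- seq.int(fitWindow, n)
  ends <- ends[ends <= max(peak, fitWindow)]
  slopes <- vapply(ends, function(e) {
    w <- (e - fitWindow + 1):e
    sum(.slopeCoefs(times[w]) * v[w])
  }, numeric(1))
  best <- max(slopes)
  if (peak == 1L || best <= 0) {
    out <- 0
    attr(out, "flagged") <- TRUE
    return(out)
  }
  best
}

#' Maximum-upslope blood-flow surrogate map
#'
#' Per myocardial voxel: the maximum upslope of the voxel's time curve
#' divided by the peak of the arterial input function, multiplied by
#' \code{scale} (default 6000 = 60 s/min x 100, expressing the 1/s ratio
#' in ml/min/100 ml). Negative fitted slopes are floored at 0 and counted
#' in \code{nFloored}. The ratio makes the map invariant under joint
#' rescaling of tissue and arterial intensities, and the slope under any
#' frame-time offset.
#'
#' @param image \linkS4class{DynamicPerfusionImage} or 4D array; should be
#'   denoised with a radius-3 median filter (see
#'   \code{\link{denoiseForPerfusion}}). Hounsfield input is refused
#'   unless \code{allowHU = TRUE}.
#' @param mask 3D logical array (myocardium).
#' @param aif \linkS4class{PerfusionCurve} from \code{\link{extractAif}}.
#' @param scale unit conversion constant.
#' @param fitWindow samples per slope window.
#' @param frameTimes required for plain-array input.
#' @param allowHU logical, permit unit "HU".
#' @return an \linkS4class{MbfMap}.
#' @export
mbfMap <- function(image, mask, aif, scale = 6000, fitWindow = 3,
                   frameTimes = NULL, allowHU = FALSE) {
  if (is(image, "DynamicPerfusionImage")) {
    if (image@unit == "HU" && !allowHU)
      stop("image is in Hounsfield units; convert with huToConcentration()",
           " or pass allowHU = TRUE")
    frameTimes <- image@frameTimes
  }
  data <- .asImageData(image)
  if (is.null(frameTimes)) stop("'frameTimes' required for array input")
  stopifnot(is(aif, "PerfusionCurve"))
  aifMax <- max(aif@values)
  if (aifMax <= 0) stop("zero AIF maximum; cannot normalize upslopes")
  d <- dim(data)
  if (!identical(dim(mask), d[1:3])) stop("'mask' shape mismatch")
  if (!any(mask)) stop("'mask' is empty")
  nT <- d[4]
  if (nT < fitWindow + 1) stop("too few frames for the fit window")

  dim(data) <- c(prod(d[1:3]), nT)
  v <- data[as.vector(mask), , drop = FALSE]
  peak <- max.col(v, ties.method = "first")
  ends <- seq.int(fitWindow, nT)
  slopeMat <- matrix(-Inf, nrow(v), length(ends))
  for (j in seq_along(ends)) {
    w <- (ends[j] - fitWindow + 1):ends[j]
    slopeMat[, j] <- v[, w, drop = FALSE] %*% .slopeCoefs(frameTimes[w])
  }
  # only windows ending at or before the per-voxel peak (first pass)
  allowed <- outer(pmax(peak, fitWindow), ends, `>=`)
  slopeMat[!allowed] <- -Inf
  sMax <- apply(slopeMat, 1, max)
  sMax[peak == 1L] <- 0
  nFloored <- sum(sMax < 0)
  sMax <- pmax(sMax, 0)

  mbf <- array(NA_real_, d[1:3])
  mbf[mask] <- sMax / aifMax * scale
  new("MbfMap", mbf = mbf, validMask = mask,
      nFloored = as.integer(nFloored))
}

#' Median denoising for perfusion mapping
#'
#' The upslope map uses stronger median filtering than fractal analysis: a
#' per-slice median with radius 3 (7 x 7 kernel), without the outlier gate.
#'
#' @param image \linkS4class{DynamicPerfusionImage} or 4D array.
#' @param radius median kernel radius.
#' @return same type as \code{image}.
#' @export
denoiseForPerfusion <- function(image, radius = 3) {
  data <- .asImageData(image)
  .withImageData(image, .medianFilter2d(data, radius))
}
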