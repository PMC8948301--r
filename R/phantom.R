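#' Gamma-variate arterial input curve
#'
#' Standard gamma-variate model of a first-pass contrast bolus, sampled on
#' the acquisition frame grid. The curve is zero up to \code{onset} and
#' peaks with value \code{amplitude} at \code{onset + alpha * beta}.
#'
#' @param times numeric, sample times in seconds, strictly increasing.
#' @param amplitude peak intensity (HU or mg iodine/ml).
#' @param onset bolus arrival time in seconds; must lie within the sampled
#'   time range.
#' @param alpha,beta positive gamma-variate shape and timescale (s).
#' @param provenance free-text label stored on the curve.
#' @return a \linkS4class{PerfusionCurve}.
#' @examples
#' aif <- makeAif(seq(0, 26, by = 2), amplitude = 300, onset = 6,
#'                alpha = 2.5, beta = 1.5)
#' max(curveValues(aif))
#' @export
makeAif <- function(times, amplitude, onset, alpha = 2.5, beta = 1.5,
                    provenance = "aif") {
  if (length(times) < 2 || any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  if (alpha <= 0 || beta <= 0) stop("'alpha' and 'beta' must be positive")
  if (onset < min(times) || onset > max(times))
    stop("'onset' must lie within the sampled time range")
  tau <- times - onset
  tPeak <- alpha * beta
  v <- ifelse(tau > 0,
              amplitude * (tau / tPeak)^alpha * exp(alpha * (1 - tau / tPeak)),
              0)
  new("PerfusionCurve", times = as.numeric(times), values = as.numeric(v),
      provenance = provenance)
}

#' Fractional Brownian texture field (spectral synthesis)
#'
#' Synthesizes a 3D fractional Brownian field by shaping the Fourier
#' transform of Gaussian white noise with the radial amplitude filter
#' |f|^-(H + d/2), d = 3, then normalizing to zero mean and unit variance.
#' The Hurst exponent H in (0, 1) controls roughness: low H is rough, high
#' H is smooth. Used as ground-truth perfusion texture whose theoretical
#' fractal dimension is known, so the blanket estimator can be validated
#' against a tunable roughness scale.
#'
#' @param shape integer length-3 grid shape.
#' @param hurst Hurst exponent H, 0 < H < 1.
#' @param seed optional integer; if given, the RNG is seeded locally so the
#'   field is a pure function of (shape, hurst, seed). If NULL the ambient
#'   RNG stream is used.
#' @param oversample integer synthesis oversampling factor. Plain spectral
#'   synthesis flattens the increment scaling near the grid Nyquist
#'   frequency; synthesizing on an oversampled grid and decimating keeps
#'   the small-lag structure function much closer to lag^(2H).
#' @return 3D numeric array with mean 0 and variance 1.
#' @export
makeFbmField <- function(shape, hurst, seed = NULL, oversample = 2) {
  if (length(shape) != 3L || any(shape < 2))
    stop("'shape' must be three dimensions of at least 2")
  if (hurst <= 0 || hurst >= 1) stop("'hurst' must lie strictly in (0, 1)")
  if (oversample < 1 || oversample != round(oversample))
    stop("'oversample' must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  s2 <- shape * oversample
  noise <- array(stats::rnorm(prod(s2)), s2)
  fr <- lapply(s2, function(n) {
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
    k / n
  })
  g <- coordGrid3d(s2)
  f <- sqrt(fr[[1]][g$x]^2 + fr[[2]][g$y]^2 + fr[[3]][g$z]^2)
  filt <- array(0, s2)
  nz <- f > 0
  filt[nz] <- f[nz]^(-(hurst + 1.5))
  spec <- stats::fft(noise) * filt
  out <- Re(stats::fft(spec, inverse = TRUE)) / prod(s2)
  out <- out[seq(1, s2[1], oversample), seq(1, s2[2], oversample),
             seq(1, s2[3], oversample)]
  out <- out - mean(out)
  out / stats::sd(out)
}

#' Phantom specification
#'
#' Collects all parameters of the synthetic 4D perfusion phantom. Defaults
#' describe a desk-scale 30-s dynamic stress acquisition: 64 x 64 in-plane
#' at 2 mm, 16 slices, 14 frames at 2-s intervals, a myocardial annulus
#' with apical cap, a simulated aorta carrying the arterial input, and
#' spatially textured perfusion whose roughness is set by a Hurst
#' exponent. Perfusion complexity is carried by two mechanisms: a static
#' multiplicative fractional-Brownian texture and a spatio-temporal
#' delivery fluctuation; lesions damp both, in addition to reducing
#' enhancement amplitude and delaying wash-in.
#'
#' @param shape grid (x, y, z, t); minimum c(32, 32, 8, 12).
#' @param spacing voxel spacing in mm (3 values).
#' @param frameInterval frame spacing in seconds.
#' @param center in-plane LV axis (x, y) in voxels; default grid center.
#' @param innerRadius,outerRadius myocardial annulus radii in voxels.
#' @param hurst roughness exponent H of the perfusion texture, 0 < H < 1.
#' @param regime lesion regime: \code{"none"}, \code{"micro"} (patchy
#'   subendocardial), or \code{"macro"} (territorial transmural).
#' @param territoryAngle macro lesion: angular span in degrees.
#' @param lesionAngle macro lesion: start angle (degrees from the RV
#'   insertion origin).
#' @param patchDensity micro lesion: fraction of the subendocardial shell
#'   covered by lesion patches.
#' @param patchScale micro lesion: correlation length (Gaussian sigma,
#'   voxels) of the patch field; sets the typical patch diameter.
#' @param depthFraction micro lesion: wall-depth fraction (from the
#'   endocardial border) in which patches may occur.
#' @param microAmplitude,macroAmplitude multiplicative enhancement
#'   reduction inside micro/macro lesions.
#' @param microDiffuseAmplitude,microDiffuseFluct mild diffuse reduction
#'   of enhancement and fluctuation across the whole subendocardial shell
#'   in the micro regime (diffuse small-vessel disease with patchy
#'   accentuation); the labeled lesions remain the patches.
#' @param microSmooth,macroSmooth Gaussian sigma (voxels) applied to the
#'   texture field inside micro/macro lesions (reduced perfusion
#'   complexity).
#' @param fluctAmp relative amplitude of the spatio-temporal perfusion
#'   fluctuation (vasomotion / beat-to-beat delivery variation),
#'   multiplicative on the local enhancement.
#' @param fluctSmooth in-plane correlation (Gaussian sigma, voxels) of the
#'   fluctuation field.
#' @param microFluct,macroFluct damping of the fluctuation inside
#'   micro/macro lesions: exhausted vasodilative reserve leaves little
#'   dynamic complexity, which is the signal the fractal analysis detects.
#' @param baseline tissue baseline intensity (HU).
#' @param enhancement mean peak myocardial enhancement above baseline (HU).
#' @param subjectSd log-normal SD of the per-subject global enhancement
#'   scale (inter-individual hemodynamic variability).
#' @param textureAmplitude multiplicative log-texture strength c in
#'   exp(c * fBm).
#' @param aifAmplitude,aifOnset,aifAlpha,aifBeta arterial input curve
#'   parameters (see \code{\link{makeAif}}).
#' @param tissueDelay mean arterial-to-tissue bolus delay in seconds.
#' @param delaySd spatial SD (s) of the per-voxel bolus delay, textured by
#'   the same field as the amplitude: perfusion heterogeneity disperses
#'   transit times as well as blood volume, so roughness lives on the
#'   temporal axis too.
#' @param microDelay,macroDelay additional mean delay (s) inside
#'   micro/macro lesions (delayed wash-in of hypoperfused tissue).
#' @param tissueBeta tissue response timescale (bolus dispersion), s.
#' @param noiseSigma Gaussian noise SD added per frame (HU).
#' @param seed integer; the single source of all phantom randomness.
#' @return a validated list of class \code{"PhantomSpec"}.
#' @export
phantomSpec <- function(shape = c(64, 64, 16, 14),
                        spacing = c(2, 2, 2),
                        frameInterval = 2,
                        center = NULL,
                        innerRadius = 10, outerRadius = 16,
                        hurst = 0.5,
                        regime = c("none", "micro", "macro"),
                        territoryAngle = 90, lesionAngle = 0,
                        patchDensity = 0.5, depthFraction = 0.5,
                        patchScale = 2.5,
                        microAmplitude = 0.8, macroAmplitude = 0.45,
                        microDiffuseAmplitude = 0.9,
                        microDiffuseFluct = 0.7,
                        microSmooth = 2, macroSmooth = 4,
                        fluctAmp = 0.45, fluctSmooth = 1.5,
                        microFluct = 0.4, macroFluct = 0.08,
                        baseline = 50, enhancement = 60,
                        subjectSd = 0.18, textureAmplitude = 0.2,
                        aifAmplitude = 300, aifOnset = 6,
                        aifAlpha = 2.5, aifBeta = 1.5,
                        tissueDelay = 4, delaySd = 1.5,
                        microDelay = 1, macroDelay = 2,
                        tissueBeta = 5.5,
                        noiseSigma = 1, seed = 1) {
  regime <- match.arg(regime)
  if (length(shape) != 4L || any(shape < c(32, 32, 8, 12)))
    stop("'shape' must be (x, y, z, t) with minimum (32, 32, 8, 12)")
  if (innerRadius >= outerRadius)
    stop("'innerRadius' must be smaller than 'outerRadius'")
  if (hurst <= 0 || hurst >= 1) stop("'hurst' must lie strictly in (0, 1)")
  if (is.null(center)) center <- (shape[1:2] + 1) / 2
  spec <- list(shape = as.integer(shape), spacing = spacing,
               frameInterval = frameInterval, center = center,
               innerRadius = innerRadius, outerRadius = outerRadius,
               hurst = hurst, regime = regime,
               territoryAngle = territoryAngle, lesionAngle = lesionAngle,
               patchDensity = patchDensity, depthFraction = depthFraction,
               patchScale = patchScale,
               microAmplitude = microAmplitude,
               macroAmplitude = macroAmplitude,
               microDiffuseAmplitude = microDiffuseAmplitude,
               microDiffuseFluct = microDiffuseFluct,
               microSmooth = microSmooth, macroSmooth = macroSmooth,
               fluctAmp = fluctAmp, fluctSmooth = fluctSmooth,
               microFluct = microFluct, macroFluct = macroFluct,
               baseline = baseline, enhancement = enhancement,
               subjectSd = subjectSd, textureAmplitude = textureAmplitude,
               aifAmplitude = aifAmplitude, aifOnset = aifOnset,
               aifAlpha = aifAlpha, aifBeta = aifBeta,
               tissueDelay = tissueDelay, delaySd = delaySd,
               microDelay = microDelay, macroDelay = macroDelay,
               tissueBeta = tissueBeta,
               noiseSigma = noiseSigma, seed = as.integer(seed))
  class(spec) <- "PhantomSpec"
  spec
}

# Geometry of the phantom myocardium: annulus slices plus an apical cap
# disc on the last slice. Returns mask plus polar coordinates.
.phantomGeometry <- function(spec) {
  d <- spec$shape[1:3]
  g <- coordGrid3d(d)
  dx <- g$x - spec$center[1]
  dy <- g$y - spec$center[2]
  rad <- sqrt(dx^2 + dy^2)
  theta <- normDeg(atan2(dy, dx) * 180 / pi)
  nz <- d[3]
  capZ <- nz
  ringZ <- seq_len(nz - 1L)
  annulus <- rad >= spec$innerRadius & rad <= spec$outerRadius &
    g$z < capZ
  cap <- rad <= spec$outerRadius & g$z == capZ
  list(mask = annulus | cap, annulus = annulus, cap = cap,
       rad = rad, theta = theta, z = g$z, ringZ = ringZ, capZ = capZ)
}

# Default AHA model matching .phantomGeometry: ring slices split into
# thirds (basal from slice 1), the last slice is the apical cap.
.phantomSegmentModel <- function(spec) {
  nz <- spec$shape[3]
  ring <- seq_len(nz - 1L)
  thirds <- split(ring, cut(seq_along(ring), 3, labels = FALSE))
  new("SegmentModel", center = spec$center, rvAngleDeg = 0,
      basalZ = as.integer(thirds[[1]]), midZ = as.integer(thirds[[2]]),
      apicalZ = as.integer(thirds[[3]]), capZ = nz)
}

#' Synthesize a 4D perfusion phantom with ground truth
#'
#' Builds a synthetic dynamic contrast-enhanced acquisition: every
#' myocardial voxel follows baseline + amplitude * tissue response, where
#' the response is a delayed, dispersed copy of the arterial input curve
#' and the amplitude is modulated multiplicatively by exp(c * fBm(H)). A
#' cylinder of "aorta" voxels carries the undelayed arterial input. Lesions
#' reduce both enhancement amplitude and texture roughness (perfusion
#' complexity): the micro regime in spatially patchy subendocardial
#' clusters, the macro regime across one full transmural angular territory.
#' Gaussian frame noise is added last. All randomness flows from
#' \code{spec$seed}; identical specs give bit-identical bundles.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return a \linkS4class{PhantomBundle}.
#' @export
synthesizePhantom <- function(spec) {
  if (!inherits(spec, "PhantomSpec"))
    stop("'spec' must be created by phantomSpec()")
  set.seed(spec$seed)
  d <- spec$shape
  geo <- .phantomGeometry(spec)
  mask <- geo$mask
  times <- (seq_len(d[4]) - 1) * spec$frameInterval

  aif <- makeAif(times, spec$aifAmplitude, spec$aifOnset,
                 spec$aifAlpha, spec$aifBeta)

  # shared random fields are drawn first so that phantoms of different
  # regimes but equal seed share texture, fluctuation and subject-level
  # scale and stay directly comparable
  fbm <- makeFbmField(d[1:3], spec$hurst)
  subjScale <- exp(stats::rnorm(1, 0, spec$subjectSd))
  # spatio-temporal perfusion fluctuation: spatially correlated within
  # each frame, independent across frames, unit variance
  eta <- array(stats::rnorm(prod(d)), d)
  if (spec$fluctSmooth > 0) {
    r <- max(1L, ceiling(3 * spec$fluctSmooth))
    k <- exp(-((-r:r)^2) / (2 * spec$fluctSmooth^2))
    k <- k / sum(k)
    eta <- convolveAxis(convolveAxis(eta, 1L, k), 2L, k)
    eta <- eta / stats::sd(eta)
  }

  # lesion label volume: 0 normal, 1 micro, 2 macro (on mask voxels)
  truth <- array(NA_integer_, d[1:3])
  truth[mask] <- 0L
  lesion <- array(FALSE, d[1:3])
  subendo <- array(FALSE, d[1:3])
  if (spec$regime == "macro") {
    a0 <- normDeg(spec$lesionAngle)
    span <- spec$territoryAngle
    ang <- normDeg(geo$theta - a0)
    lesion <- mask & ang < span
    if (!any(lesion))
      stop("macro lesion territory is empty after rasterization; ",
           "check 'territoryAngle'/'lesionAngle'")
    truth[lesion] <- 2L
  } else if (spec$regime == "micro") {
    wall <- (geo$rad - spec$innerRadius) /
      (spec$outerRadius - spec$innerRadius)
    subendo <- geo$annulus & wall <= spec$depthFraction
    subendo[is.na(subendo)] <- FALSE
    patchField <- gaussianBlur3d(array(stats::rnorm(prod(d[1:3])), d[1:3]),
                                 spec$patchScale)
    thr <- stats::quantile(patchField[subendo], 1 - spec$patchDensity)
    lesion <- subendo & patchField > thr
    if (!any(lesion))
      stop("micro lesion patches are empty after rasterization; ",
           "check 'patchDensity'/'depthFraction'")
    truth[lesion] <- 1L
  }

  # perfusion texture; smoothed (complexity reduced) inside lesions
  tex <- fbm
  if (spec$regime == "micro") {
    sm <- gaussianBlur3d(fbm, spec$microSmooth)
    tex[lesion] <- sm[lesion]
  } else if (spec$regime == "macro") {
    sm <- gaussianBlur3d(fbm, spec$macroSmooth)
    tex[lesion] <- sm[lesion]
  }

  amp <- array(0, d[1:3])
  amp[mask] <- spec$enhancement * subjScale *
    exp(spec$textureAmplitude * tex[mask])
  if (spec$regime == "micro") {
    amp[subendo & !lesion] <- amp[subendo & !lesion] *
      spec$microDiffuseAmplitude
    amp[lesion] <- amp[lesion] * spec$microAmplitude
  } else if (spec$regime == "macro") {
    amp[lesion] <- amp[lesion] * spec$macroAmplitude
  }

  # aorta cylinder, placed outside the annulus
  aortaCenter <- c(spec$center[1] - spec$outerRadius - 8,
                   spec$center[2] - spec$outerRadius - 8)
  if (any(aortaCenter < 5))
    aortaCenter <- pmax(aortaCenter, 5)
  g <- coordGrid3d(d[1:3])
  aortaDist <- sqrt((g$x - aortaCenter[1])^2 + (g$y - aortaCenter[2])^2)
  aorta <- aortaDist <= 4 & !mask
  # AIF ROI kept central in the vessel, clear of boundary voxels, as an
  # operator would place it
  aifRoi <- aortaDist <= 2.5 & !mask

  # per-voxel bolus delay: textured like the amplitude (transit-time
  # heterogeneity), with an additional mean delay inside lesions
  delay <- spec$tissueDelay + spec$delaySd * tex
  if (spec$regime == "micro") delay[lesion] <- delay[lesion] + spec$microDelay
  if (spec$regime == "macro") delay[lesion] <- delay[lesion] + spec$macroDelay

  # fluctuation damping: full dynamic complexity in healthy tissue,
  # strongly damped where vasodilative reserve is exhausted
  damp <- array(1, d[1:3])
  if (spec$regime == "micro") {
    damp[subendo & !lesion] <- spec$microDiffuseFluct
    damp[lesion] <- spec$microFluct
  }
  if (spec$regime == "macro") damp[lesion] <- spec$macroFluct

  # assemble frames: dispersed gamma-variate tissue response (unit peak)
  # evaluated per voxel at its own arrival time, modulated by the
  # perfusion fluctuation
  data <- array(spec$baseline, d)
  tPeak <- spec$aifAlpha * spec$tissueBeta
  ampM <- amp[mask]
  delayM <- delay[mask]
  dampM <- damp[mask]
  maskV <- as.vector(mask)
  for (f in seq_len(d[4])) {
    frame <- array(spec$baseline, d[1:3])
    tau <- times[f] - spec$aifOnset - delayM
    g <- ifelse(tau > 0,
                (tau / tPeak)^spec$aifAlpha *
                  exp(spec$aifAlpha * (1 - tau / tPeak)),
                0)
    etaF <- eta[, , , f][maskV]
    frame[mask] <- spec$baseline +
      ampM * g * (1 + spec$fluctAmp * dampM * etaF)
    frame[aorta] <- spec$baseline + aif@values[f]
    data[, , , f] <- frame
  }
  if (spec$noiseSigma > 0)
    data <- data + array(stats::rnorm(length(data), 0, spec$noiseSigma),
                         dim = d)

  img <- new("DynamicPerfusionImage", data = data, spacing = spec$spacing,
             frameTimes = times, unit = "HU")
  model <- .phantomSegmentModel(spec)
  labels <- assignSegments(mask, model)
  segTruth <- .segmentTruth(labels, truth)
  new("PhantomBundle", image = img, mask = mask, aifRoi = aifRoi,
      truth = truth, segmentTruth = segTruth, model = model,
      spec = unclass(spec))
}

# Per-segment truth: a segment carries a lesion class when at least
# `minFraction` of its voxels are lesion voxels of that class.
.segmentTruth <- function(labels, truth, minFraction = 0.1) {
  segs <- sort(unique(labels[!is.na(labels)]))
  cls <- vapply(segs, function(s) {
    v <- truth[!is.na(labels) & labels == s]
    if (mean(v == 2L) >= minFraction) "macro"
    else if (mean(v == 1L) >= minFraction) "micro"
    else "normal"
  }, character(1))
  data.frame(segment = segs, truthClass = cls, stringsAsFactors = FALSE)
}

#' Write a phantom bundle to disk
#'
#' Writes the 4D image, the myocardium mask, the AIF ROI and the truth
#' labels as NIfTI-1 volumes plus a JSON sidecar holding the full phantom
#' specification.
#'
#' @param bundle a \linkS4class{PhantomBundle}.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths written.
#' @export
writePhantom <- function(bundle, dir) {
  stopifnot(is(bundle, "PhantomBundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(image = file.path(dir, "phantom_4d.nii.gz"),
             mask = file.path(dir, "phantom_mask.nii.gz"),
             aifRoi = file.path(dir, "phantom_aif_roi.nii.gz"),
             truth = file.path(dir, "phantom_truth.nii.gz"),
             spec = file.path(dir, "phantom_spec.json"))
  writeDynamicVolume(bundle@image, paths["image"])
  .writeVolume3d(bundle@mask * 1L, bundle@spec$spacing, paths["mask"])
  .writeVolume3d(bundle@aifRoi * 1L, bundle@spec$spacing, paths["aifRoi"])
  truth <- bundle@truth
  truth[is.na(truth)] <- -1L
  .writeVolume3d(truth, bundle@spec$spacing, paths["truth"])
  jsonlite::write_json(bundle@spec, paths["spec"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
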