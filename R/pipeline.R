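# End-to-end analysis drivers: preprocess -> fractal -> perfusion ->
# segments -> classification, for in-memory objects, phantom bundles and
# file-based runs.

#' Analyze one 4D study in memory
#'
#' Runs the full quantitative chain on a motion-corrected acquisition:
#' noise estimation on baseline frames, gated-median + bilateral
#' denoising, HU-to-concentration standardization, local 4D fractal
#' analysis, maximum-upslope perfusion mapping (with its own radius-3
#' median filtering), AHA segment assignment and per-segment aggregation.
#'
#' @param image \linkS4class{DynamicPerfusionImage} in HU.
#' @param mask 3D logical myocardium mask.
#' @param aifRoi 3D logical aortic ROI.
#' @param model \linkS4class{SegmentModel}.
#' @param baselineFrames pre-contrast frame indices.
#' @param huPerMgMl HU-to-concentration factor.
#' @param epsMax,windowRadius,levels,neighborhood fractal parameters, see
#'   \code{\link{fdMap}}.
#' @param fitWindow,scale,perfusionMedianRadius perfusion parameters, see
#'   \code{\link{mbfMap}}.
#' @param sigmaDomain,gateK denoising parameters, see
#'   \code{\link{denoiseImage}}.
#' @param roiPolicy,minVoxels segment aggregation, see
#'   \code{\link{segmentSummary}}.
#' @param truth optional per-segment truth table (phantoms).
#' @param patient patient id recorded in the table.
#' @return list with \code{fd} (\linkS4class{FdMap}), \code{mbf}
#'   (\linkS4class{MbfMap}), \code{segments} (data.frame), \code{labels},
#'   \code{noise}, \code{aif}.
#' @export
analyzeStudy <- function(image, mask, aifRoi, model,
                         baselineFrames = c(1, 2), huPerMgMl = 24,
                         epsMax = 4, windowRadius = epsMax + 1,
                         levels = 256, neighborhood = "axis",
                         fitWindow = 3, scale = 6000,
                         perfusionMedianRadius = 3,
                         sigmaDomain = 2, gateK = 3,
                         roiPolicy = "all", minVoxels = 10,
                         truth = NULL, patient = NA_character_) {
  stopifnot(is(image, "DynamicPerfusionImage"))
  noise <- estimateNoiseSigma(image, mask, baselineFrames)
  den <- denoiseImage(image, noise, sigmaDomain = sigmaDomain,
                      gateK = gateK)
  conc <- huToConcentration(den, baselineFrames, huPerMgMl,
                            mask = mask, noise = noise)
  fd <- fdMap(conc, mask, epsMax = epsMax, windowRadius = windowRadius,
              levels = levels, neighborhood = neighborhood)
  perf <- denoiseForPerfusion(conc, radius = perfusionMedianRadius)
  # AIF from the standard-preprocessed image: the strong in-plane median
  # would erode the small aortic ROI and depress the AIF peak
  aif <- extractAif(conc, aifRoi)
  mbf <- mbfMap(perf, mask, aif, scale = scale, fitWindow = fitWindow)
  labels <- assignSegments(mask, model)
  segments <- segmentSummary(fd, mbf, labels, roiPolicy = roiPolicy,
                             minVoxels = minVoxels, truth = truth,
                             patient = patient)
  list(fd = fd, mbf = mbf, segments = segments, labels = labels,
       noise = noise, aif = aif)
}

#' Analyze a synthetic phantom bundle
#'
#' Convenience wrapper of \code{\link{analyzeStudy}} that pulls image,
#' mask, AIF ROI, segment model and ground truth out of a
#' \linkS4class{PhantomBundle}.
#'
#' @param bundle a \linkS4class{PhantomBundle}.
#' @param patient patient id for the segment table (default
#'   "seed<seed>").
#' @param ... further arguments to \code{\link{analyzeStudy}}.
#' @return as \code{\link{analyzeStudy}}.
#' @export
analyzePhantom <- function(bundle, patient = NULL, ...) {
  stopifnot(is(bundle, "PhantomBundle"))
  if (is.null(patient)) patient <- paste0("seed", bundle@spec$seed)
  analyzeStudy(bundle@image, bundle@mask, bundle@aifRoi, bundle@model,
               truth = bundle@segmentTruth, patient = patient, ...)
}

#' Run phantom cohorts through the full pipeline
#'
#' Generates \code{nPerGroup} phantoms per lesion regime (normal, micro,
#' macro) with consecutive seeds starting at \code{seedBase}, analyzes
#' each, and binds the per-segment tables. One phantom plays the role of
#' one patient.
#'
#' @param nPerGroup phantoms per regime.
#' @param seedBase first seed; phantom i of regime j uses seed
#'   \code{seedBase + (j - 1) * nPerGroup + (i - 1)}.
#' @param specArgs named list of overrides passed to
#'   \code{\link{phantomSpec}}.
#' @param ... further arguments to \code{\link{analyzeStudy}}.
#' @return data.frame of per-segment rows with columns as
#'   \code{\link{segmentSummary}} plus \code{regime}.
#' @export
cohortExperiment <- function(nPerGroup = 10, seedBase = 1,
                             specArgs = list(), ...) {
  regimes <- c("none", "micro", "macro")
  out <- list()
  for (j in seq_along(regimes)) {
    for (i in seq_len(nPerGroup)) {
      seed <- seedBase + (j - 1) * nPerGroup + (i - 1)
      spec <- do.call(phantomSpec,
                      c(list(regime = regimes[j], seed = seed), specArgs))
      bundle <- synthesizePhantom(spec)
      res <- suppressWarnings(
        analyzePhantom(bundle,
                       patient = sprintf("%s_%02d", regimes[j], i), ...))
      tab <- res$segments
      # ground-truth patient class: the "none" regime is normal perfusion
      tab$regime <- if (regimes[j] == "none") "normal" else regimes[j]
      out[[length(out) + 1L]] <- tab
    }
  }
  do.call(rbind, out)
}

#' Patient summary statistic for cutoff derivation and classification
#'
#' Reduces a per-segment table to one value per patient: the mean of the
#' two lowest unflagged segment values ("the most abnormal region"). A
#' focal macrovascular defect is carried by its worst segments, diffuse
#' microvascular disease lowers many segments, and in normal myocardium
#' the statistic stays near the patient mean; averaging the two lowest
#' segments keeps it robust against a single noisy segment estimate.
#'
#' @param segTable data.frame with patient and value columns.
#' @param marker \code{"fd"} or \code{"mbf"}.
#' @return named numeric vector of patient statistics.
#' @export
patientLowSegmentStat <- function(segTable, marker = c("fd", "mbf")) {
  marker <- match.arg(marker)
  col <- if (marker == "fd") "meanFd" else "meanMbf"
  tab <- segTable[!segTable$flagged & !is.na(segTable[[col]]), ]
  vapply(split(tab[[col]], tab$patient), function(v) {
    v <- sort(v)
    mean(v[seq_len(min(2, length(v)))])
  }, numeric(1))
}

#' Phantom cohort validation study
#'
#' The end-to-end parameter-recovery experiment: a training cohort
#' (\code{nPerGroup} phantoms per regime) is analyzed, FD and MBF cutoffs
#' are derived from the training patients' low-segment statistics, and a
#' held-out cohort with disjoint seeds is classified with those cutoffs.
#' Reports balanced accuracy and Hand-Till multi-class AUC for both
#' markers.
#'
#' @param nPerGroup phantoms per regime and cohort.
#' @param seedTrain,seedTest seed bases of the two cohorts (kept disjoint
#'   by the caller).
#' @param specArgs phantom overrides, see \code{\link{cohortExperiment}}.
#' @param ... further arguments to \code{\link{analyzeStudy}}.
#' @return list with \code{cutoffs} (per marker), \code{balancedAccuracy},
#'   \code{auc}, \code{train}, \code{test} (patient-level data.frames) and
#'   the raw segment tables.
#' @export
runValidationStudy <- function(nPerGroup = 10, seedTrain = 1,
                               seedTest = 1001, specArgs = list(), ...) {
  train <- cohortExperiment(nPerGroup, seedTrain, specArgs, ...)
  test <- cohortExperiment(nPerGroup, seedTest, specArgs, ...)
  patientFrame <- function(segTable) {
    fd <- patientLowSegmentStat(segTable, "fd")
    mbf <- patientLowSegmentStat(segTable, "mbf")
    regime <- vapply(split(segTable$regime, segTable$patient),
                     function(r) r[1], character(1))
    data.frame(patient = names(fd), fd = fd, mbf = mbf[names(fd)],
               regime = regime[names(fd)], stringsAsFactors = FALSE)
  }
  ptr <- patientFrame(train)
  pte <- patientFrame(test)
  cutFd <- optimalCutoffs(ptr$fd, ptr$regime)
  cutMbf <- optimalCutoffs(ptr$mbf, ptr$regime)
  predFd <- .classify(pte$fd, cutFd$cutoffIschemia, cutFd$cutoffMacro)
  predMbf <- .classify(pte$mbf, cutMbf$cutoffIschemia, cutMbf$cutoffMacro)
  list(cutoffs = list(fd = cutFd, mbf = cutMbf),
       balancedAccuracy = c(fd = balancedAccuracy(predFd, pte$regime),
                            mbf = balancedAccuracy(predMbf, pte$regime)),
       auc = c(fd = multiclassAuc(pte$fd, pte$regime),
               mbf = multiclassAuc(pte$mbf, pte$regime)),
       train = ptr, test = pte,
       trainSegments = train, testSegments = test,
       predicted = data.frame(patient = pte$patient, regime = pte$regime,
                              fd = as.character(predFd),
                              mbf = as.character(predMbf),
                              stringsAsFactors = FALSE))
}

#' Patient-level classification of a segment table
#'
#' Classifies every unflagged segment with the given cutoffs, then
#' aggregates to one class per patient (macro when at least one segment is
#' macro, else micro when at least one is micro, else normal).
#'
#' @param segTable data.frame from \code{\link{segmentSummary}} /
#'   \code{\link{cohortExperiment}} with a \code{patient} column.
#' @param cutoffs a \linkS4class{CutoffSet}.
#' @param marker \code{"fd"} or \code{"mbf"}.
#' @return named character vector of patient classes.
#' @export
classifyPatients <- function(segTable, cutoffs, marker = c("fd", "mbf")) {
  marker <- match.arg(marker)
  col <- if (marker == "fd") "meanFd" else "meanMbf"
  tab <- segTable[!segTable$flagged & !is.na(segTable[[col]]), ]
  cls <- if (marker == "fd") classifyFd(tab[[col]], cutoffs)
         else classifyMbf(tab[[col]], cutoffs)
  idx <- split(seq_len(nrow(tab)), tab$patient)
  vapply(idx, function(i) {
    as.character(aggregateToVesselPatient(tab$segment[i],
                                          cls[i])$patient)
  }, character(1))
}

#' Run the file-based analysis pipeline
#'
#' Reads the configured volumes, executes the full chain, classifies the
#' segments with the configured cutoffs and writes FD/MBF maps (NIfTI),
#' the segment table (CSV), a diagnostic report (JSON) and a provenance
#' record (config hash, package version, seed) to the output directory.
#'
#' @param config YAML path or named list, see \code{\link{readRunConfig}}.
#' @return invisibly, the \code{\link{analyzeStudy}} result plus
#'   \code{outputFiles}.
#' @export
runPipeline <- function(config) {
  cfg <- readRunConfig(config)
  for (key in c("image", "mask", "output"))
    if (is.null(cfg[[key]])) stop("config key '", key, "' is required")
  if (!file.exists(cfg$image)) stop("image file not found: ", cfg$image)
  if (!file.exists(cfg$mask)) stop("mask file not found: ", cfg$mask)
  set.seed(cfg$seed)
  quiet <- cfg$verbosity < 1
  image <- readDynamicVolume(cfg$image, quiet = quiet)
  mask <- .readMask(cfg$mask)
  aifRoi <- if (!is.null(cfg$aifRoi)) .readMask(cfg$aifRoi) else
    stop("config key 'aifRoi' is required")
  lm <- cfg$landmarks
  if (is.null(lm$center) || is.null(lm$basalZ))
    stop("config block 'landmarks' must define center and slice thirds")
  model <- segmentModel(lm$center, lm$rvAngleDeg, lm$basalZ, lm$midZ,
                        lm$apicalZ, lm$capZ)
  res <- analyzeStudy(image, mask, aifRoi, model,
                      baselineFrames = cfg$preprocess$baselineFrames,
                      huPerMgMl = cfg$preprocess$huPerMgMl,
                      sigmaDomain = cfg$preprocess$sigmaDomain,
                      gateK = cfg$preprocess$medianGateK,
                      epsMax = cfg$fractal$epsMax,
                      windowRadius = cfg$fractal$windowRadius,
                      levels = cfg$fractal$levels,
                      neighborhood = cfg$fractal$neighborhood,
                      fitWindow = cfg$perfusion$fitWindow,
                      scale = cfg$perfusion$scale,
                      perfusionMedianRadius = cfg$perfusion$medianRadius,
                      roiPolicy = cfg$classify$roiPolicy,
                      minVoxels = cfg$classify$minVoxels)

  cutoffs <- if (identical(cfg$classify$cutoffs, "reference"))
    referenceCutoffs()
  else do.call(cutoffSet, cfg$classify$cutoffs)
  seg <- res$segments
  ok <- !seg$flagged
  seg$fdClass <- NA_character_
  seg$mbfClass <- NA_character_
  seg$fdClass[ok] <- as.character(classifyFd(seg$meanFd[ok], cutoffs))
  seg$mbfClass[ok] <- as.character(classifyMbf(seg$meanMbf[ok], cutoffs))
  aggFd <- aggregateToVesselPatient(seg$segment[ok], seg$fdClass[ok])
  aggMbf <- aggregateToVesselPatient(seg$segment[ok], seg$mbfClass[ok])

  if (!dir.exists(cfg$output)) dir.create(cfg$output, recursive = TRUE)
  hash <- .configHash(cfg)
  paths <- c(fd = file.path(cfg$output, "fd_map.nii.gz"),
             mbf = file.path(cfg$output, "mbf_map.nii.gz"),
             segments = file.path(cfg$output, "segments.csv"),
             report = file.path(cfg$output, "report.json"),
             provenance = file.path(cfg$output, "provenance.json"))
  writeFdMap(res$fd, paths["fd"], spacing = image@spacing)
  .writeVolume3d(ifelse(is.na(res$mbf@mbf), -1, res$mbf@mbf),
                 image@spacing, paths["mbf"])
  segOut <- seg
  segOut$configHash <- hash
  utils::write.csv(segOut, paths["segments"], row.names = FALSE)
  report <- list(
    configHash = hash,
    cutoffs = list(fdIschemia = cutoffs@fdIschemia,
                   fdMacro = cutoffs@fdMacro,
                   mbfIschemia = cutoffs@mbfIschemia,
                   mbfMacro = cutoffs@mbfMacro),
    patientClassFd = as.character(aggFd$patient),
    patientClassMbf = as.character(aggMbf$patient),
    vesselClassFd = as.list(as.character(aggFd$vessel)),
    vesselClassMbf = as.list(as.character(aggMbf$vessel)),
    sigmaRange = res$noise@sigmaRange)
  names(report$vesselClassFd) <- names(aggFd$vessel)
  names(report$vesselClassMbf) <- names(aggMbf$vessel)
  jsonlite::write_json(report, paths["report"], auto_unbox = TRUE,
                       digits = NA)
  prov <- list(configHash = hash, config = cfg,
               package = as.character(utils::packageVersion("fractalCTP")),
               rVersion = R.version.string, seed = cfg$seed)
  jsonlite::write_json(prov, paths["provenance"], auto_unbox = TRUE,
                       digits = NA)
  invisible(c(res, list(outputFiles = paths, report = report)))
}

.readMask <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("mask must be a 3D volume: ", path)
  array(as.numeric(img) > 0.5, d)
}
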