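# Threshold classification of perfusion state and cutoff derivation.

#' Build a cutoff set
#'
#' @param fdIschemia,fdMacro FD thresholds (normal vs any ischemia; micro
#'   vs macro), \code{fdMacro < fdIschemia}.
#' @param mbfIschemia,mbfMacro MBF analogues in ml/min/100 ml.
#' @return a \linkS4class{CutoffSet}.
#' @export
cutoffSet <- function(fdIschemia = NA_real_, fdMacro = NA_real_,
                      mbfIschemia = NA_real_, mbfMacro = NA_real_) {
  new("CutoffSet", fdIschemia = as.numeric(fdIschemia),
      fdMacro = as.numeric(fdMacro),
      mbfIschemia = as.numeric(mbfIschemia),
      mbfMacro = as.numeric(mbfMacro))
}

#' Reference cutoffs from a clinical stress 4D-CTP cohort
#'
#' FD and MBF thresholds reported for a 30-patient clinical stress
#' perfusion cohort with invasive reference standard. Absolute FD values
#' depend on implementation choices (quantization, scale range, window);
#' these constants are reference values for that calibration, not a
#' universal one, and phantom experiments should derive their own cutoffs
#' with \code{\link{optimalCutoffs}}.
#'
#' @return a \linkS4class{CutoffSet} with FD 4.41/4.31 and
#'   MBF 107.7/86.5 ml/min/100 ml.
#' @export
referenceCutoffs <- function() {
  cutoffSet(fdIschemia = 4.41, fdMacro = 4.31,
            mbfIschemia = 107.7, mbfMacro = 86.5)
}

.classify <- function(x, cutIschemia, cutMacro) {
  if (any(!is.finite(x))) stop("values must be finite")
  out <- ifelse(x <= cutMacro, "macro",
         ifelse(x <= cutIschemia, "micro", "normal"))
  factor(out, levels = .PERFUSION_CLASSES)
}

#' Classify perfusion state from fractal dimension
#'
#' Values at or below the macro threshold are macrovascular; values above
#' it but at or below the ischemia threshold are microvascular; higher
#' values are normal ("<=" assigns the more diseased class on the
#' boundary).
#'
#' @param fd numeric FD values.
#' @param cutoffs a \linkS4class{CutoffSet}.
#' @return factor with levels normal, micro, macro.
#' @export
classifyFd <- function(fd, cutoffs = referenceCutoffs()) {
  stopifnot(is(cutoffs, "CutoffSet"))
  .classify(fd, cutoffs@fdIschemia, cutoffs@fdMacro)
}

#' Classify perfusion state from the MBF surrogate
#'
#' @param mbf numeric MBF values (ml/min/100 ml).
#' @param cutoffs a \linkS4class{CutoffSet}.
#' @return factor with levels normal, micro, macro.
#' @export
classifyMbf <- function(mbf, cutoffs = referenceCutoffs()) {
  stopifnot(is(cutoffs, "CutoffSet"))
  .classify(mbf, cutoffs@mbfIschemia, cutoffs@mbfMacro)
}

#' Aggregate segment classes to vessels and patient
#'
#' A unit (vessel or patient) is macrovascular (CAD) when at least one of
#' its member segments is macro; otherwise microvascular when at least one
#' is micro; otherwise normal. Order of the segments is irrelevant.
#'
#' @param segments integer/character segment ids.
#' @param classes factor/character per-segment classes (normal, micro,
#'   macro).
#' @param vesselMap named vector mapping segment id to vessel (default the
#'   AHA convention, \code{\link{ahaVesselMap}}).
#' @return list with \code{patient} (single class) and \code{vessel}
#'   (named factor per vessel).
#' @export
aggregateToVesselPatient <- function(segments, classes,
                                     vesselMap = ahaVesselMap()) {
  cls <- as.character(classes)
  if (!all(cls %in% .PERFUSION_CLASSES)) stop("unknown class label")
  vessels <- vesselMap[as.character(segments)]
  if (any(is.na(vessels)))
    stop("unmapped segment id: ",
         paste(segments[is.na(vessels)], collapse = ", "))
  worst <- function(x) {
    if (any(x == "macro")) "macro" else if (any(x == "micro")) "micro"
    else "normal"
  }
  vcls <- vapply(split(cls, vessels), worst, character(1))
  list(patient = factor(worst(cls), levels = .PERFUSION_CLASSES),
       vessel = factor(vcls, levels = .PERFUSION_CLASSES))
}

#' Per-patient averaging of segment values
#'
#' Eliminates intra-patient clustering before patient-level statistics by
#' arithmetic averaging of segment values within each patient.
#'
#' @param values numeric per-segment values.
#' @param patient patient identifier per value.
#' @return named numeric vector of patient means.
#' @export
patientAverage <- function(values, patient) {
  if (length(values) != length(patient)) stop("length mismatch")
  c(tapply(values, patient, mean))
}

# Youden-optimal threshold for the rule "value <= cutoff => positive".
# Candidates are midpoints between consecutive sorted unique values;
# among ties the midpoint of the optimal interval is returned.
.youdenCutoff <- function(values, positive) {
  u <- sort(unique(values))
  if (length(u) < 2)
    return(list(cutoff = u[1], j = 0, reliable = FALSE))
  cand <- (u[-1] + u[-length(u)]) / 2
  j <- vapply(cand, function(cc) {
    sens <- mean(values[positive] <= cc)
    spec <- mean(values[!positive] > cc)
    sens + spec - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)
  cutoff <- mean(range(cand[best]))
  list(cutoff = cutoff, j = max(j), reliable = max(j) > 0.1)
}

#' Derive optimal classification cutoffs from labeled values
#'
#' Two-stage multi-class ROC: the ischemia threshold separates normal from
#' pooled (micro + macro) ischemia, the macro threshold separates micro
#' from macro within the ischemic values. Each threshold maximizes
#' Youden's J over candidate midpoints between sorted unique values, with
#' ties broken toward the midpoint of the optimal interval. Lower values
#' are assumed more diseased (as for both FD and MBF).
#'
#' @param values numeric marker values (typically patient-averaged).
#' @param labels classes (normal, micro, macro); at least two distinct
#'   classes must be present.
#' @return list with \code{cutoffIschemia}, \code{cutoffMacro},
#'   \code{jIschemia}, \code{jMacro}, \code{reliable}.
#' @export
optimalCutoffs <- function(values, labels) {
  cls <- as.character(labels)
  if (!all(cls %in% .PERFUSION_CLASSES)) stop("unknown class label")
  if (length(unique(cls)) < 2)
    stop("degenerate single-class input; cutoffs undefined")
  s1 <- .youdenCutoff(values, positive = cls != "normal")
  isch <- cls != "normal"
  s2 <- if (all(c("micro", "macro") %in% cls)) {
    .youdenCutoff(values[isch], positive = cls[isch] == "macro")
  } else list(cutoff = NA_real_, j = NA_real_, reliable = FALSE)
  list(cutoffIschemia = s1$cutoff, cutoffMacro = s2$cutoff,
       jIschemia = s1$j, jMacro = s2$j,
       reliable = isTRUE(s1$reliable) &&
         (is.na(s2$j) || isTRUE(s2$reliable)))
}
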