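#' @import methods
NULL

.PERFUSION_CLASSES <- c("normal", "micro", "macro")
.INTENSITY_UNITS <- c("HU", "mg_iodine_per_ml")

#' PerfusionCurve: a sampled contrast-enhancement time curve
#'
#' Holds a time-to-intensity curve sampled on the acquisition frame grid,
#' either an arterial input function (AIF) measured in the aorta or a
#' myocardial tissue curve.
#'
#' @slot times numeric, sample times in seconds, strictly increasing.
#' @slot values numeric, intensity at each sample (HU or mg iodine/ml).
#' @slot provenance character, free-text origin (e.g. "aif", "voxel").
#' @exportClass PerfusionCurve
setClass("PerfusionCurve",
  representation(times = "numeric", values = "numeric",
                 provenance = "character"),
  prototype(provenance = "curve"),
  validity = function(object) {
    msg <- NULL
    if (length(object@times) != length(object@values))
      msg <- c(msg, "'times' and 'values' must have equal length")
    if (length(object@times) >= 2 && any(diff(object@times) <= 0))
      msg <- c(msg, "'times' must be strictly increasing")
    if (anyNA(object@times) || anyNA(object@values))
      msg <- c(msg, "NA values are not allowed in a PerfusionCurve")
    if (is.null(msg)) TRUE else msg
  })

#' DynamicPerfusionImage: a 4D dynamic contrast-enhanced volume
#'
#' The analyzed object: a 4D intensity array ordered (x, y, z, t) with
#' spatial voxel spacing and per-frame acquisition times.
#'
#' @slot data 4D numeric array (x, y, z, t).
#' @slot spacing numeric length-3, voxel spacing in mm per spatial axis.
#' @slot frameTimes numeric, acquisition time of each frame in seconds,
#'   strictly increasing, length equal to \code{dim(data)[4]}.
#' @slot unit character, \code{"HU"} or \code{"mg_iodine_per_ml"}.
#' @exportClass DynamicPerfusionImage
setClass("DynamicPerfusionImage",
  representation(data = "array", spacing = "numeric",
                 frameTimes = "numeric", unit = "character"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@data)
    if (length(d) != 4L)
      msg <- c(msg, "'data' must be a 4D array (x, y, z, t)")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "'spacing' must be 3 positive values (mm)")
    if (length(d) == 4L && length(object@frameTimes) != d[4])
      msg <- c(msg, "'frameTimes' length must equal the number of frames")
    if (length(object@frameTimes) >= 2 && any(diff(object@frameTimes) <= 0))
      msg <- c(msg, "'frameTimes' must be strictly increasing")
    if (length(object@unit) != 1L || !object@unit %in% .INTENSITY_UNITS)
      msg <- c(msg, sprintf("'unit' must be one of: %s",
                            paste(.INTENSITY_UNITS, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
  })

#' NoiseEstimate: image noise level from unenhanced baseline frames
#'
#' @slot sigmaRange numeric, pooled intensity standard deviation of the
#'   masked myocardium over the baseline (pre-contrast) frames, after
#'   per-frame mean removal.
#' @slot sourceFrames integer, indices of the baseline frames used.
#' @slot nVoxels integer, number of mask voxels that entered the estimate.
#' @exportClass NoiseEstimate
setClass("NoiseEstimate",
  representation(sigmaRange = "numeric", sourceFrames = "integer",
                 nVoxels = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@sigmaRange) != 1L || is.na(object@sigmaRange) ||
        object@sigmaRange < 0)
      msg <- c(msg, "'sigmaRange' must be a single non-negative number")
    if (length(object@sourceFrames) < 1L)
      msg <- c(msg, "'sourceFrames' must be non-empty")
    if (is.null(msg)) TRUE else msg
  })

#' BlanketState: paired top/bottom blanket hypertextures at one scale
#'
#' State of the blanket (Minkowski cover) iteration: the top blanket u is
#' iteratively raised from the quantized image, the bottom blanket b
#' lowered, so that at scale epsilon the sandwich
#' \code{b <= image <= u} holds with thickness \code{u - b >= 2*epsilon}.
#'
#' @slot u numeric array, top blanket (same shape as the image).
#' @slot b numeric array, bottom blanket.
#' @slot epsilon integer, the current scale (iteration counter, >= 0).
#' @exportClass BlanketState
setClass("BlanketState",
  representation(u = "array", b = "array", epsilon = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@u), dim(object@b)))
      msg <- c(msg, "'u' and 'b' must have identical dimensions")
    if (length(object@epsilon) != 1L || object@epsilon < 0L)
      msg <- c(msg, "'epsilon' must be a single non-negative integer")
    if (object@epsilon > 0L &&
        any(object@u - object@b < 2 * object@epsilon - 1e-9))
      msg <- c(msg, "blanket sandwich violated: u - b < 2*epsilon")
    if (is.null(msg)) TRUE else msg
  })

#' FdMap: 3D map of local fractal dimension
#'
#' The result of 4D local fractal analysis: the temporal dimension is
#' collapsed by the blanket construction, yielding one fractal-dimension
#' value per spatial voxel (nominal range [4, 5] for a 4D hypertexture).
#'
#' @slot fd 3D numeric array of local fractal dimension; NA outside the
#'   valid region.
#' @slot validMask 3D logical array: voxels whose local analysis window
#'   lies fully inside the grid and the analysis mask.
#' @slot fitR2 3D numeric array, per-voxel R^2 of the log-log fit.
#' @slot epsilons numeric, the scales used in the fit.
#' @slot levels numeric, intensity quantization levels used.
#' @exportClass FdMap
setClass("FdMap",
  representation(fd = "array", validMask = "array", fitR2 = "array",
                 epsilons = "numeric", levels = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@fd)) != 3L)
      msg <- c(msg, "'fd' must be a 3D array")
    if (!identical(dim(object@fd), dim(object@validMask)) ||
        !identical(dim(object@fd), dim(object@fitR2)))
      msg <- c(msg, "'fd', 'validMask' and 'fitR2' dimensions must agree")
    v <- object@fd[object@validMask]
    if (length(v) && any(is.na(v)))
      msg <- c(msg, "'fd' must be finite on the valid mask")
    if (is.null(msg)) TRUE else msg
  })

#' MbfMap: 3D map of the maximum-upslope blood-flow surrogate
#'
#' @slot mbf 3D numeric array in ml/min/100 ml; NA outside the valid mask.
#' @slot validMask 3D logical array.
#' @slot nFloored integer, number of voxels whose negative upslope fit was
#'   floored at 0 (flagged, not silently hidden).
#' @exportClass MbfMap
setClass("MbfMap",
  representation(mbf = "array", validMask = "array", nFloored = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@mbf)) != 3L)
      msg <- c(msg, "'mbf' must be a 3D array")
    if (!identical(dim(object@mbf), dim(object@validMask)))
      msg <- c(msg, "'mbf' and 'validMask' dimensions must agree")
    v <- object@mbf[object@validMask]
    if (length(v) && (any(is.na(v)) || any(v < 0)))
      msg <- c(msg, "'mbf' must be finite and >= 0 on the valid mask")
    if (is.null(msg)) TRUE else msg
  })

#' SegmentModel: geometry of the AHA 17-segment partition
#'
#' Defines how left-ventricular myocardium mask voxels are assigned to the
#' standard AHA 17 segments: a long-axis position (here the slice axis), an
#' angular origin at the anterior right-ventricular insertion point, and the
#' partition of slices into basal, mid-cavity and apical thirds plus the
#' apical cap.
#'
#' @slot center numeric length-2, in-plane (x, y) voxel coordinates of the
#'   LV long axis.
#' @slot rvAngleDeg numeric, angle (degrees, in voxel coordinates,
#'   counter-clockwise from +x) of the anterior RV insertion; the angular
#'   origin of segment 1.
#' @slot basalZ,midZ,apicalZ,capZ integer vectors of slice indices forming
#'   the basal, mid-cavity and apical thirds and the apical cap.
#' @exportClass SegmentModel
setClass("SegmentModel",
  representation(center = "numeric", rvAngleDeg = "numeric",
                 basalZ = "integer", midZ = "integer",
                 apicalZ = "integer", capZ = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@center) != 2L)
      msg <- c(msg, "'center' must be (x, y)")
    if (length(object@rvAngleDeg) != 1L || object@rvAngleDeg < 0 ||
        object@rvAngleDeg >= 360)
      msg <- c(msg, "'rvAngleDeg' must be in [0, 360)")
    zs <- c(object@basalZ, object@midZ, object@apicalZ, object@capZ)
    if (anyDuplicated(zs))
      msg <- c(msg, "slice thirds and cap must not overlap")
    if (is.null(msg)) TRUE else msg
  })

#' CutoffSet: classification thresholds for FD and MBF
#'
#' Two-threshold rule per marker: values at or below the macro threshold are
#' macrovascular, values above the ischemia threshold are normal, values in
#' between are microvascular. The "at or below" convention assigns the more
#' diseased class on the boundary.
#'
#' @slot fdIschemia,fdMacro numeric FD thresholds (normal vs any ischemia;
#'   micro vs macro), with \code{fdMacro < fdIschemia}.
#' @slot mbfIschemia,mbfMacro numeric MBF analogues in ml/min/100 ml.
#' @exportClass CutoffSet
setClass("CutoffSet",
  representation(fdIschemia = "numeric", fdMacro = "numeric",
                 mbfIschemia = "numeric", mbfMacro = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@fdIschemia) && length(object@fdMacro) &&
        !is.na(object@fdIschemia) && !is.na(object@fdMacro) &&
        object@fdMacro >= object@fdIschemia)
      msg <- c(msg, "'fdMacro' must be < 'fdIschemia'")
    if (length(object@mbfIschemia) && length(object@mbfMacro) &&
        !is.na(object@mbfIschemia) && !is.na(object@mbfMacro) &&
        object@mbfMacro >= object@mbfIschemia)
      msg <- c(msg, "'mbfMacro' must be < 'mbfIschemia'")
    if (is.null(msg)) TRUE else msg
  })

#' PhantomBundle: a synthetic 4D perfusion dataset with ground truth
#'
#' @slot image DynamicPerfusionImage, the simulated 4D acquisition.
#' @slot mask 3D logical array, myocardium.
#' @slot aifRoi 3D logical array, voxels of the simulated aorta used for
#'   AIF extraction; disjoint from the myocardium mask.
#' @slot truth 3D integer array on mask voxels: 0 normal, 1 micro, 2 macro
#'   (NA outside the mask).
#' @slot segmentTruth data.frame with columns segment, truthClass.
#' @slot model SegmentModel matching the phantom geometry.
#' @slot spec list, the full phantom specification used.
#' @exportClass PhantomBundle
setClass("PhantomBundle",
  representation(image = "DynamicPerfusionImage", mask = "array",
                 aifRoi = "array", truth = "array",
                 segmentTruth = "data.frame", model = "SegmentModel",
                 spec = "list"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@image@data)[1:3]
    if (!identical(dim(object@mask), d) || !identical(dim(object@aifRoi), d) ||
        !identical(dim(object@truth), d))
      msg <- c(msg, "mask/aifRoi/truth must match the spatial grid")
    if (any(object@mask & object@aifRoi))
      msg <- c(msg, "'aifRoi' must be disjoint from the myocardium mask")
    if (any(is.na(object@truth[object@mask])))
      msg <- c(msg, "'truth' must be defined on every mask voxel")
    if (any(!is.na(object@truth[!object@mask])))
      msg <- c(msg, "'truth' must be NA outside the mask")
    if (is.null(msg)) TRUE else msg
  })
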