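#' Accessors for fractalCTP objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object an object of the corresponding fractalCTP class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("intensityUnit", function(object) standardGeneric("intensityUnit"))
#' @rdname accessors
#' @export
setGeneric("curveTimes", function(object) standardGeneric("curveTimes"))
#' @rdname accessors
#' @export
setGeneric("curveValues", function(object) standardGeneric("curveValues"))
#' @rdname accessors
#' @export
setGeneric("fdValues", function(object) standardGeneric("fdValues"))
#' @rdname accessors
#' @export
setGeneric("mbfValues", function(object) standardGeneric("mbfValues"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("fitR2", function(object) standardGeneric("fitR2"))
#' @rdname accessors
#' @export
setGeneric("sigmaRange", function(object) standardGeneric("sigmaRange"))

#' @rdname accessors
setMethod("imageData", "DynamicPerfusionImage", function(object) object@data)
#' @rdname accessors
setMethod("voxelSpacing", "DynamicPerfusionImage",
          function(object) object@spacing)
#' @rdname accessors
setMethod("frameTimes", "DynamicPerfusionImage",
          function(object) object@frameTimes)
#' @rdname accessors
setMethod("intensityUnit", "DynamicPerfusionImage",
          function(object) object@unit)
#' @rdname accessors
setMethod("imageData", "PhantomBundle", function(object) object@image@data)

#' @rdname accessors
setMethod("curveTimes", "PerfusionCurve", function(object) object@times)
#' @rdname accessors
setMethod("curveValues", "PerfusionCurve", function(object) object@values)

#' @rdname accessors
setMethod("fdValues", "FdMap", function(object) object@fd)
#' @rdname accessors
setMethod("validMask", "FdMap", function(object) object@validMask)
#' @rdname accessors
setMethod("fitR2", "FdMap", function(object) object@fitR2)
#' @rdname accessors
setMethod("mbfValues", "MbfMap", function(object) object@mbf)
#' @rdname accessors
setMethod("validMask", "MbfMap", function(object) object@validMask)
#' @rdname accessors
setMethod("sigmaRange", "NoiseEstimate", function(object) object@sigmaRange)

#' Phantom accessors
#'
#' @param object a \linkS4class{PhantomBundle}.
#' @name phantom-accessors
NULL

#' @rdname phantom-accessors
#' @export
setGeneric("phantomImage", function(object) standardGeneric("phantomImage"))
#' @rdname phantom-accessors
#' @export
setGeneric("phantomMask", function(object) standardGeneric("phantomMask"))
#' @rdname phantom-accessors
#' @export
setGeneric("phantomAifRoi", function(object) standardGeneric("phantomAifRoi"))
#' @rdname phantom-accessors
#' @export
setGeneric("phantomTruth", function(object) standardGeneric("phantomTruth"))
#' @rdname phantom-accessors
#' @export
setGeneric("phantomSegmentTruth",
           function(object) standardGeneric("phantomSegmentTruth"))
#' @rdname phantom-accessors
#' @export
setGeneric("phantomModel", function(object) standardGeneric("phantomModel"))

#' @rdname phantom-accessors
setMethod("phantomImage", "PhantomBundle", function(object) object@image)
#' @rdname phantom-accessors
setMethod("phantomMask", "PhantomBundle", function(object) object@mask)
#' @rdname phantom-accessors
setMethod("phantomAifRoi", "PhantomBundle", function(object) object@aifRoi)
#' @rdname phantom-accessors
setMethod("phantomTruth", "PhantomBundle", function(object) object@truth)
#' @rdname phantom-accessors
setMethod("phantomSegmentTruth", "PhantomBundle",
          function(object) object@segmentTruth)
#' @rdname phantom-accessors
setMethod("phantomModel", "PhantomBundle", function(object) object@model)

#' Cutoff accessors
#'
#' @param object a \linkS4class{CutoffSet}.
#' @param marker \code{"fd"} or \code{"mbf"}.
#' @return numeric length-2 vector \code{c(ischemia, macro)}.
#' @export
cutoffValues <- function(object, marker = c("fd", "mbf")) {
  stopifnot(is(object, "CutoffSet"))
  marker <- match.arg(marker)
  if (marker == "fd") c(ischemia = object@fdIschemia, macro = object@fdMacro)
  else c(ischemia = object@mbfIschemia, macro = object@mbfMacro)
}

setMethod("show", "DynamicPerfusionImage", function(object) {
  d <- dim(object@data)
  cat("DynamicPerfusionImage\n")
  cat(sprintf("  grid     : %d x %d x %d voxels, %d frames\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing  : %s mm\n",
              paste(format(object@spacing), collapse = " x ")))
  cat(sprintf("  frames   : %.1f .. %.1f s\n",
              min(object@frameTimes), max(object@frameTimes)))
  cat(sprintf("  unit     : %s\n", object@unit))
})

setMethod("show", "FdMap", function(object) {
  v <- object@fd[object@validMask]
  cat("FdMap (local 4D blanket fractal dimension)\n")
  cat(sprintf("  grid        : %s\n", paste(dim(object@fd), collapse = " x ")))
  cat(sprintf("  valid voxels: %d\n", sum(object@validMask)))
  if (length(v))
    cat(sprintf("  FD range    : %.3f .. %.3f (median %.3f)\n",
                min(v), max(v), stats::median(v)))
  cat(sprintf("  scales      : %s\n",
              paste(object@epsilons, collapse = ", ")))
})

setMethod("show", "MbfMap", function(object) {
  v <- object@mbf[object@validMask]
  cat("MbfMap (maximum-upslope perfusion surrogate)\n")
  cat(sprintf("  grid        : %s\n", paste(dim(object@mbf), collapse = " x ")))
  cat(sprintf("  valid voxels: %d\n", sum(object@validMask)))
  if (length(v))
    cat(sprintf("  MBF median  : %.1f ml/min/100ml\n", stats::median(v)))
  if (object@nFloored > 0L)
    cat(sprintf("  flagged     : %d voxels floored at 0\n", object@nFloored))
})

setMethod("show", "CutoffSet", function(object) {
  cat("CutoffSet (value <= cutoff assigns the more diseased class)\n")
  cat(sprintf("  FD : ischemia <= %.3f, macro <= %.3f\n",
              object@fdIschemia, object@fdMacro))
  cat(sprintf("  MBF: ischemia <= %.1f, macro <= %.1f ml/min/100ml\n",
              object@mbfIschemia, object@mbfMacro))
})

setMethod("show", "PhantomBundle", function(object) {
  cat("PhantomBundle\n")
  cat(sprintf("  regime : %s\n", object@spec$regime))
  cat(sprintf("  seed   : %s, hurst %.2f, noise sigma %.1f\n",
              object@spec$seed, object@spec$hurst, object@spec$noiseSigma))
  show(object@image)
  tab <- table(factor(.PERFUSION_CLASSES[object@truth[object@mask] + 1L],
                      levels = .PERFUSION_CLASSES))
  cat(sprintf("  voxels : %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "NoiseEstimate", function(object) {
  cat(sprintf(
    "NoiseEstimate: sigma_range = %.3f (frames %s, %d voxels)\n",
    object@sigmaRange, paste(object@sourceFrames, collapse = ","),
    object@nVoxels))
})
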