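# NIfTI-1 reading/writing and run configuration handling.

#' Read a 4D dynamic volume from NIfTI-1
#'
#' Axes are taken as (x, y, z, t); spatial spacing comes from the header
#' pixdim, frame times from the temporal pixdim unless overridden. Input
#' volumes are assumed motion-corrected: registration is outside the scope
#' of this package and a notice is logged on read. DICOM series are not
#' supported; convert to NIfTI upstream.
#'
#' @param path path to a 4D NIfTI-1 file.
#' @param frameInterval optional frame spacing override in seconds.
#' @param frameTimes optional explicit frame times (overrides everything).
#' @param unit intensity unit of the stored data.
#' @param quiet suppress the motion-correction notice.
#' @return a \linkS4class{DynamicPerfusionImage}.
#' @export
readDynamicVolume <- function(path, frameInterval = NULL,
                              frameTimes = NULL, unit = "HU",
                              quiet = FALSE) {
  if (dir.exists(path))
    stop("'", path, "' is a directory; DICOM series are not supported -- ",
         "convert the series to a 4D NIfTI-1 file first")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 5L && d[5] == 1L) {
    dim(img) <- d <- d[1:4]
  }
  if (length(d) != 4L)
    stop("expected a 4D (x, y, z, t) volume; got ", length(d),
         " dimensions. A 3D input has no time axis.")
  pd <- RNifti::pixdim(img)
  spacing <- abs(pd[1:3])
  if (is.null(frameTimes)) {
    dt <- if (!is.null(frameInterval)) frameInterval
          else if (length(pd) >= 4) abs(pd[4]) else 0
    if (!is.finite(dt) || dt <= 0)
      stop("frame timing missing from the header; pass 'frameInterval' ",
           "or 'frameTimes'")
    frameTimes <- (seq_len(d[4]) - 1) * dt
  }
  if (!quiet)
    message("note: input is assumed motion-corrected; this package does ",
            "not perform registration")
  new("DynamicPerfusionImage", data = array(as.numeric(img), d),
      spacing = as.numeric(spacing), frameTimes = as.numeric(frameTimes),
      unit = unit)
}

#' Write a 4D dynamic volume to NIfTI-1
#'
#' Frame times are stored as a uniform temporal pixdim (the first frame
#' interval); irregular frame grids should be carried in a sidecar.
#'
#' @param image a \linkS4class{DynamicPerfusionImage}.
#' @param path output path (.nii or .nii.gz).
#' @return invisibly, \code{path}.
#' @export
writeDynamicVolume <- function(image, path) {
  stopifnot(is(image, "DynamicPerfusionImage"))
  dt <- if (length(image@frameTimes) >= 2) diff(image@frameTimes)[1] else 1
  nii <- RNifti::asNifti(image@data)
  RNifti::pixdim(nii) <- c(image@spacing, dt)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

# 3D volume writer used for masks, labels and maps.
.writeVolume3d <- function(data, spacing, path) {
  nii <- RNifti::asNifti(array(as.numeric(data), dim(data)))
  RNifti::pixdim(nii) <- spacing
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Write an FD map (and its fit-quality companion) to NIfTI-1
#'
#' @param fdmap an \linkS4class{FdMap}.
#' @param path output path for the FD volume; the R^2 companion gets a
#'   "_r2" suffix.
#' @param spacing voxel spacing in mm.
#' @return invisibly, the two paths.
#' @export
writeFdMap <- function(fdmap, path, spacing = c(1, 1, 1)) {
  stopifnot(is(fdmap, "FdMap"))
  .writeVolume3d(fdmap@fd, spacing, path)
  r2path <- sub("(\\.nii(\\.gz)?)$", "_r2\\1", path)
  if (r2path == path) r2path <- paste0(path, "_r2.nii.gz")
  .writeVolume3d(fdmap@fitR2, spacing, r2path)
  invisible(c(path, r2path))
}

# ---- run configuration ----

.configSchema <- function() {
  list(
    image = NULL, mask = NULL, aifRoi = NULL, output = NULL,
    seed = 1, verbosity = 1,
    landmarks = list(center = NULL, rvAngleDeg = 0, basalZ = NULL,
                     midZ = NULL, apicalZ = NULL, capZ = integer(0)),
    preprocess = list(baselineFrames = c(1, 2), medianGateK = 3,
                      sigmaDomain = 2, huPerMgMl = 24),
    fractal = list(epsMax = 4, windowRadius = 5, levels = 256,
                   neighborhood = "axis"),
    perfusion = list(fitWindow = 3, scale = 6000, medianRadius = 3),
    classify = list(cutoffs = "reference", minVoxels = 10,
                    roiPolicy = "all")
  )
}

.mergeConfig <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]])) stop("config key '", path, k,
                                    "' must be a block")
      defaults[[k]] <- .mergeConfig(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read and validate a run configuration
#'
#' Accepts a YAML file path or a named list; unknown keys are rejected.
#' See \code{\link{runPipeline}} for the recognized blocks.
#'
#' @param config path to a YAML file, or a named list.
#' @return validated configuration list with defaults filled in.
#' @export
readRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("'config' must be a list or a YAML path")
  .mergeConfig(.configSchema(), config)
}

# Stable hash of a configuration (md5 of its canonical JSON). Output
# location and verbosity do not change the analysis and are excluded, so
# re-running the same analysis elsewhere keeps its identity.
.configHash <- function(config) {
  config$output <- NULL
  config$verbosity <- NULL
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(f))
}
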