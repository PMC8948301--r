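# AHA 17-segment model: regional aggregation of FD and MBF maps.

#' Construct a segment model
#'
#' @param center in-plane (x, y) voxel coordinates of the LV long axis.
#' @param rvAngleDeg angular origin (degrees, counter-clockwise from +x in
#'   voxel coordinates) at the anterior RV insertion point.
#' @param basalZ,midZ,apicalZ,capZ slice indices of the basal, mid and
#'   apical thirds and of the apical cap.
#' @return a \linkS4class{SegmentModel}.
#' @export
segmentModel <- function(center, rvAngleDeg, basalZ, midZ, apicalZ,
                         capZ = integer(0)) {
  new("SegmentModel", center = as.numeric(center),
      rvAngleDeg = normDeg(rvAngleDeg), basalZ = as.integer(basalZ),
      midZ = as.integer(midZ), apicalZ = as.integer(apicalZ),
      capZ = as.integer(capZ))
}

#' Assign myocardium voxels to AHA segments
#'
#' Basal slices are split into six 60-degree sectors (segments 1-6,
#' counting from the RV-insertion origin), mid-cavity slices into segments
#' 7-12, apical slices into four 90-degree sectors (segments 13-16), and
#' the apical cap becomes segment 17. Mask voxels lying exactly on the
#' long axis of a non-cap slice cannot be assigned an angle and are
#' excluded, with the count reported via attribute
#' \code{"nUnassigned"}.
#'
#' @param mask 3D logical myocardium mask (an annulus around the axis in
#'   each non-cap slice).
#' @param model a \linkS4class{SegmentModel}.
#' @return 3D integer array of segment ids 1-17 (NA outside the mask),
#'   with attribute \code{"nUnassigned"}.
#' @export
assignSegments <- function(mask, model) {
  stopifnot(is(model, "SegmentModel"))
  d <- dim(mask)
  g <- coordGrid3d(d)
  theta <- normDeg(atan2(g$y - model@center[2],
                         g$x - model@center[1]) * 180 / pi -
                   model@rvAngleDeg)
  onAxis <- g$x == model@center[1] & g$y == model@center[2]
  labels <- array(NA_integer_, d)
  zBand <- array(NA_integer_, d)
  zBand[, , model@basalZ] <- 1L
  zBand[, , model@midZ] <- 2L
  zBand[, , model@apicalZ] <- 3L
  zBand[, , model@capZ] <- 4L

  sel <- mask & !is.na(zBand)
  sector6 <- pmin(floor(theta / 60), 5) + 1L
  sector4 <- pmin(floor(theta / 90), 3) + 1L
  lab <- ifelse(zBand == 1L, sector6,
         ifelse(zBand == 2L, 6L + sector6,
         ifelse(zBand == 3L, 12L + sector4, 17L)))
  labels[sel] <- lab[sel]
  unassigned <- sel & onAxis & zBand != 4L
  nUn <- sum(unassigned, na.rm = TRUE)
  labels[which(unassigned)] <- NA_integer_
  if (nUn > 0)
    message(sprintf("%d mask voxel(s) on the long axis excluded", nUn))
  attr(labels, "nUnassigned") <- as.integer(nUn)
  labels
}

#' The standard AHA segment-to-vessel convention
#'
#' Fixed mapping of the 17 segments to the three coronary territories
#' (LAD, RCA, LCX) for vessel-level analysis.
#'
#' @return named character vector, names are segment ids "1".."17".
#' @export
ahaVesselMap <- function() {
  m <- character(17)
  m[c(1, 2, 7, 8, 13, 14, 17)] <- "LAD"
  m[c(3, 4, 9, 10, 15)] <- "RCA"
  m[c(5, 6, 11, 12, 16)] <- "LCX"
  names(m) <- as.character(1:17)
  m
}

#' Per-segment summary of FD and MBF maps
#'
#' For every segment the ROI is the set of voxels that are valid in BOTH
#' maps (identical voxel sets for FD and MBF by construction). The default
#' policy uses the whole valid segment; policy \code{"core"} first erodes
#' each segment in-plane by \code{coreErosion} voxels to avoid boundary
#' effects. Segments whose ROI falls below \code{minVoxels} are flagged
#' and meant to be excluded from downstream statistics.
#'
#' @param fdmap an \linkS4class{FdMap}.
#' @param mbfmap an \linkS4class{MbfMap} on the same grid.
#' @param labels segment label volume from \code{\link{assignSegments}}.
#' @param roiPolicy \code{"all"} or \code{"core"}.
#' @param minVoxels minimum ROI size.
#' @param coreErosion in-plane erosion radius for the core policy.
#' @param truth optional data.frame (segment, truthClass) merged into the
#'   output.
#' @param patient optional patient identifier stored in the table.
#' @return data.frame with columns patient, segment, nVoxels, meanFd,
#'   meanMbf, truthClass (NA if not supplied), flagged; attribute
#'   \code{"roiPolicy"} records the policy used.
#' @export
segmentSummary <- function(fdmap, mbfmap, labels,
                           roiPolicy = c("all", "core"), minVoxels = 10,
                           coreErosion = 2, truth = NULL,
                           patient = NA_character_) {
  stopifnot(is(fdmap, "FdMap"), is(mbfmap, "MbfMap"))
  roiPolicy <- match.arg(roiPolicy)
  if (!identical(dim(fdmap@fd), dim(mbfmap@mbf)) ||
      !identical(dim(fdmap@fd), dim(labels)))
    stop("maps and segment labels must share one grid")
  segs <- sort(unique(labels[!is.na(labels)]))
  segArr <- labels
  if (roiPolicy == "core") {
    brush <- EBImage::makeBrush(2 * coreErosion + 1, shape = "disc")
    keep <- array(FALSE, dim(labels))
    for (s in segs) {
      segMask <- !is.na(labels) & labels == s
      er <- EBImage::erode(segMask * 1, brush)
      keep <- keep | (er > 0.5)
    }
    segArr[!keep] <- NA_integer_
  }
  valid <- fdmap@validMask & mbfmap@validMask
  rows <- lapply(segs, function(s) {
    roi <- !is.na(segArr) & segArr == s & valid
    n <- sum(roi)
    data.frame(patient = patient, segment = s, nVoxels = n,
               meanFd = if (n) mean(fdmap@fd[roi]) else NA_real_,
               meanMbf = if (n) mean(mbfmap@mbf[roi]) else NA_real_,
               flagged = n < minVoxels, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$truthClass <- NA_character_
  if (!is.null(truth)) {
    i <- match(out$segment, truth$segment)
    out$truthClass <- truth$truthClass[i]
  }
  out <- out[, c("patient", "segment", "nVoxels", "meanFd", "meanMbf",
                 "truthClass", "flagged")]
  attr(out, "roiPolicy") <- roiPolicy
  out
}
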