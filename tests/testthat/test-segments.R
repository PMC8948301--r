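mkModel <- function(nz = 7, center = c(16.5, 16.5)) {
  thirds <- split(seq_len(nz), cut(seq_len(nz), 3, labels = FALSE))
  segmentModel(center, 0, thirds[[1]], thirds[[2]], thirds[[3]],
               capZ = nz + 1L)
}

annulusMask <- function(d = c(32, 32, 8), center = c(16.5, 16.5),
                        r = c(5, 8)) {
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  rad <- array(sqrt((g$x - center[1])^2 + (g$y - center[2])^2), d[1:2])
  ring <- rad >= r[1] & rad <= r[2]
  cap <- rad <= 0.6 * r[2]
  mask <- array(FALSE, d)
  for (z in 1:(d[3] - 1)) mask[, , z] <- ring
  mask[, , d[3]] <- cap
  mask
}

test_that("segment assignment follows the AHA convention", {
  mask <- annulusMask()
  model <- mkModel()
  lab <- assignSegments(mask, model)
  # every mask voxel labeled, nothing else
  expect_true(all(!is.na(lab[mask])))
  expect_true(all(is.na(lab[!mask])))
  # all 17 segments present on an ideal annulus with cap
  expect_setequal(sort(unique(lab[mask])), 1:17)
  # apical cap voxels are segment 17
  expect_true(all(lab[, , 8][!is.na(lab[, , 8])] == 17L))
  # angular arithmetic: +30 deg -> segment 1, +90 deg -> segment 2 (basal)
  ang <- function(deg, r = 6.5)
    round(c(16.5 + r * cos(deg * pi / 180), 16.5 + r * sin(deg * pi / 180)))
  p1 <- ang(30); p2 <- ang(90)
  expect_equal(lab[p1[1], p1[2], 1], 1L)
  expect_equal(lab[p2[1], p2[2], 1], 2L)
  # mid-cavity slices map to 7..12, apical ring to 13..16
  expect_true(all(lab[, , 4][mask[, , 4]] %in% 7:12))
  expect_true(all(lab[, , 7][mask[, , 7]] %in% 13:16))
  # basal sectors have near-equal voxel counts by symmetry
  counts <- table(lab[, , 1][mask[, , 1]])
  expect_lte(diff(range(counts)), 4)
})

test_that("segment labels partition the mask", {
  b <- synthesizePhantom(smallSpec(seed = 4))
  lab <- assignSegments(phantomMask(b), phantomModel(b))
  expect_equal(sum(!is.na(lab)), sum(phantomMask(b)))
  expect_true(all(!is.na(lab[phantomMask(b)])))
})

test_that("vessel map covers all 17 segments across LAD/RCA/LCX", {
  vm <- ahaVesselMap()
  expect_setequal(names(vm), as.character(1:17))
  expect_setequal(unique(vm), c("LAD", "RCA", "LCX"))
  expect_equal(unname(vm["17"]), "LAD")
})

test_that("segment summaries use identical ROIs for FD and MBF", {
  mask <- annulusMask()
  model <- mkModel()
  lab <- assignSegments(mask, model)
  d <- dim(mask)
  fdArr <- array(NA_real_, d); fdArr[mask] <- 4.2
  r2 <- array(NA_real_, d); r2[mask] <- 1
  # FD valid on a sub-region only; MBF valid everywhere on the mask
  fdValid <- mask; fdValid[, , 1] <- FALSE
  fdArr[!fdValid] <- NA
  fdm <- new("FdMap", fd = fdArr, validMask = fdValid, fitR2 = r2,
             epsilons = 1:4, levels = 256)
  mbfArr <- array(NA_real_, d); mbfArr[mask] <- 120
  mbm <- new("MbfMap", mbf = mbfArr, validMask = mask, nFloored = 0L)
  tab <- segmentSummary(fdm, mbm, lab)
  # constant maps: every unflagged segment mean equals the constant
  ok <- !tab$flagged
  expect_true(all(tab$meanFd[ok] == 4.2))
  expect_true(all(tab$meanMbf[ok] == 120))
  # segments living only on slice 1 lose their FD support and are flagged
  basalOnly <- setdiff(unique(lab[, , 1][mask[, , 1]]), unique(lab[, , 2]))
  # roi voxel counts reflect the intersected valid masks
  full <- segmentSummary(fdm, mbm, lab, minVoxels = 1)
  perSeg <- table(lab[fdValid & mask])
  expect_equal(full$nVoxels[match(names(perSeg), full$segment)],
               as.integer(perSeg))
})

test_that("flagged rows mark segments below the minimum ROI size", {
  mask <- annulusMask()
  lab <- assignSegments(mask, mkModel())
  d <- dim(mask)
  fdArr <- array(NA_real_, d)
  valid <- array(FALSE, d)
  sel <- !is.na(lab) & lab == 3L
  valid[sel] <- TRUE
  fdArr[sel] <- 4.5
  fdm <- new("FdMap", fd = fdArr, validMask = valid,
             fitR2 = ifelse(valid, 1, NA_real_), epsilons = 1:4,
             levels = 256)
  mbfArr <- array(NA_real_, d); mbfArr[mask] <- 100
  mbm <- new("MbfMap", mbf = mbfArr, validMask = mask, nFloored = 0L)
  tab <- segmentSummary(fdm, mbm, lab)
  expect_equal(sum(!tab$flagged), 1L)
  expect_equal(tab$segment[!tab$flagged], 3L)
})

test_that("macro-lesion phantoms show lower FD in lesion than remote segments", {
  for (s in 1:2) {
    b <- synthesizePhantom(phantomSpec(regime = "macro", seed = s))
    res <- suppressWarnings(analyzePhantom(b))
    tab <- res$segments[!res$segments$flagged, ]
    expect_lt(mean(tab$meanFd[tab$truthClass == "macro"]),
              mean(tab$meanFd[tab$truthClass == "normal"]))
    expect_lt(mean(tab$meanMbf[tab$truthClass == "macro"]),
              mean(tab$meanMbf[tab$truthClass == "normal"]))
  }
})
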