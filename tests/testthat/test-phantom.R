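test_that("gamma-variate AIF peaks at onset + alpha*beta with the stated amplitude", {
  times <- seq(0, 30, by = 0.5)
  aif <- makeAif(times, amplitude = 250, onset = 5, alpha = 3, beta = 1.5)
  v <- curveValues(aif)
  # analytic maximum, cross-checked on a dense grid
  tDense <- seq(0, 30, by = 1e-3)
  vDense <- curveValues(makeAif(tDense, 250, 5, 3, 1.5))
  expect_equal(max(vDense), 250, tolerance = 1e-6)
  expect_equal(tDense[which.max(vDense)], 5 + 3 * 1.5, tolerance = 2e-3)
  # the peak lands exactly on a sample here (5 + 4.5 = 9.5)
  expect_equal(v[times == 9.5], 250)
  expect_true(all(v >= 0))
})

test_that("AIF degenerate cases behave", {
  times <- seq(0, 26, by = 2)
  expect_equal(curveValues(makeAif(times, 0, 6)), rep(0, length(times)))
  lateOnset <- makeAif(times, 300, onset = 26)
  expect_true(all(curveValues(lateOnset) == 0))
  expect_error(makeAif(c(0, 2, 2, 4), 1, 1), "strictly increasing")
  expect_error(makeAif(times, 1, onset = 40), "time range")
  expect_error(makeAif(times, 1, onset = 6, alpha = -1), "positive")
})

test_that("fBm field is deterministic, normalized and smoother for higher H", {
  f1 <- makeFbmField(c(16, 16, 8), 0.5, seed = 42)
  f2 <- makeFbmField(c(16, 16, 8), 0.5, seed = 42)
  expect_identical(f1, f2)
  expect_equal(mean(f1), 0, tolerance = 1e-12)
  expect_equal(stats::var(as.vector(f1)), 1, tolerance = 1e-6)
  expect_error(makeFbmField(c(16, 16, 8), 1.2), "hurst")

  rougher <- 0
  for (s in 1:20) {
    lo <- makeFbmField(c(24, 24, 8), 0.2, seed = s)
    hi <- makeFbmField(c(24, 24, 8), 0.8, seed = s)
    d1 <- mean(abs(lo[-1, , ] - lo[-24, , ]))
    d2 <- mean(abs(hi[-1, , ] - hi[-24, , ]))
    rougher <- rougher + (d1 > d2)
  }
  expect_gte(rougher, 19)
})

test_that("phantom synthesis is deterministic and labels are consistent", {
  spec <- smallSpec(regime = "micro", seed = 3)
  b1 <- synthesizePhantom(spec)
  b2 <- synthesizePhantom(spec)
  expect_identical(imageData(b1), imageData(b2))
  expect_identical(phantomTruth(b1), phantomTruth(b2))
  # truth defined exactly on the mask, AIF ROI disjoint
  expect_true(all(!is.na(phantomTruth(b1)[phantomMask(b1)])))
  expect_true(all(is.na(phantomTruth(b1)[!phantomMask(b1)])))
  expect_false(any(phantomMask(b1) & phantomAifRoi(b1)))
})

test_that("regime none gives all-normal labels and enhancement above baseline", {
  b <- synthesizePhantom(smallSpec(regime = "none", seed = 7,
                                   noiseSigma = 0))
  expect_true(all(phantomTruth(b)[phantomMask(b)] == 0L))
  expect_true(all(phantomSegmentTruth(b)$truthClass == "normal"))
  dat <- imageData(b)
  nt <- dim(dat)[4]
  peak <- apply(dat, 1:3, max)
  base <- dat[, , , 1]
  expect_true(all(peak[phantomMask(b)] > base[phantomMask(b)]))
})

test_that("macro lesion is one 4-connected transmural angular sector", {
  b <- synthesizePhantom(smallSpec(regime = "macro", seed = 5))
  les <- !is.na(phantomTruth(b)) & phantomTruth(b) == 2L
  expect_true(any(les))
  expect_equal(connectedComponents3d(les), 1L)
  # transmural: lesion spans the full wall thickness in lesion slices
  spec <- b@spec
  g <- expand.grid(x = seq_len(dim(les)[1]), y = seq_len(dim(les)[2]))
  rad <- sqrt((g$x - spec$center[1])^2 + (g$y - spec$center[2])^2)
  z1 <- which(apply(les, 3, any))[1]
  radLes <- rad[as.vector(les[, , z1])]
  expect_lt(min(radLes), spec$innerRadius + 1.5)
  expect_gt(max(radLes), spec$outerRadius - 1.5)
})

test_that("micro lesion stays subendocardial and forms several patches", {
  b <- synthesizePhantom(phantomSpec(regime = "micro", seed = 11))
  les <- !is.na(phantomTruth(b)) & phantomTruth(b) == 1L
  spec <- b@spec
  g <- expand.grid(x = seq_len(dim(les)[1]), y = seq_len(dim(les)[2]))
  rad <- array(sqrt((g$x - spec$center[1])^2 + (g$y - spec$center[2])^2),
               dim(les)[1:2])
  wallMax <- spec$innerRadius +
    spec$depthFraction * (spec$outerRadius - spec$innerRadius)
  for (z in seq_len(dim(les)[3]))
    if (any(les[, , z]))
      expect_lte(max(rad[les[, , z]]), wallMax + 1e-9)
  expect_gte(connectedComponents3d(les), 3L)
})

test_that("empty lesion rasterization is rejected with a geometry hint", {
  expect_error(
    synthesizePhantom(smallSpec(regime = "macro", territoryAngle = 1e-9)),
    "territoryAngle")
})

test_that("peak enhancement orders macro < micro < normal on shared seeds", {
  for (s in 1:3) {
    peaks <- sapply(c("none", "micro", "macro"), function(reg) {
      b <- synthesizePhantom(smallSpec(regime = reg, seed = s))
      lab <- phantomTruth(b)
      sel <- if (reg == "none") !is.na(lab) else !is.na(lab) & lab > 0L
      peak <- apply(imageData(b), 1:3, max)
      mean(peak[sel])
    })
    expect_lt(peaks["macro"], peaks["micro"])
    expect_lt(peaks["micro"], peaks["none"])
  }
})

test_that("AIF peak precedes the mean myocardial peak by at least one frame", {
  for (s in 1:3) {
    b <- synthesizePhantom(smallSpec(seed = s))
    aif <- extractAif(b@image, phantomAifRoi(b))
    myo <- colMeans(apply(imageData(b), 4, function(fr) fr[phantomMask(b)]))
    expect_lte(which.max(curveValues(aif)), which.max(myo) - 1L)
  }
})

test_that("phantom round-trips through NIfTI with spec sidecar", {
  b <- synthesizePhantom(smallSpec(seed = 2))
  dir <- withr::local_tempdir()
  paths <- writePhantom(b, dir)
  expect_true(all(file.exists(paths)))
  img <- suppressMessages(readDynamicVolume(paths["image"], quiet = TRUE))
  expect_equal(imageData(img), imageData(b), tolerance = 1e-6)
  expect_equal(frameTimes(img), frameTimes(phantomImage(b)))
  sidecar <- jsonlite::read_json(paths["spec"])
  expect_equal(sidecar$seed, 2)
  expect_equal(sidecar$regime, "none")
})
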