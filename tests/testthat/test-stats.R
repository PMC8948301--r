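test_that("threshold classification uses the <=-is-diseased convention", {
  cuts <- referenceCutoffs()
  expect_equal(as.character(classifyFd(c(4.26, 4.31, 4.49, 4.41, 4.35),
                                       cuts)),
               c("macro", "macro", "normal", "micro", "micro"))
  expect_equal(as.character(classifyMbf(c(68.2, 105.6, 138.1), cuts)),
               c("macro", "micro", "normal"))
  # step monotonicity: classes only get less diseased as the value grows
  x <- sort(runif(50, 4.0, 4.8))
  cls <- as.integer(factor(classifyFd(x, cuts),
                           levels = c("macro", "micro", "normal")))
  expect_true(all(diff(cls) >= 0))
  expect_error(cutoffSet(fdIschemia = 4.3, fdMacro = 4.4), "fdMacro")
})

test_that("vessel/patient aggregation follows the any-abnormal-segment rule", {
  agg <- aggregateToVesselPatient(1:17, rep("normal", 17))
  expect_equal(as.character(agg$patient), "normal")
  cls <- rep("normal", 17); cls[9] <- "macro"
  agg2 <- aggregateToVesselPatient(1:17, cls)
  expect_equal(as.character(agg2$patient), "macro")
  expect_equal(as.character(agg2$vessel["RCA"]), "macro")
  expect_equal(as.character(agg2$vessel["LAD"]), "normal")
  cls3 <- rep("normal", 17); cls3[c(2, 12)] <- "micro"
  expect_equal(as.character(aggregateToVesselPatient(1:17, cls3)$patient),
               "micro")
  # order independence
  o <- sample(17)
  expect_equal(aggregateToVesselPatient(o, cls3[o])$patient,
               aggregateToVesselPatient(1:17, cls3)$patient)
  expect_error(aggregateToVesselPatient(c(1, 18), c("normal", "macro")),
               "unmapped")
})

test_that("patient averaging eliminates per-segment clustering", {
  expect_equal(unname(patientAverage(c(4.2, 4.4), c("p1", "p1"))), 4.3)
  expect_equal(unname(patientAverage(5, "p9")), 5)
  pa <- patientAverage(c(1, 1, 3), c("a", "a", "b"))
  expect_equal(unname(pa[c("a", "b")]), c(1, 3))
})

test_that("optimal cutoffs recover a separating threshold and flag degenerate input", {
  set.seed(10)
  vals <- c(rnorm(20, 4.5, 0.01), rnorm(10, 4.35, 0.01),
            rnorm(10, 4.2, 0.01))
  labs <- rep(c("normal", "micro", "macro"), c(20, 10, 10))
  oc <- optimalCutoffs(vals, labs)
  expect_gt(oc$cutoffIschemia, max(vals[labs != "normal"]))
  expect_lt(oc$cutoffIschemia, min(vals[labs == "normal"]))
  expect_gt(oc$cutoffMacro, max(vals[labs == "macro"]))
  expect_lt(oc$cutoffMacro, min(vals[labs == "micro"]))
  expect_equal(oc$jIschemia, 1)
  expect_true(oc$reliable)
  # identical distributions: J near zero, flagged unreliable
  same <- optimalCutoffs(rep(c(4.3, 4.4), 20),
                         rep(c("normal", "micro"), 20))
  expect_lt(same$jIschemia, 0.2)
  expect_false(same$reliable)
  expect_error(optimalCutoffs(1:5, rep("normal", 5)), "single-class")
})

test_that("sensitivity/specificity carry exact Clopper-Pearson intervals", {
  ss <- sensSpec(tp = 10, fn = 0, fp = 3, tn = 17)
  expect_equal(ss["sensitivity", "estimate"], 1)
  expect_equal(ss["specificity", "estimate"], 0.85)
  expect_equal(ss["sensitivity", "lower"], 0.025^(1 / 10), tolerance = 1e-9)
  bt <- binom.test(17, 20)$conf.int
  expect_equal(unlist(ss["specificity", c("lower", "upper")]),
               c(lower = bt[1], upper = bt[2]), tolerance = 1e-9)
  one <- sensSpec(tp = 1, fn = 0, fp = 0, tn = 1)
  expect_equal(one$estimate, c(1, 1))
  expect_error(sensSpec(tp = -1, fn = 0, fp = 0, tn = 1), "non-negative")
})

test_that("Cohen's kappa matches hand-computed po/pe and brute-force tables", {
  k <- cohensKappa(rbind(c(93, 10), c(0, 113)))
  expect_equal(k$po, 206 / 216, tolerance = 1e-12)
  expect_equal(k$pe, 23478 / 46656, tolerance = 1e-12)
  expect_equal(k$kappa, 0.91, tolerance = 0.005)
  expect_equal(cohensKappa(diag(c(5, 8, 2)))$kappa, 1)
  expect_equal(cohensKappa(matrix(25, 2, 2))$kappa, 0)

  # brute-force counting oracle on random tables, both weightings
  set.seed(12)
  for (rep in 1:200) {
    k <- sample(2:6, 1)
    m <- matrix(rpois(k * k, 4), k, k)
    if (sum(m) == 0) next
    for (w in c("none", "quadratic")) {
      wts <- if (w == "none") diag(k) else
        1 - (outer(1:k, 1:k, `-`))^2 / (k - 1)^2
      po <- pe <- 0
      n <- sum(m)
      for (i in 1:k) for (j in 1:k) {
        po <- po + wts[i, j] * m[i, j] / n
        pe <- pe + wts[i, j] * sum(m[i, ]) * sum(m[, j]) / n^2
      }
      oracle <- (po - pe) / (1 - pe)
      expect_equal(cohensKappa(m, w)$kappa, oracle, tolerance = 1e-12)
    }
  }
})

test_that("quadratic weighting rewards near-diagonal agreement", {
  m <- rbind(c(10, 5, 0), c(5, 10, 5), c(0, 5, 10))
  expect_gt(cohensKappa(m, "quadratic")$kappa, cohensKappa(m, "none")$kappa)
})

test_that("McNemar test is exact on small discordant counts", {
  expect_equal(mcnemarTest(c(0, 0))$p, 1)
  expect_equal(mcnemarTest(c(12, 0))$p, 2 * 0.5^12, tolerance = 1e-12)
  expect_equal(mcnemarTest(c(3, 3))$p, 1)
  # vector interface
  a <- c(TRUE, TRUE, TRUE, FALSE)
  b <- c(TRUE, FALSE, FALSE, FALSE)
  r <- mcnemarTest(a, b)
  expect_equal(c(r$n10, r$n01), c(2, 0))
  # large discordant counts switch to the corrected chi-squared
  big <- mcnemarTest(c(30, 10))
  expect_equal(big$method, "chisq")
  expect_equal(big$p, mcnemar.test(rbind(c(0, 30), c(10, 0)))$p.value,
               tolerance = 1e-12)
})

test_that("Bland-Altman bias and limits of agreement", {
  a <- rnorm(50, 4.4, 0.1)
  r0 <- blandAltman(a, a)
  expect_equal(r0$bias, 0)
  expect_equal(r0$loa, c(0, 0))
  r1 <- blandAltman(a, a + 0.3)
  expect_equal(r1$bias, -0.3, tolerance = 1e-12)
  expect_equal(diff(r1$loa), 0, tolerance = 1e-12)
  set.seed(13)
  b <- a + rnorm(50, 0, 0.05)
  r2 <- blandAltman(a, b)
  expect_equal(unname(diff(r2$loa)) / 2, 1.96 * sd(a - b), tolerance = 1e-9)
})

test_that("Hand-Till multi-class AUC matches pair counting and is 0.5 under shuffling", {
  vals <- c(4.5, 4.4, 4.35, 4.2)
  labs <- c("normal", "normal", "micro", "macro")
  expect_equal(multiclassAuc(vals, labs), 1)

  set.seed(14)
  vals2 <- c(rnorm(10, 4.5, 0.05), rnorm(10, 4.35, 0.05),
             rnorm(10, 4.2, 0.05))
  labs2 <- rep(c("normal", "micro", "macro"), each = 10)
  # brute-force counting oracle over the three pairs
  oracle <- mean(c(
    countingAuc(vals2[labs2 == "normal"], vals2[labs2 == "micro"]),
    countingAuc(vals2[labs2 == "normal"], vals2[labs2 == "macro"]),
    countingAuc(vals2[labs2 == "micro"], vals2[labs2 == "macro"])))
  expect_equal(multiclassAuc(vals2, labs2), oracle, tolerance = 1e-12)

  perms <- replicate(100, multiclassAuc(vals2, sample(labs2)))
  expect_lt(abs(mean(perms) - 0.5), 0.05)
})

test_that("pairwise AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(15)
  x <- rnorm(40)
  g <- rep(c("macro", "normal"), each = 20)
  ours <- multiclassAuc(x, g, classOrder = c("macro", "normal"))
  ref <- suppressMessages(pROC::auc(pROC::roc(g, x, levels = c("macro", "normal"),
                                              direction = "<")))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("group tests: Kruskal-Wallis, exact Mann-Whitney floor, Bonferroni", {
  set.seed(16)
  same <- rnorm(30)
  g3 <- rep(c("a", "b", "c"), each = 10)
  r <- groupTests(same, g3)
  expect_gt(r$kruskalP, 0.05)
  expect_equal(r$pairwise$pAdjusted,
               pmin(1, r$pairwise$p * 3), tolerance = 1e-12)
  # fully separated groups of 10: the exact two-sided floor 2/C(20,10)
  sep <- c(1:10, 101:110)
  r2 <- groupTests(sep, rep(c("a", "b"), each = 10))
  expect_equal(r2$pairwise$p, 2 / choose(20, 10), tolerance = 1e-9)
})

test_that("balanced accuracy averages per-class recall", {
  expect_equal(balancedAccuracy(c("a", "a", "b"), c("a", "a", "b")), 1)
  expect_equal(balancedAccuracy(c("a", "b", "b", "b"),
                                c("a", "a", "b", "b")), 0.75)
})
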