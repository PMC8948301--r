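# Diagnostic-accuracy statistics: exact binomial CIs, Cohen's kappa
# (unweighted and quadratic-weighted) with asymptotic CI, exact McNemar,
# Bland-Altman, Hand-Till multi-class AUC and rank-based group tests.
# Standard machinery (binom.test, kruskal.test, wilcox.test, p.adjust)
# comes from base R; kappa and the multi-class AUC have no pre-packaged
# implementation here and are written out.

#' Sensitivity and specificity with exact confidence intervals
#'
#' @param tp,fn,fp,tn confusion counts; alternatively pass a 2x2 matrix
#'   \code{rbind(c(tp, fn), c(fp, tn))} as \code{tp}.
#' @param conf.level confidence level of the Clopper-Pearson intervals.
#' @return data.frame with rows "sensitivity" and "specificity", columns
#'   estimate, lower, upper (proportions in [0, 1]), k, n.
#' @export
sensSpec <- function(tp, fn = NULL, fp = NULL, tn = NULL,
                     conf.level = 0.95) {
  if (is.matrix(tp)) {
    m <- tp
    if (!all(dim(m) == 2)) stop("confusion matrix must be 2x2")
    tp <- m[1, 1]; fn <- m[1, 2]; fp <- m[2, 1]; tn <- m[2, 2]
  }
  counts <- c(tp, fn, fp, tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  one <- function(k, n) {
    bt <- stats::binom.test(k, n, conf.level = conf.level)
    c(estimate = k / n, lower = bt$conf.int[1], upper = bt$conf.int[2],
      k = k, n = n)
  }
  out <- rbind(sensitivity = one(tp, tp + fn),
               specificity = one(tn, tn + fp))
  as.data.frame(out)
}

#' Cohen's kappa (unweighted or quadratic-weighted) with asymptotic CI
#'
#' Chance-corrected agreement for a K x K cross-classification. Quadratic
#' weights score partial agreement by 1 - (i - j)^2 / (K - 1)^2. The
#' confidence interval uses the large-sample variance of the weighted
#' kappa (Fleiss, Cohen and Everitt).
#'
#' @param table K x K matrix of counts (rows: method/reader A, columns:
#'   B or truth).
#' @param weighting \code{"none"} or \code{"quadratic"}.
#' @param conf.level confidence level.
#' @return list with \code{kappa}, \code{se}, \code{lower}, \code{upper},
#'   \code{po}, \code{pe}, \code{n}.
#' @export
cohensKappa <- function(table, weighting = c("none", "quadratic"),
                        conf.level = 0.95) {
  weighting <- match.arg(weighting)
  m <- as.matrix(table)
  if (nrow(m) != ncol(m)) stop("table must be square")
  k <- nrow(m)
  n <- sum(m)
  if (n == 0) stop("empty table")
  p <- m / n
  w <- if (weighting == "quadratic" && k > 1) {
    1 - (outer(seq_len(k), seq_len(k), `-`))^2 / (k - 1)^2
  } else diag(k)
  pr <- rowSums(p)
  pc <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pr, pc))
  kap <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt asymptotic variance for weighted kappa
  wr <- as.vector(w %*% pc)       # row-wise expected weight
  wc <- as.vector(t(w) %*% pr)    # column-wise expected weight
  term <- (w - outer(wr, wc, `+`) * (1 - kap))^2
  varK <- (sum(p * term) - (kap - pe * (1 - kap))^2) / (n * (1 - pe)^2)
  se <- sqrt(max(varK, 0))
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  list(kappa = kap, se = se,
       lower = max(-1, kap - z * se), upper = min(1, kap + z * se),
       po = po, pe = pe, n = n)
}

#' McNemar test for paired diagnostic methods
#'
#' Compares two methods on the same cases via their discordant pairs. With
#' fewer than \code{exactMax} discordant pairs the exact binomial test is
#' used, otherwise the continuity-corrected chi-squared approximation. No
#' discordant pairs yields p = 1.
#'
#' @param correctA,correctB logical vectors (was each case classified
#'   correctly by method A / B); alternatively pass the two discordant
#'   counts directly as \code{correctA = c(n10, n01)}.
#' @param exactMax switch point between exact and asymptotic p.
#' @return list with \code{p}, \code{n10}, \code{n01}, \code{method}.
#' @export
mcnemarTest <- function(correctA, correctB = NULL, exactMax = 25) {
  if (is.null(correctB)) {
    if (length(correctA) != 2) stop("need discordant counts c(n10, n01)")
    n10 <- correctA[1]; n01 <- correctA[2]
  } else {
    if (length(correctA) != length(correctB)) stop("length mismatch")
    n10 <- sum(correctA & !correctB)
    n01 <- sum(!correctA & correctB)
  }
  nd <- n10 + n01
  if (nd == 0) return(list(p = 1, n10 = n10, n01 = n01, method = "exact"))
  if (nd < exactMax) {
    p <- stats::binom.test(n10, nd, 0.5)$p.value
    method <- "exact"
  } else {
    stat <- (abs(n10 - n01) - 1)^2 / nd
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chisq"
  }
  list(p = p, n10 = n10, n01 = n01, method = method)
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as reference minus comparison (\code{a - b}); the
#' limits of agreement are bias +/- 1.96 SD of the differences.
#'
#' @param a numeric, reference reader/method.
#' @param b numeric, comparison reader/method.
#' @return list with \code{bias}, \code{biasCi} (95\% CI of the bias),
#'   \code{loa} (lower, upper limits of agreement), \code{sd}, \code{n}.
#' @export
blandAltman <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  d <- a - b
  n <- length(d)
  bias <- mean(d)
  s <- stats::sd(d)
  if (is.na(s)) s <- 0
  se <- s / sqrt(n)
  list(bias = bias,
       biasCi = c(bias - 1.96 * se, bias + 1.96 * se),
       loa = c(bias - 1.96 * s, bias + 1.96 * s),
       sd = s, n = n)
}

# Pairwise AUC: probability that a value from the high class exceeds one
# from the low class (ties count 1/2), computed from ranks.
.pairAuc <- function(high, low) {
  r <- rank(c(high, low))
  nh <- length(high)
  nl <- length(low)
  (sum(r[seq_len(nh)]) - nh * (nh + 1) / 2) / (nh * nl)
}

#' Multi-class AUC (Hand-Till average of pairwise AUCs)
#'
#' For a single scalar marker and K ordered classes, the Hand-Till measure
#' is the unweighted mean over all class pairs of the two-class AUC. The
#' class ordering fixes the orientation: for each pair, the AUC is the
#' probability that a value from the class listed later in
#' \code{classOrder} exceeds a value from the earlier class. With the
#' default ordering (macro, micro, normal) this suits markers that
#' decrease with disease severity, such as FD and MBF.
#'
#' @param values numeric marker values.
#' @param labels class labels.
#' @param classOrder character, classes from lowest to highest expected
#'   marker value.
#' @return the multi-class AUC in [0, 1].
#' @export
multiclassAuc <- function(values, labels,
                          classOrder = c("macro", "micro", "normal")) {
  cls <- as.character(labels)
  if (!all(cls %in% classOrder)) stop("labels outside 'classOrder'")
  present <- classOrder[classOrder %in% cls]
  if (length(present) < 2) stop("need at least two classes")
  pairs <- utils::combn(seq_along(present), 2)
  aucs <- apply(pairs, 2, function(ij) {
    lowC <- present[ij[1]]; highC <- present[ij[2]]
    .pairAuc(values[cls == highC], values[cls == lowC])
  })
  mean(aucs)
}

#' Rank-based group comparisons
#'
#' Kruskal-Wallis test across all groups plus pairwise two-sided
#' Mann-Whitney U tests with Bonferroni adjustment, on per-patient values.
#'
#' @param values numeric values (one per patient).
#' @param groups group labels.
#' @return list with \code{kruskalP} and data.frame \code{pairwise}
#'   (groupA, groupB, p, pAdjusted).
#' @export
groupTests <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  kw <- stats::kruskal.test(values, groups)
  pairs <- utils::combn(levels(groups), 2)
  praw <- apply(pairs, 2, function(gg) {
    stats::wilcox.test(values[groups == gg[1]],
                       values[groups == gg[2]])$p.value
  })
  list(kruskalP = kw$p.value,
       pairwise = data.frame(groupA = pairs[1, ], groupB = pairs[2, ],
                             p = praw,
                             pAdjusted = stats::p.adjust(praw,
                                                         "bonferroni"),
                             stringsAsFactors = FALSE))
}

#' Balanced accuracy of a multi-class assignment
#'
#' Mean per-class recall; insensitive to class imbalance.
#'
#' @param predicted,truth class labels of equal length.
#' @return balanced accuracy in [0, 1].
#' @export
balancedAccuracy <- function(predicted, truth) {
  p <- as.character(predicted)
  t <- as.character(truth)
  if (length(p) != length(t)) stop("length mismatch")
  mean(vapply(unique(t), function(cl) mean(p[t == cl] == cl), numeric(1)))
}
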