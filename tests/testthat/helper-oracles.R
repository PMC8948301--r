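# Independent oracles used across the suite. These deliberately re-derive
# quantities with naive loops so they cannot share bugs with the
# vectorized implementations.

# Naive blanket iteration: explicit per-sample loop over the axis
# neighborhood (center + 2d axis neighbors), edge replication.
naiveBlanketStep <- function(u, b) {
  d <- dim(u)
  nd <- length(d)
  un <- u
  bn <- b
  idx <- as.matrix(expand.grid(lapply(d, seq_len)))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, ]
    nbMaxU <- u[matrix(i, 1)]
    nbMinB <- b[matrix(i, 1)]
    for (ax in seq_len(nd)) for (s in c(-1L, 1L)) {
      j <- i
      j[ax] <- min(max(j[ax] + s, 1L), d[ax])
      nbMaxU <- max(nbMaxU, u[matrix(j, 1)])
      nbMinB <- min(nbMinB, b[matrix(j, 1)])
    }
    un[matrix(i, 1)] <- max(u[matrix(i, 1)] + 1, nbMaxU)
    bn[matrix(i, 1)] <- min(b[matrix(i, 1)] - 1, nbMinB)
  }
  list(u = un, b = bn)
}

naiveHypervolume <- function(u, b, eps) sum(u - b) / (2 * eps)

# 6-connected components of a 3D logical array by label propagation.
connectedComponents3d <- function(m) {
  lab <- array(0L, dim(m))
  lab[m] <- seq_len(sum(m))
  shift1 <- function(x, axis, by) {
    d <- dim(x)
    idx <- lapply(d, seq_len)
    idx[[axis]] <- pmin(pmax(idx[[axis]] - by, 1L), d[axis])
    do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  }
  repeat {
    new <- lab
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      sh <- shift1(lab, ax, s)
      new <- pmax(new, ifelse(m & sh > 0, sh, 0L))
    }
    dim(new) <- dim(lab)
    if (all(new == lab)) break
    lab <- new
  }
  length(unique(lab[m]))
}

# Small phantom spec used where full desk scale is unnecessary.
smallSpec <- function(...) {
  phantomSpec(shape = c(32, 32, 8, 12), innerRadius = 5, outerRadius = 8,
              ...)
}

# Brute-force pairwise AUC by counting all pairs.
countingAuc <- function(high, low) {
  s <- 0
  for (h in high) for (l in low) s <- s + (h > l) + 0.5 * (h == l)
  s / (length(high) * length(low))
}
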