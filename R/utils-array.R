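# Array helpers shared by the blanket, filtering and phantom code.
# All operate in index space; edge handling is replication unless noted.

# Shift an n-d array along one axis by `by` voxels, replicating edges.
# by > 0 brings the value at position i - by to position i.
shiftArray <- function(x, axis, by) {
  d <- dim(x)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- pmin(pmax(idx[[axis]] - by, 1L), d[axis])
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Separable convolution along one axis with a 1D kernel (edge replication).
convolveAxis <- function(x, axis, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim(x))
  for (k in seq_along(kernel))
    out <- out + kernel[k] * shiftArray(x, axis, k - r - 1L)
  out
}

# Isotropic Gaussian blur of a 3D array, separable, kernel cut at 3 sigma.
gaussianBlur3d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  for (axis in 1:3) x <- convolveAxis(x, axis, k)
  x
}

# Cumulative sum along one axis of an n-d array.
cumsumAxis <- function(x, axis) {
  d <- dim(x)
  perm <- c(axis, seq_along(d)[-axis])
  xp <- aperm(x, perm)
  dp <- dim(xp)
  dim(xp) <- c(dp[1], prod(dp[-1]))
  xp <- apply(xp, 2, cumsum)
  dim(xp) <- dp
  aperm(xp, order(perm))
}

# Sum of x over a centered cube of half-width r, per 3D voxel.
# Positions whose window is not fully inside the grid get NA (marked after
# all three passes so partial sums at borders never contaminate the
# integral images).
boxSum3d <- function(x, r) {
  d <- dim(x)
  idxAll <- lapply(d, seq_len)
  lin <- array(seq_len(prod(d)), d)
  for (axis in 1:3) {
    cs <- cumsumAxis(x, axis)
    n <- d[axis]
    idxHi <- idxAll; idxHi[[axis]] <- pmin(seq_len(n) + r, n)
    top <- do.call(`[`, c(list(cs), idxHi, list(drop = FALSE)))
    lo <- seq_len(n) - r - 1L
    idxLo <- idxAll; idxLo[[axis]] <- pmax(lo, 1L)
    bottom <- do.call(`[`, c(list(cs), idxLo, list(drop = FALSE)))
    if (any(lo < 1L)) {
      idxZ <- idxAll; idxZ[[axis]] <- which(lo < 1L)
      bottom[as.vector(do.call(`[`, c(list(lin), idxZ,
                                      list(drop = FALSE))))] <- 0
    }
    x <- top - bottom
  }
  for (axis in 1:3) {
    n <- d[axis]
    bad <- which(seq_len(n) <= r | seq_len(n) > n - r)
    if (length(bad)) {
      idxB <- idxAll; idxB[[axis]] <- bad
      x[as.vector(do.call(`[`, c(list(lin), idxB,
                                 list(drop = FALSE))))] <- NA_real_
    }
  }
  x
}

# Voxel-coordinate grids for a 3D shape (1-based indices).
coordGrid3d <- function(d) {
  list(x = array(rep(seq_len(d[1]), times = d[2] * d[3]), d),
       y = array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d),
       z = array(rep(seq_len(d[3]), each = d[1] * d[2]), d))
}

# Normalize an angle in degrees to [0, 360).
normDeg <- function(a) ((a %% 360) + 360) %% 360
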