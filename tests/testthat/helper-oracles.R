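# Independent oracles used to check the package's numerics. Each is a
# deliberately different code path from the implementation it guards.

# dense least-squares via the normal equations (implementation uses SVD)
lsq_oracle <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# classical pooled two-sample t for the arc (i, j] against its complement,
# unit weights; plain R arithmetic on explicit index sets
arc_t_oracle <- function(v, i, j) {
  n <- length(v)
  a <- v[(i + 1):j]
  b <- v[setdiff(seq_len(n), (i + 1):j)]
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n - 2)
  abs(mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# exhaustive arc enumeration; ties toward smaller i then smaller j
brute_max_arc <- function(v, min_len = 1) {
  n <- length(v)
  best <- list(i = 0, j = min_len, T = -Inf)
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      len <- j - i
      if (len < min_len || len > n - min_len) next
      T <- arc_t_oracle(v, i, j)
      if (is.finite(T) && T > best$T + 1e-12) best <- list(i = i, j = j, T = T)
    }
  }
  best
}

# brute-force grid search for the baseline centering factor
baseline_grid_oracle <- function(v, bound = 1, step = 1e-4) {
  grid <- seq(-bound, bound, by = step)
  f <- vapply(grid, function(s) median(abs(v - s)), numeric(1))
  list(s = grid[which.min(f)], f = min(f))
}

# independent recursive unweighted CBS used as segmentation reference on
# small arms: brute-force max arc plus its own permutation loop
reference_cbs <- function(v, alpha = 0.01, n_perm = 500, min_width = 2) {
  breaks <- integer(0)
  recurse <- function(lo, hi) {
    len <- hi - lo + 1
    if (len < 2 * min_width) return(invisible(NULL))
    vv <- v[lo:hi]
    obs <- brute_max_arc(vv, min_width)
    if (!is.finite(obs$T) || obs$T <= 0) return(invisible(NULL))
    exceed <- 0
    for (p in seq_len(n_perm)) {
      exceed <- exceed + (brute_max_arc(sample(vv), min_width)$T >= obs$T - 1e-12)
    }
    if ((1 + exceed) / (1 + n_perm) >= alpha) return(invisible(NULL))
    i <- obs$i; j <- obs$j
    if (i > 0) breaks <<- c(breaks, lo - 1 + i)
    if (j < len) breaks <<- c(breaks, lo - 1 + j)
    if (i > 0) recurse(lo, lo - 1 + i)
    recurse(lo + i, lo - 1 + j)
    if (j < len) recurse(lo + j, hi)
  }
  recurse(1, length(v))
  sort(unique(breaks))
}

# breakpoints (indices between adjacent bins) of a segment table restricted
# to one arm, expressed in arm-local bin indices
segment_breaks <- function(st, bp, chrom, arm) {
  rows <- which(bp$chrom == chrom & bp$arm == arm)
  seg <- st[st$chrom == chrom & st$arm == arm, , drop = FALSE]
  ends <- sort(seg$end)
  ends <- ends[-length(ends)]
  match(ends, bp$end[rows])
}
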