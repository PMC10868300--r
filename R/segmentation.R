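#' Maximal circular arc statistic
#'
#' Treats the value vector as a circle and finds the arc `(i, j]` (bins
#' `i+1 .. j`) that maximizes the absolute weighted two-sample t-like
#' statistic between the arc and its complement: weighted means on both
#' sides, pooled weighted residual variance with `n - 2` degrees of
#' freedom. With unit weights this is the classical pooled two-sample t.
#' Wrapping arcs are complements of non-wrapping ones and share the same
#' statistic, so boundaries satisfy `0 <= i < j <= n`. Ties are broken
#' toward the smaller `i`, then the smaller `j`.
#'
#' @param values Numeric vector (length >= 2) of bin values.
#' @param weights Positive weights, same length.
#' @param min_len Minimum number of bins on each side of the split
#'   (default 1).
#' @return List with `i`, `j` (arc boundaries) and `T` (the statistic; 0
#'   when all values are identical).
#' @export
circular_max_stat <- function(values, weights = rep(1, length(values)), min_len = 1) {
  if (any(weights <= 0)) mc_stop("circular_max_stat: weights must be positive")
  cbs_max_stat_cpp(as.numeric(values), as.numeric(weights), as.integer(min_len))
}

#' Permutation p-value of the maximal arc statistic
#'
#' Values and weights are permuted jointly (pairs kept together); the
#' p-value uses the add-one rule
#' `p = (1 + #permutation max statistics >= T_obs) / (1 + n_perm)`, so it
#' is never exactly zero and equals 1 for constant input. Reproducible
#' bit-exactly for a fixed seed.
#'
#' @inheritParams circular_max_stat
#' @param T_obs Observed statistic from [circular_max_stat()] on the same
#'   data.
#' @param n_perm Number of permutations (default 10000; below 100 a
#'   warning is issued).
#' @param seed Optional integer seed.
#' @return The permutation p-value.
#' @export
permutation_pvalue <- function(values, weights = rep(1, length(values)), T_obs,
                               n_perm = 10000, min_len = 1, seed = NULL) {
  if (n_perm < 100) mc_warn("permutation_pvalue: n_perm < 100 gives a coarse p-value")
  if (!is.null(seed)) set.seed(seed)
  res <- cbs_perm_count_cpp(as.numeric(values), as.numeric(weights), T_obs,
                            as.integer(n_perm), as.integer(min_len), 0L)
  (1 + res$count) / (1 + n_perm)
}

#' Weighted circular binary segmentation of a bin profile
#'
#' Each chromosome arm is segmented recursively: the maximal weighted arc
#' statistic is computed, its significance assessed by joint permutation of
#' (value, weight) pairs, and, while `p < alpha` and both resulting pieces
#' hold at least `min_width` bins, the arm is split at the arc boundaries
#' and the pieces are revisited. Inside the recursion the permutation loop
#' stops early once non-significance at `alpha` is certain; the split
#' decisions are identical to the full loop. Optionally, adjacent segments
#' whose weighted means differ by fewer than `undo_sd` pooled standard
#' errors are merged back after the recursion.
#'
#' @param bp A baseline-corrected, weighted `bin_profile`.
#' @param alpha Significance level for accepting a split (default 0.01).
#' @param n_perm Permutations per split test (default 10000).
#' @param min_width Minimum number of bins per resulting piece (default 2).
#' @param undo_sd Merge-back threshold in pooled standard errors; 0
#'   disables (default).
#' @param seed Optional integer seed governing all permutations.
#' @return A `segment_table` data frame: `sample`, `chrom`, `arm`, `start`,
#'   `end` (half-open on 1-based positions), `n_bins`, `n_probes`,
#'   `seg_mean` (weighted mean of member bin values).
#' @export
segment_profile <- function(bp, alpha = 0.01, n_perm = 10000, min_width = 2,
                            undo_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample_id <- attr(bp, "sample_id")
  if (is.null(sample_id)) sample_id <- "sample"
  arm_key <- paste(bp$chrom, bp$arm)
  out <- list()
  for (key in unique(arm_key)) {
    rows <- which(arm_key == key)
    segs <- segment_arm(bp$value[rows], bp$weight[rows], alpha, n_perm, min_width)
    if (undo_sd > 0) {
      segs <- undo_splits(segs, bp$value[rows], bp$weight[rows], undo_sd)
    }
    for (s in seq_len(nrow(segs))) {
      lo <- rows[segs$lo[s]]; hi <- rows[segs$hi[s]]
      idx <- rows[segs$lo[s]:segs$hi[s]]
      out[[length(out) + 1L]] <- data.frame(
        sample = sample_id, chrom = bp$chrom[lo], arm = bp$arm[lo],
        start = bp$start[lo], end = bp$end[hi],
        n_bins = length(idx), n_probes = sum(bp$n_probes[idx]),
        seg_mean = wmean(bp$value[idx], bp$weight[idx]),
        stringsAsFactors = FALSE)
    }
  }
  st <- do.call(rbind, out)
  rownames(st) <- NULL
  class(st) <- c("segment_table", "data.frame")
  st
}

# recursive splitting of one arm; returns data.frame(lo, hi) of bin index
# ranges (1-based, inclusive) in arm order
segment_arm <- function(v, w, alpha, n_perm, min_width) {
  n <- length(v)
  breaks <- integer(0)
  early <- ceiling(alpha * (1 + n_perm))
  recurse <- function(lo, hi) {
    len <- hi - lo + 1L
    if (len < max(2L, 2L * min_width)) return(invisible(NULL))
    vv <- v[lo:hi]; ww <- w[lo:hi]
    ms <- cbs_max_stat_cpp(vv, ww, as.integer(min_width))
    if (ms$T <= 0) return(invisible(NULL))
    pc <- cbs_perm_count_cpp(vv, ww, ms$T, as.integer(n_perm),
                             as.integer(min_width), as.integer(early))
    p <- (1 + pc$count) / (1 + n_perm)
    if (p >= alpha) return(invisible(NULL))
    i <- ms$i; j <- ms$j
    if (i > 0L) breaks <<- c(breaks, lo - 1L + i)
    if (j < len) breaks <<- c(breaks, lo - 1L + j)
    if (i > 0L) recurse(lo, lo - 1L + i)
    recurse(lo + i, lo - 1L + j)
    if (j < len) recurse(lo + j, hi)
    invisible(NULL)
  }
  recurse(1L, n)
  breaks <- sort(unique(breaks))
  lo <- c(1L, breaks + 1L)
  hi <- c(breaks, n)
  data.frame(lo = lo, hi = hi)
}

# merge back adjacent segments whose weighted means differ by fewer than
# undo_sd pooled standard errors
undo_splits <- function(segs, v, w, undo_sd) {
  repeat {
    if (nrow(segs) < 2L) return(segs)
    z <- rep(Inf, nrow(segs) - 1L)
    for (k in seq_len(nrow(segs) - 1L)) {
      a <- segs$lo[k]:segs$hi[k]; b <- segs$lo[k + 1L]:segs$hi[k + 1L]
      ma <- wmean(v[a], w[a]); mb <- wmean(v[b], w[b])
      Wa <- sum(w[a]); Wb <- sum(w[b])
      ss <- sum(w[a] * (v[a] - ma)^2) + sum(w[b] * (v[b] - mb)^2)
      df <- max(length(a) + length(b) - 2L, 1L)
      se <- sqrt(max(ss / df, 1e-300) * (1 / Wa + 1 / Wb))
      z[k] <- abs(ma - mb) / se
    }
    k <- which.min(z)
    if (z[k] >= undo_sd) return(segs)
    segs$hi[k] <- segs$hi[k + 1L]
    segs <- segs[-(k + 1L), , drop = FALSE]
  }
}
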