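#' Collapse probe-level log2-ratios into bin-level values
#'
#' The value of each genomic bin is the median log2-ratio of its member
#' probes; the per-bin unbiased sample variance of those probe ratios is
#' retained for inverse-variance weighting. Bin boundaries come from the
#' sample-independent [build_bins()] map, so bins are identical between
#' samples.
#'
#' @param profile A `normalized_profile` aligned to the manifest used to
#'   build `bins`.
#' @param bins A `bin_map`.
#' @return A `bin_profile` data frame with columns `chrom`, `arm`, `start`,
#'   `end`, `n_probes`, `value`, `variance` (NA for single-probe bins),
#'   `weight` (initialized to 1), and attributes `sample_id`, `shift` (0
#'   until [baseline_correct()] is applied).
#' @export
summarize_bins <- function(profile, bins) {
  idx <- match(bins$probe_id, profile$probe_id)
  if (anyNA(idx)) {
    mc_stop("summarize_bins: ", sum(is.na(idx)),
            " bin-map probe(s) missing from the profile; profile and bin map",
            " must come from the same manifest")
  }
  R <- profile$R[idx]
  nb <- nrow(bins$bins)
  f <- factor(bins$probe_bin, levels = seq_len(nb))
  value <- as.numeric(tapply(R, f, median))
  variance <- as.numeric(tapply(R, f, function(x) if (length(x) >= 2L) var(x) else NA_real_))
  if (anyNA(value)) mc_stop("summarize_bins: bin with zero member probes in map")
  bp <- bins$bins
  bp$value <- value
  bp$variance <- variance
  bp$weight <- 1
  attr(bp, "sample_id") <- attr(profile, "sample_id")
  attr(bp, "shift") <- 0
  class(bp) <- c("bin_profile", "data.frame")
  bp
}

# median absolute deviation of values about a candidate center
mad_about <- function(v, s) median(abs(v - s))

#' Baseline correction of a bin profile
#'
#' Determines the copy-number neutral level by shifting bin values by the
#' centering factor `s*` that minimizes the median absolute deviation to
#' zero, searched within `[-search_bound, +search_bound]`. The objective
#' `median(|value - s|)` is piecewise linear in `s` with kinks only at bin
#' values and midpoints of bin-value pairs, so the minimizer is found
#' exactly by evaluating those candidates (profiles with more than
#' `exact_limit` bins fall back to a fine two-stage grid). Ties prefer the
#' smallest `|s|`, which makes the operation exactly idempotent.
#'
#' @param bp A `bin_profile`.
#' @param search_bound Half-width of the search interval (default 1.0
#'   log2 units).
#' @param exact_limit Maximum number of bins for the exact candidate
#'   search (default 1500).
#' @return The corrected `bin_profile`; the applied shift accumulates in
#'   `attr(bp, "shift")` so that `value_corrected = value_raw - shift`.
#' @export
baseline_correct <- function(bp, search_bound = 1.0, exact_limit = 1500) {
  v <- bp$value
  n <- length(v)
  if (n < 1L) mc_stop("baseline_correct: empty bin profile")
  b <- abs(search_bound)
  if (n <= exact_limit) {
    sv <- sort(v)
    # the objective's kinks sit at bin values and at midpoints of pairs
    # whose rank distance straddles the median index of the n distances
    h1 <- (n + 1L) %/% 2L
    h2 <- n %/% 2L + 1L
    ks <- unique(pmax(1L, c(h1 - 1L, h1, h1 + 1L, h2, h2 + 1L)))
    ks <- ks[ks <= n - 1L]
    mids <- unlist(lapply(ks, function(k) {
      i <- seq_len(n - k)
      (sv[i] + sv[i + k]) / 2
    }))
    cand <- unique(pmin(pmax(c(sv, mids), -b), b))
    cand <- unique(c(cand, 0, -b, b))
  } else {
    coarse <- seq(-b, b, by = 1e-3)
    f_coarse <- vapply(coarse, mad_about, numeric(1), v = v)
    s0 <- coarse[which.min(f_coarse)]
    cand <- unique(pmin(pmax(seq(s0 - 2e-3, s0 + 2e-3, by = 1e-5), -b), b))
    cand <- unique(c(cand, 0))
  }
  fval <- vapply(cand, mad_about, numeric(1), v = v)
  best <- fval <= min(fval) + 1e-12
  cb <- cand[best]
  s_star <- cb[order(abs(cb), cb)][1L]
  bp$value <- bp$value - s_star
  attr(bp, "shift") <- attr(bp, "shift") + s_star
  bp
}

#' Inverse-variance bin weights
#'
#' Bins with high within-bin probe variance carry less information about
#' the underlying copy-number level; segmentation therefore weights each
#' bin by the reciprocal of its probe variance, floored at `min_variance`
#' so near-constant bins cannot dominate. Single-probe bins (undefined
#' variance) receive the weight implied by the profile's median bin
#' variance.
#'
#' @param bp A `bin_profile` from [summarize_bins()].
#' @param min_variance Variance floor (default 1e-4).
#' @param variance Optional replacement variance vector (same length as
#'   bins), e.g. computed from the control panel via
#'   [bin_variance_from_controls()].
#' @return The `bin_profile` with its `weight` column set.
#' @export
bin_weights <- function(bp, min_variance = 1e-4, variance = NULL) {
  v <- if (is.null(variance)) bp$variance else variance
  if (length(v) != nrow(bp)) mc_stop("bin_weights: variance length mismatch")
  med <- median(v, na.rm = TRUE)
  if (is.na(med)) med <- min_variance
  v[is.na(v)] <- med
  bp$weight <- 1 / pmax(v, min_variance)
  bp
}

#' Per-bin probe variance estimated from the control panel
#'
#' Alternative weight source: each control is referenced against the mean
#' of the remaining panel in log2 space, and the per-bin variance pools the
#' resulting normalized probe values across all controls.
#'
#' @param controls Combined intensity matrix (probes x controls) aligned to
#'   the manifest underlying `bins`.
#' @param bins A `bin_map`.
#' @param floor Intensity floor before log2 (default 1).
#' @return Numeric vector of per-bin variances (NA where undefined).
#' @export
bin_variance_from_controls <- function(controls, bins, floor = 1) {
  X <- log2(pmax(as.matrix(controls), floor))
  centered <- X - rowMeans(X)
  nb <- nrow(bins$bins)
  f <- factor(rep(bins$probe_bin, ncol(centered)), levels = seq_len(nb))
  vals <- as.vector(centered)
  as.numeric(tapply(vals, f, function(x) if (length(x) >= 2L) var(x) else NA_real_))
}

#' Write a bin profile as TSV (1-based inclusive coordinates)
#'
#' Columns: `chrom  start  end  n_probes  value  variance  weight`.
#'
#' @param bp A `bin_profile`.
#' @param path Output path.
#' @export
write_bin_profile <- function(bp, path) {
  out <- data.frame(chrom = bp$chrom, start = bp$start, end = bp$end - 1,
                    n_probes = bp$n_probes,
                    value = round(bp$value, 6), variance = round(bp$variance, 6),
                    weight = round(bp$weight, 6))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
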