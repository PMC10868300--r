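#' Assign a copy-number state to each bin
#'
#' One-dimensional k-means with k = 3 on the baseline-corrected bin values.
#' Centers are initialized deterministically at the 10th/50th/90th
#' percentiles and refined by Lloyd iterations, so the assignment does not
#' depend on the random seed. The cluster with the lowest center is `loss`,
#' the highest `gain`, the middle `balanced`. With fewer than 3 distinct
#' bin values the assignment degenerates to all-`balanced` with a warning.
#'
#' @param bp A baseline-corrected `bin_profile`.
#' @param seed Unused; present for call-signature symmetry with the
#'   bootstrap sampler (initialization is deterministic).
#' @return A `state_assignment`: list with `state` (character per bin:
#'   `loss`/`balanced`/`gain`) and `centers` (3 ascending reals, NA in the
#'   degenerate case).
#' @export
assign_states <- function(bp, seed = NULL) {
  v <- bp$value
  degenerate <- length(unique(v)) < 3L
  if (!degenerate) {
    init <- unname(quantile(v, c(0.1, 0.5, 0.9), type = 7))
    degenerate <- length(unique(init)) < 3L
  }
  if (degenerate) {
    mc_warn("assign_states: fewer than 3 distinct bin values/centers; ",
            "all bins set to 'balanced'")
    return(structure(list(state = rep("balanced", length(v)),
                          centers = rep(NA_real_, 3)),
                     class = "state_assignment"))
  }
  km <- suppressWarnings(stats::kmeans(matrix(v, ncol = 1),
                                       centers = matrix(init, ncol = 1),
                                       iter.max = 200, algorithm = "Lloyd"))
  ord <- order(km$centers[, 1])
  labels <- c("loss", "balanced", "gain")[order(ord)]
  structure(list(state = labels[km$cluster],
                 centers = unname(sort(km$centers[, 1]))),
            class = "state_assignment")
}

#' Segmented block bootstrap of a bin profile
#'
#' Builds a sample-specific null distribution of bin values that preserves
#' both the local autocorrelation and the copy-number state structure of
#' the profile. In every iteration, each maximal same-state run of bins (in
#' genomic order, within chromosome arms) is reconstructed by concatenating
#' blocks of `block_length` bases drawn uniformly with replacement from all
#' genome-wide windows whose bins carry that state, trimmed to the run's
#' original bin count. Values pooled over all iterations form the null.
#'
#' @param bp A baseline-corrected `bin_profile`.
#' @param states A `state_assignment` aligned to `bp`.
#' @param block_length Source block length in bases (default 500 kb).
#' @param iterations Number of bootstrap iterations (default 100).
#' @param seed Optional integer seed for the block sampler.
#' @return A `bootstrap_null`: list with `pool` (all resampled values),
#'   `sequences` (bins x iterations matrix), `iterations`, `block_length`,
#'   `seed`.
#' @export
block_bootstrap <- function(bp, states, block_length = 500000, iterations = 100,
                            seed = NULL) {
  if (length(states$state) != nrow(bp)) mc_stop("block_bootstrap: state/bin mismatch")
  if (!is.null(seed)) set.seed(seed)
  v <- bp$value
  arm_key <- paste(bp$chrom, bp$arm)
  run_id <- cumsum(c(TRUE, states$state[-1] != states$state[-length(v)] |
                       arm_key[-1] != arm_key[-length(v)]))
  runs <- split(seq_along(v), run_id)
  run_state <- vapply(runs, function(ix) states$state[ix[1L]], character(1))
  # candidate source blocks: each run tiled into block_length windows
  blocks <- list(loss = list(), balanced = list(), gain = list())
  for (r in seq_along(runs)) {
    ix <- runs[[r]]
    offs <- floor((bp$start[ix] - bp$start[ix[1L]]) / block_length)
    for (g in split(ix, offs)) {
      blocks[[run_state[r]]][[length(blocks[[run_state[r]]]) + 1L]] <- v[g]
    }
  }
  n_blocks <- vapply(blocks, length, integer(1))
  seqs <- matrix(NA_real_, nrow = length(v), ncol = iterations)
  for (it in seq_len(iterations)) {
    for (r in seq_along(runs)) {
      ix <- runs[[r]]
      st <- run_state[r]
      if (n_blocks[[st]] == 0L) {
        mc_warn("block_bootstrap: no source blocks in state '", st,
                "'; resampling from 'balanced'")
        st <- "balanced"
      }
      pool <- blocks[[st]]
      need <- length(ix)
      got <- numeric(0)
      while (length(got) < need) {
        got <- c(got, pool[[sample.int(length(pool), 1L)]])
      }
      seqs[ix, it] <- got[seq_len(need)]
    }
  }
  structure(list(pool = as.vector(seqs), sequences = seqs,
                 iterations = iterations, block_length = block_length,
                 seed = seed),
            class = "bootstrap_null")
}

#' Sample-specific amplification and deletion thresholds
#'
#' Two-sided confidence bounds of the pooled bootstrap distribution:
#' the deletion threshold is its `tail` quantile and the amplification
#' threshold its `1 - tail` quantile. A noisier profile yields a wider
#' interval, which is what makes the thresholds sample-specific.
#'
#' @param null A `bootstrap_null`.
#' @param tail One-sided tail probability in (0, 0.5); default 0.005
#'   (99\% two-sided interval).
#' @return List with `del_thr` and `amp_thr`.
#' @export
derive_thresholds <- function(null, tail = 0.005) {
  if (!is.numeric(tail) || tail <= 0 || tail >= 0.5) {
    mc_stop("derive_thresholds: tail must be in (0, 0.5)")
  }
  q <- unname(quantile(null$pool, c(tail, 1 - tail), type = 7))
  list(del_thr = q[1L], amp_thr = q[2L])
}

#' Gene-level log2-ratio values
#'
#' The value of a gene is the median normalized log2-ratio of probes whose
#' position lies inside the gene interval (1-based inclusive; a probe
#' exactly at the start or end coordinate counts). Genes with no
#' overlapping probes are excluded with a logged count.
#'
#' @param profile A `normalized_profile`.
#' @param genes A `gene_annotation`.
#' @return Data frame `symbol`, `chrom`, `start`, `end`, `category`,
#'   `n_probes`, `value`, one row per gene with at least one probe.
#' @export
gene_values <- function(profile, genes) {
  pr <- GenomicRanges::GRanges(profile$chrom,
                               IRanges::IRanges(profile$pos, profile$pos))
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(gr, pr)
  med <- tapply(profile$R[S4Vectors::subjectHits(hits)],
                factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(genes))),
                median)
  n <- tapply(rep(1L, length(hits)),
              factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(genes))),
              sum)
  out <- data.frame(symbol = genes$symbol, chrom = genes$chrom,
                    start = genes$start, end = genes$end,
                    category = genes$category,
                    n_probes = as.integer(ifelse(is.na(n), 0L, n)),
                    value = as.numeric(med),
                    stringsAsFactors = FALSE)
  dropped <- sum(out$n_probes == 0L)
  if (dropped > 0) mc_msg("gene_values: ", dropped, " gene(s) without overlapping probes")
  out[out$n_probes > 0L, , drop = FALSE]
}

#' Call focal amplifications and deletions on genes
#'
#' A gene is called a deletion if its value lies strictly below the
#' deletion threshold and an amplification if strictly above the
#' amplification threshold. The empirical p-value is the add-one one-sided
#' tail of the pooled bootstrap distribution on the side of the gene's
#' deviation from the pool median, so it is never exactly zero.
#'
#' @param values Gene-value table from [gene_values()].
#' @param null A `bootstrap_null`.
#' @param tail Tail probability passed to [derive_thresholds()]
#'   (default 0.005).
#' @return A `focal_calls` data frame: gene columns plus `direction`
#'   (`amplification`/`deletion`/`none`), `p_empirical`, `significant`,
#'   `del_thr`, `amp_thr`.
#' @export
call_focal <- function(values, null, tail = 0.005) {
  thr <- derive_thresholds(null, tail)
  pool <- null$pool
  n <- length(pool)
  center <- median(pool)
  p_lo <- (1 + vapply(values$value, function(x) sum(pool <= x), numeric(1))) / (1 + n)
  p_hi <- (1 + vapply(values$value, function(x) sum(pool >= x), numeric(1))) / (1 + n)
  out <- values
  out$direction <- ifelse(values$value < thr$del_thr, "deletion",
                          ifelse(values$value > thr$amp_thr, "amplification", "none"))
  out$p_empirical <- ifelse(values$value < center, p_lo, p_hi)
  out$significant <- out$direction != "none"
  out$del_thr <- thr$del_thr
  out$amp_thr <- thr$amp_thr
  class(out) <- c("focal_calls", "data.frame")
  out
}

#' Write focal calls as TSV
#'
#' @param calls A `focal_calls` table.
#' @param path Output path.
#' @export
write_focal <- function(calls, path) {
  out <- as.data.frame(calls)
  out$value <- round(out$value, 4)
  out$p_empirical <- signif(out$p_empirical, 6)
  out$del_thr <- round(out$del_thr, 4)
  out$amp_thr <- round(out$amp_thr, 4)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
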