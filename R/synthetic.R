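#' Simulation configuration
#'
#' Defines the synthetic study conditions: a small genome, clustered probe
#' placement mimicking CpG-island density, a control panel of the
#' recommended size, a shared low-rank technical-bias structure (the
#' signal tangent normalization is designed to remove), multiplicative
#' lognormal measurement noise, and a list of copy-number events.
#'
#' @param n_chrom Number of chromosomes (default 2).
#' @param chrom_length Length of each chromosome in bases (default 10 Mb).
#' @param n_probes Total probe count (default 4000).
#' @param cluster_factor Fraction of probes placed in dense clusters
#'   rather than uniformly (default 0.5; 0 gives uniform placement).
#' @param n_controls Control-panel size (default 20, honoring the >= 16
#'   recommendation).
#' @param n_queries Number of query samples (default 3).
#' @param n_factors Number of latent technical factors shared between
#'   queries and controls (default 3).
#' @param factor_scale Standard deviation of the per-sample factor
#'   loadings (default 0.3, log-intensity units).
#' @param noise_sigma Lognormal measurement noise sigma (default 0.25).
#' @param mean_intensity Median combined intensity of a neutral probe
#'   (default 2000 fluorescence units).
#' @param cnvs Data frame of events: columns `query` (1-based query
#'   index), `chrom`, `start`, `end` (1-based inclusive), `cn` (integer
#'   copy state; 2 = neutral, 0 = homozygous deletion).
#' @param seed Integer seed; the generator is bit-reproducible per seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chrom = 2, chrom_length = 10e6, n_probes = 4000,
                       cluster_factor = 0.5, n_controls = 20, n_queries = 3,
                       n_factors = 3, factor_scale = 0.3, noise_sigma = 0.25,
                       mean_intensity = 2000, cnvs = NULL, seed = 1) {
  cfg <- list(n_chrom = n_chrom, chrom_length = chrom_length,
              n_probes = n_probes, cluster_factor = cluster_factor,
              n_controls = n_controls, n_queries = n_queries,
              n_factors = n_factors, factor_scale = factor_scale,
              noise_sigma = noise_sigma, mean_intensity = mean_intensity,
              cnvs = cnvs, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a probe manifest and genome assembly
#'
#' Chromosomes carry a centromere over the central 10% of their length.
#' Probe positions mix a uniform background with dense clusters (cluster
#' centers uniform, spread ~20 kb), rejected out of the centromere, so
#' probe density varies the way CpG-island-centric array designs do.
#'
#' @param cfg A [sim_config()].
#' @return List with `manifest` (a `probe_manifest`) and `genome`
#'   (a [genome_assembly()]).
#' @export
simulate_manifest <- function(cfg) {
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  L <- rep_len(cfg$chrom_length, cfg$n_chrom)
  genome <- genome_assembly(chroms, L,
                            cen_start = floor(0.45 * L),
                            cen_end = floor(0.55 * L))
  per <- rep(cfg$n_probes %/% cfg$n_chrom, cfg$n_chrom)
  per[seq_len(cfg$n_probes %% cfg$n_chrom)] <- per[seq_len(cfg$n_probes %% cfg$n_chrom)] + 1L
  rows <- list()
  for (k in seq_len(cfg$n_chrom)) {
    n <- per[k]
    n_clustered <- round(cfg$cluster_factor * n)
    n_centers <- max(1L, round(n_clustered / 25))
    centers <- runif(n_centers, 1, L[k])
    pos <- numeric(0)
    while (length(pos) < n) {
      need <- n - length(pos)
      u <- runif(need)
      cand <- ifelse(u < cfg$cluster_factor,
                     centers[sample.int(n_centers, need, replace = TRUE)] +
                       rnorm(need, 0, 20000),
                     runif(need, 1, L[k]))
      cand <- round(cand)
      ok <- cand >= 1 & cand <= L[k] &
        !(cand >= genome$cen_start[k] & cand <= genome$cen_end[k])
      pos <- c(pos, cand[ok])
    }
    rows[[k]] <- data.frame(chrom = chroms[k], pos = sort(pos[seq_len(n)]),
                            stringsAsFactors = FALSE)
  }
  m <- do.call(rbind, rows)
  m <- data.frame(probe_id = sprintf("cg%06d", seq_len(nrow(m))),
                  chrom = m$chrom, pos = m$pos,
                  type = sample(c("I", "II"), nrow(m), replace = TRUE,
                                prob = c(0.3, 0.7)),
                  excluded = FALSE, stringsAsFactors = FALSE)
  class(m) <- c("probe_manifest", "data.frame")
  attr(m, "genome") <- genome
  list(manifest = m, genome = genome)
}

#' Simulate a control panel and query samples with known ground truth
#'
#' Combined intensity of probe `i` in sample `s` is
#' `alpha_i * (CN_is / 2) * exp(F_i . lambda_s) * eps_is` with lognormal
#' probe affinities `alpha`, latent technical factor loadings `F` shared by
#' all samples, per-sample factor scores `lambda`, and lognormal noise
#' `eps`. Controls are copy-neutral everywhere; query copy states come from
#' `cfg$cnvs`. Homozygous deletions (`cn = 0`) use a residual factor of
#' 0.05 rather than 0, emulating background fluorescence and impurity.
#' The methylated/unmethylated split uses a per-probe beta-distributed
#' methylation fraction and is irrelevant downstream.
#'
#' @param cfg A [sim_config()].
#' @param manifest The manifest from [simulate_manifest()] (same config).
#' @return List with `controls` and `queries` (both `intensity_matrix`)
#'   and `truth` (list: `events` table, `probe_cn` probes x queries matrix
#'   of copy states).
#' @export
simulate_cohort <- function(cfg, manifest) {
  set.seed(cfg$seed + 1L)
  genome <- attr(manifest, "genome")
  p <- nrow(manifest)
  alpha <- rlnorm(p, meanlog = log(cfg$mean_intensity), sdlog = 0.6)
  Fmat <- matrix(rnorm(p * cfg$n_factors), nrow = p)
  n_all <- cfg$n_controls + cfg$n_queries
  lambda <- matrix(rnorm(n_all * cfg$n_factors, 0, cfg$factor_scale),
                   nrow = cfg$n_factors)
  beta <- rbeta(p, 0.5, 0.5)
  cn <- matrix(2, nrow = p, ncol = cfg$n_queries)
  if (!is.null(cfg$cnvs) && nrow(cfg$cnvs) > 0L) {
    ev <- cfg$cnvs
    stopifnot_cols(ev, c("query", "chrom", "start", "end", "cn"), "simulate_cohort")
    gi <- match(ev$chrom, genome$chrom)
    if (anyNA(gi) || any(ev$start < 1) || any(ev$end > genome$length[gi])) {
      mc_stop("simulate_cohort: event outside chromosome bounds")
    }
    for (e in seq_len(nrow(ev))) {
      hit <- manifest$chrom == ev$chrom[e] & manifest$pos >= ev$start[e] &
        manifest$pos <= ev$end[e]
      cn[hit, ev$query[e]] <- ev$cn[e]
    }
  }
  cn_factor <- function(x) ifelse(x == 0, 0.05, x / 2)
  make <- function(cols, cnmat) {
    I <- matrix(0, nrow = p, ncol = length(cols))
    for (jj in seq_along(cols)) {
      s <- cols[jj]
      eps <- exp(rnorm(p, 0, cfg$noise_sigma))
      I[, jj] <- alpha * cn_factor(cnmat[, jj]) *
        exp(drop(Fmat %*% lambda[, s])) * eps
    }
    I
  }
  cI <- make(seq_len(cfg$n_controls), matrix(2, p, cfg$n_controls))
  qI <- make(cfg$n_controls + seq_len(cfg$n_queries), cn)
  dimnames(cI) <- list(manifest$probe_id, sprintf("control%02d", seq_len(cfg$n_controls)))
  dimnames(qI) <- list(manifest$probe_id, sprintf("query%02d", seq_len(cfg$n_queries)))
  as_im <- function(I) {
    M <- I * beta; U <- I - M
    dimnames(M) <- dimnames(U) <- dimnames(I)
    structure(list(M = M, U = U, I = I), class = "intensity_matrix")
  }
  list(controls = as_im(cI), queries = as_im(qI),
       truth = list(events = cfg$cnvs, probe_cn = cn))
}

#' Expected log2-ratio of a copy state
#'
#' `log2(cn / 2)`, with the homozygous-deletion residual factor 0.05 for
#' `cn = 0` (matching the generator).
#'
#' @param cn Integer copy state vector.
#' @return Expected log2-ratios.
#' @export
expected_log2 <- function(cn) log2(ifelse(cn == 0, 0.05, cn / 2))

#' Evaluate calls against simulation ground truth
#'
#' Computes breakpoint recall/precision at a bin-index slack, the per-bin
#' gain/loss/balanced confusion matrix of segment means at fixed
#' thresholds, and (when focal calls are supplied) gene-level sensitivity
#' and specificity of focal calling for one query.
#'
#' @param truth Truth list from [simulate_cohort()].
#' @param query Query index the calls belong to.
#' @param segments A `segment_table` for that query.
#' @param bins The `bin_map` used.
#' @param manifest The simulated `probe_manifest`.
#' @param focal Optional `focal_calls` table.
#' @param match_slack Breakpoint matching slack in bins (default 1).
#' @param gain_thr,loss_thr Per-bin classification thresholds
#'   (defaults +/-0.1).
#' @return List with `breakpoint_recall`, `breakpoint_precision`,
#'   `bin_confusion` (3 x 3 true-state x called-state counts), and, with
#'   focal calls, `focal_sensitivity`, `focal_specificity`.
#' @export
evaluate_calls <- function(truth, query, segments, bins, manifest, focal = NULL,
                           match_slack = 1, gain_thr = 0.1, loss_thr = -0.1) {
  b <- bins$bins
  # per-bin true state from the probe-level copy states (majority)
  pid <- match(bins$probe_id, manifest$probe_id)
  cnp <- truth$probe_cn[pid, query]
  f <- factor(bins$probe_bin, levels = seq_len(nrow(b)))
  bin_cn <- as.numeric(tapply(cnp, f, function(x) as.numeric(names(sort(table(x),
                                                                        decreasing = TRUE))[1L])))
  true_lab <- ifelse(bin_cn > 2, "gain", ifelse(bin_cn < 2, "loss", "balanced"))
  # called per-bin value from covering segment mean
  called_val <- rep(NA_real_, nrow(b))
  for (s in seq_len(nrow(segments))) {
    cover <- b$chrom == segments$chrom[s] & b$start >= segments$start[s] &
      b$end <= segments$end[s]
    called_val[cover] <- segments$seg_mean[s]
  }
  called_lab <- ifelse(called_val > gain_thr, "gain",
                       ifelse(called_val < loss_thr, "loss", "balanced"))
  lv <- c("loss", "balanced", "gain")
  confusion <- table(true = factor(true_lab, lv), called = factor(called_lab, lv))
  # breakpoints as indices between adjacent bins of the same arm
  arm_key <- paste(b$chrom, b$arm)
  interior <- which(arm_key[-1] == arm_key[-nrow(b)])
  true_bk <- interior[true_lab[interior] != true_lab[interior + 1L]]
  call_bk <- interior[!is.na(called_val[interior]) &
                        called_val[interior] != called_val[interior + 1L]]
  match_near <- function(a, ref) {
    if (length(a) == 0L) return(logical(0))
    vapply(a, function(x) any(abs(ref - x) <= match_slack), logical(1))
  }
  recall <- if (length(true_bk) == 0L) 1 else mean(match_near(true_bk, call_bk))
  precision <- if (length(call_bk) == 0L) 1 else mean(match_near(call_bk, true_bk))
  out <- list(breakpoint_recall = recall, breakpoint_precision = precision,
              bin_confusion = confusion)
  if (!is.null(focal)) {
    ev <- truth$events
    ev <- ev[!is.null(ev) & ev$query == query, , drop = FALSE]
    true_dir <- rep("none", nrow(focal))
    if (nrow(ev) > 0L) {
      for (e in seq_len(nrow(ev))) {
        hit <- focal$chrom == ev$chrom[e] & focal$start <= ev$end[e] &
          focal$end >= ev$start[e]
        true_dir[hit] <- if (ev$cn[e] > 2) "amplification" else
          if (ev$cn[e] < 2) "deletion" else "none"
      }
    }
    pos <- true_dir != "none"
    tp <- sum(pos & focal$direction == true_dir)
    fn <- sum(pos & focal$direction != true_dir)
    tn <- sum(!pos & focal$direction == "none")
    fp <- sum(!pos & focal$direction != "none")
    out$focal_sensitivity <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    out$focal_specificity <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
    out$focal_counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  }
  out
}

#' Write simulated fixtures in the package's TSV dialects
#'
#' Writes `genome.tsv`, `manifest.tsv`, `controls_meth.tsv`,
#' `controls_unmeth.tsv`, `queries_meth.tsv`, `queries_unmeth.tsv` and
#' `truth_events.tsv` under a directory.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory.
#' @return Invisibly, `out_dir`.
#' @export
write_simulation <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_manifest(cfg)
  coh <- simulate_cohort(cfg, sim$manifest)
  write.table(as.data.frame(sim$genome), file.path(out_dir, "genome.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  man <- sim$manifest[, c("probe_id", "chrom", "pos", "type")]
  write.table(man, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  wr <- function(m, f) {
    write.table(data.frame(probe_id = rownames(m), round(m, 3), check.names = FALSE),
                file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(coh$controls$M, "controls_meth.tsv")
  wr(coh$controls$U, "controls_unmeth.tsv")
  wr(coh$queries$M, "queries_meth.tsv")
  wr(coh$queries$U, "queries_unmeth.tsv")
  if (!is.null(coh$truth$events)) {
    write.table(coh$truth$events, file.path(out_dir, "truth_events.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}

#' Place synthetic genes on probe-dense loci
#'
#' On real methylation arrays, cancer-relevant genes lie in probe-dense
#' CpG-island regions, and a focal event there covers a vanishing fraction
#' of the genome's bins. At the generator's desk scale (a few hundred
#' bins) the same share is preserved by sizing each gene to the probe-dense
#' core of one bin: the gene spans the first ~45% of the probes of a
#' probe-rich bin, so it carries at least `min_probes` probes for a stable
#' gene-level median while a focal event confined to it never dominates
#' the bin median that feeds the bootstrap null. Placement is
#' deterministic given the manifest and bin map.
#'
#' @param manifest A `probe_manifest` from [simulate_manifest()].
#' @param genome The matching [genome_assembly()].
#' @param bins Optional `bin_map`; built with defaults when omitted.
#' @param n Number of genes to place (default 22).
#' @param min_probes Minimum probes per gene (default 10).
#' @param spacing Minimum start-to-start distance between genes on the
#'   same chromosome (default 300 kb).
#' @return A `gene_annotation` of `n` genes named `G01 ... Gn`.
#' @export
place_genes <- function(manifest, genome, bins = NULL, n = 22,
                        min_probes = 10, spacing = 300000) {
  if (is.null(bins)) bins <- build_bins(manifest, genome)
  b <- bins$bins
  ord <- order(-b$n_probes)
  sel <- integer(0)
  starts <- ends <- numeric(0)
  for (i in ord) {
    if (b$n_probes[i] < ceiling(min_probes / 0.45)) next
    same <- which(b$chrom[sel] == b$chrom[i])
    if (length(same) > 0L && any(abs(b$start[sel[same]] - b$start[i]) < spacing)) next
    ids <- bins$probe_id[bins$probe_bin == i]
    pos <- sort(manifest$pos[match(ids, manifest$probe_id)])
    k <- max(min_probes, floor(0.45 * length(pos)))
    k <- min(k, floor(0.45 * length(pos)))
    if (k < min_probes) next
    sel <- c(sel, i)
    starts <- c(starts, pos[1L])
    ends <- c(ends, pos[k])
    if (length(sel) >= n) break
  }
  if (length(sel) < n) {
    mc_stop("place_genes: could not place ", n, " genes with the given spacing")
  }
  o <- order(factor(b$chrom[sel], levels = genome$chrom), starts)
  gene_annotation(sprintf("G%02d", seq_len(n)), b$chrom[sel][o],
                  starts[o], ends[o])
}
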