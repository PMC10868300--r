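#' Convert per-sample segmentations into referential segments
#'
#' The union of all samples' breakpoints defines a non-overlapping tiling
#' of each chromosome ("referential segments"). Every sample's segment
#' mean is propagated onto each referential segment it covers and
#' classified as gain (`mean > gain_thr`), loss (`mean < loss_thr`) or
#' balanced; per referential segment the three classes are summarized as
#' percentages of the covering samples. The default thresholds +/-0.1
#' follow common GISTIC practice.
#'
#' @param tables List of `segment_table`s (or a single one).
#' @param gain_thr,loss_thr Classification thresholds on segment means
#'   (defaults +0.1 / -0.1).
#' @return A `cohort_summary` data frame: `chrom`, `start`, `end`
#'   (half-open), `n_samples`, `pct_gain`, `pct_loss`, `pct_balanced`.
#' @export
referential_segments <- function(tables, gain_thr = 0.1, loss_thr = -0.1) {
  if (inherits(tables, "segment_table")) tables <- list(tables)
  if (length(tables) < 1L) mc_stop("referential_segments: need at least one table")
  all_seg <- do.call(rbind, lapply(tables, as.data.frame))
  out <- list()
  for (ch in unique(all_seg$chrom)) {
    seg_ch <- all_seg[all_seg$chrom == ch, , drop = FALSE]
    bounds <- sort(unique(c(seg_ch$start, seg_ch$end)))
    for (k in seq_len(length(bounds) - 1L)) {
      s <- bounds[k]; e <- bounds[k + 1L]
      cover <- seg_ch$start <= s & seg_ch$end >= e
      if (!any(cover)) next
      means <- seg_ch$seg_mean[cover]
      n <- length(means)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = s, end = e, n_samples = n,
        pct_gain = 100 * sum(means > gain_thr) / n,
        pct_loss = 100 * sum(means < loss_thr) / n,
        pct_balanced = 100 * sum(means <= gain_thr & means >= loss_thr) / n,
        stringsAsFactors = FALSE)
    }
  }
  cs <- do.call(rbind, out)
  rownames(cs) <- NULL
  attr(cs, "gain_thr") <- gain_thr
  attr(cs, "loss_thr") <- loss_thr
  class(cs) <- c("cohort_summary", "data.frame")
  cs
}

#' Gene-wise weighted mean of overlapping segment log2-ratios
#'
#' Segment boundaries are not restricted to gene locations, so a gene may
#' span several segments. Its summary value is the mean of the overlapping
#' segments' log2-ratios weighted by the length of each intersection.
#'
#' @param table A `segment_table` of one sample.
#' @param genes A `gene_annotation` (1-based inclusive intervals).
#' @return Data frame `symbol`, `chrom`, `start`, `end`, `value`; genes
#'   with no overlapping segment are excluded.
#' @export
gene_weighted_mean <- function(table, genes) {
  out <- list()
  for (g in seq_len(nrow(genes))) {
    seg <- table[table$chrom == genes$chrom[g], , drop = FALSE]
    if (nrow(seg) == 0L) next
    # segment [start, end) vs gene [start, end] inclusive
    ov_lo <- pmax(seg$start, genes$start[g])
    ov_hi <- pmin(seg$end - 1, genes$end[g])
    len <- pmax(ov_hi - ov_lo + 1, 0)
    if (sum(len) <= 0) next
    out[[length(out) + 1L]] <- data.frame(
      symbol = genes$symbol[g], chrom = genes$chrom[g],
      start = genes$start[g], end = genes$end[g],
      value = sum(len * seg$seg_mean) / sum(len),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(symbol = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0), value = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write segment tables in SEG format (IGV/GISTIC dialect)
#'
#' Header `Sample  Chromosome  Start  End  Num_Probes  Seg_Mean`,
#' tab-separated, coordinates 1-based inclusive, means printed with 4
#' decimals.
#'
#' @param tables A `segment_table` or list of them.
#' @param path Output path.
#' @export
write_seg <- function(tables, path) {
  if (inherits(tables, "segment_table")) tables <- list(tables)
  seg <- do.call(rbind, lapply(tables, as.data.frame))
  out <- data.frame(Sample = seg$sample, Chromosome = seg$chrom,
                    Start = seg$start, End = seg$end - 1,
                    Num_Probes = seg$n_probes,
                    Seg_Mean = sprintf("%.4f", seg$seg_mean))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG file
#'
#' Inverse of [write_seg()] on coordinates, probe counts and means (to the
#' printed precision). Malformed lines raise an error naming the line.
#'
#' @param path Path to a SEG file.
#' @return A `segment_table` (with `arm` and `n_bins` unavailable, NA).
#' @export
read_seg <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  stopifnot_cols(d, c("Sample", "Chromosome", "Start", "End", "Num_Probes",
                      "Seg_Mean"), "read_seg")
  num <- function(col, what) {
    x <- suppressWarnings(as.numeric(d[[col]]))
    if (anyNA(x) && nrow(d) > 0) {
      mc_stop("read_seg: malformed ", what, " at data line ", which(is.na(x))[1L])
    }
    x
  }
  st <- data.frame(sample = d$Sample, chrom = d$Chromosome,
                   arm = rep(NA_character_, nrow(d)),
                   start = num("Start", "Start"), end = num("End", "End") + 1,
                   n_bins = rep(NA_integer_, nrow(d)),
                   n_probes = as.integer(num("Num_Probes", "Num_Probes")),
                   seg_mean = num("Seg_Mean", "Seg_Mean"),
                   stringsAsFactors = FALSE)
  class(st) <- c("segment_table", "data.frame")
  st
}

#' Default analysis configuration
#'
#' All tunable parameters of the workflow with their defaults. Any subset
#' can be overridden through the `config` argument of [run_cohort()].
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(mode = "log", floor = 1,
       bin_size = 50000, min_probes = 15, min_size = 50000,
       search_bound = 1.0, min_variance = 1e-4, weight_source = "query",
       alpha = 0.01, n_perm = 10000, min_width = 2, undo_sd = 0,
       gain_thr = 0.1, loss_thr = -0.1,
       tail = 0.005, block_length = 500000, iterations = 100,
       noise_threshold = 0.6, seed = 1)
}

#' Run the full workflow for a cohort of query samples
#'
#' For each query: tangent normalization against the shared control panel,
#' genomic binning with baseline correction and inverse-variance weights,
#' weighted circular binary segmentation, copy-number state assignment,
#' segmented block bootstrap, and (if a gene annotation is given) focal
#' calling. Per-sample failures are isolated: the sample is reported as
#' failed and the remaining samples proceed. Outputs under `out_dir`:
#' `<sample>.seg`, `<sample>_focal.tsv`, `qc.tsv`, `summary.tsv` and a
#' machine-readable `run_manifest.json` with every parameter and seed.
#' Reruns with identical inputs and seeds produce byte-identical files.
#'
#' @param queries,controls Combined intensity matrices (probes x samples,
#'   probe rownames) or `intensity_matrix` objects.
#' @param manifest A `probe_manifest`.
#' @param genome The [genome_assembly()] the manifest was loaded against.
#' @param genes Optional `gene_annotation` for focal calling.
#' @param out_dir Output directory (created if missing); `NULL` to skip
#'   writing files.
#' @param config Named list overriding entries of [default_config()].
#' @return Invisible list with `samples` (per-sample result lists),
#'   `qc` (noise table), `summary` (a `cohort_summary` or NULL), `config`.
#' @export
run_cohort <- function(queries, controls, manifest, genome, genes = NULL,
                       out_dir = NULL, config = list()) {
  cfg <- modifyList(default_config(), config)
  qI <- if (inherits(queries, "intensity_matrix")) queries$I else as.matrix(queries)
  cI <- if (inherits(controls, "intensity_matrix")) controls$I else as.matrix(controls)
  shared <- intersect(rownames(qI), rownames(cI))
  man <- manifest[manifest$probe_id %in% shared, , drop = FALSE]
  class(man) <- class(manifest)
  qI <- qI[man$probe_id[!man$excluded], , drop = FALSE]
  cI <- cI[man$probe_id[!man$excluded], , drop = FALSE]
  bins <- build_bins(man, genome, cfg$bin_size, cfg$min_probes, cfg$min_size)
  ctrl_var <- if (identical(cfg$weight_source, "controls")) {
    bin_variance_from_controls(cI, bins, cfg$floor)
  } else NULL
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  samples <- colnames(qI)
  if (is.null(samples)) samples <- paste0("query", seq_len(ncol(qI)))
  results <- list()
  qc <- data.frame(sample = samples, noise = NA_real_, shift = NA_real_,
                   flagged = NA, status = "ok", stringsAsFactors = FALSE)
  for (k in seq_along(samples)) {
    sid <- samples[k]
    res <- tryCatch({
      q <- qI[, k]
      names(q) <- NULL
      fit <- if (identical(cfg$mode, "raw")) {
        fit_tangent_raw(q, cI, cfg$floor)
      } else {
        fit_tangent_log(q, cI, cfg$floor)
      }
      prof <- log_ratio(q, fit, man, sample_id = sid)
      noise <- noise_parameter(prof)
      bp <- summarize_bins(prof, bins)
      bp <- baseline_correct(bp, cfg$search_bound)
      bp <- bin_weights(bp, cfg$min_variance, variance = ctrl_var)
      seg <- segment_profile(bp, alpha = cfg$alpha, n_perm = cfg$n_perm,
                             min_width = cfg$min_width, undo_sd = cfg$undo_sd,
                             seed = cfg$seed + 2L * k)
      st <- assign_states(bp)
      null <- block_bootstrap(bp, st, block_length = cfg$block_length,
                              iterations = cfg$iterations,
                              seed = cfg$seed + 2L * k + 1L)
      focal <- if (!is.null(genes)) {
        call_focal(gene_values(prof, genes), null, tail = cfg$tail)
      } else NULL
      list(sample = sid, profile = prof, noise = noise, bin_profile = bp,
           segments = seg, states = st, null = null, focal = focal,
           shift = attr(bp, "shift"))
    }, error = function(e) {
      mc_warn("run_cohort: sample '", sid, "' failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) {
      qc$status[k] <- "failed"
      next
    }
    qc$noise[k] <- res$noise
    qc$shift[k] <- res$shift
    qc$flagged[k] <- res$noise > cfg$noise_threshold
    results[[sid]] <- res
    if (!is.null(out_dir)) {
      write_seg(res$segments, file.path(out_dir, paste0(sid, ".seg")))
      if (!is.null(res$focal)) {
        write_focal(res$focal, file.path(out_dir, paste0(sid, "_focal.tsv")))
      }
    }
  }
  summary <- NULL
  if (length(results) > 0L) {
    summary <- referential_segments(lapply(results, `[[`, "segments"),
                                    gain_thr = cfg$gain_thr, loss_thr = cfg$loss_thr)
  }
  if (!is.null(out_dir)) {
    qc_out <- qc
    qc_out$noise <- round(qc_out$noise, 6)
    qc_out$shift <- round(qc_out$shift, 6)
    write.table(qc_out, file.path(out_dir, "qc.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(summary)) {
      sm <- as.data.frame(summary)
      sm$end <- sm$end - 1  # 1-based inclusive in text output
      sm$pct_gain <- round(sm$pct_gain, 4)
      sm$pct_loss <- round(sm$pct_loss, 4)
      sm$pct_balanced <- round(sm$pct_balanced, 4)
      write.table(sm, file.path(out_dir, "summary.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(list(parameters = cfg, samples = samples,
                              n_controls = ncol(cI), n_probes = nrow(qI),
                              n_bins = nrow(bins$bins)),
                         file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(samples = results, qc = qc, summary = summary, config = cfg,
                 bins = bins))
}

#' Static genome plot of a binned, segmented profile
#'
#' Bin values are drawn as points with point size proportional to weight,
#' segment means as horizontal lines, and gene labels for genes inside the
#' plotted range. Supports whole-genome, single-chromosome and region
#' modes.
#'
#' @param bp A `bin_profile`.
#' @param table A `segment_table` for the same sample.
#' @param genes Optional `gene_annotation` to label.
#' @param path Output file (`.pdf` or `.png` by extension).
#' @param chrom Optional chromosome to restrict to.
#' @param from,to Optional 1-based range within `chrom`.
#' @return Invisibly, the path.
#' @export
genome_plot <- function(bp, table, genes = NULL, path, chrom = NULL,
                        from = NULL, to = NULL) {
  sel_b <- rep(TRUE, nrow(bp))
  sel_s <- rep(TRUE, nrow(table))
  if (!is.null(chrom)) {
    sel_b <- bp$chrom == chrom
    sel_s <- table$chrom == chrom
    if (!is.null(from)) {
      sel_b <- sel_b & bp$end > from & bp$start <= to
      sel_s <- sel_s & table$end > from & table$start <= to
    }
  }
  b <- bp[sel_b, , drop = FALSE]
  s <- table[sel_s, , drop = FALSE]
  if (nrow(b) == 0L) mc_warn("genome_plot: no bins in the requested region")
  chroms <- unique(bp$chrom)
  offs <- setNames(c(0, cumsum(vapply(chroms, function(ch)
    max(bp$end[bp$chrom == ch]), numeric(1))))[seq_along(chroms)], chroms)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    grDevices::png(path, width = 1400, height = 500)
  } else {
    grDevices::pdf(path, width = 14, height = 5)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  ylim <- if (nrow(b) > 0L) range(c(b$value, -1.5, 1.5)) else c(-1.5, 1.5)
  if (nrow(b) > 0L) {
    x <- offs[b$chrom] + (b$start + b$end) / 2
    cex <- 0.4 + 0.8 * sqrt(b$weight / max(b$weight))
    plot(x, b$value, pch = 16, cex = cex, col = "grey40",
         xlab = "genomic position", ylab = "log2-ratio", ylim = ylim,
         main = attr(bp, "sample_id"))
  } else {
    plot(NA, xlim = c(0, 1), ylim = ylim, xlab = "genomic position",
         ylab = "log2-ratio", main = attr(bp, "sample_id"))
  }
  graphics::abline(h = 0, col = "grey70", lty = 2)
  if (is.null(chrom)) {
    graphics::abline(v = offs[-1], col = "grey85")
  }
  if (nrow(s) > 0L) {
    graphics::segments(offs[s$chrom] + s$start, s$seg_mean,
                       offs[s$chrom] + s$end, s$seg_mean,
                       col = "red", lwd = 2)
  }
  if (!is.null(genes) && nrow(genes) > 0L) {
    g <- genes[genes$chrom %in% chroms, , drop = FALSE]
    if (!is.null(chrom)) {
      g <- g[g$chrom == chrom, , drop = FALSE]
      if (!is.null(from)) g <- g[g$end >= from & g$start <= to, , drop = FALSE]
    }
    if (nrow(g) > 0L) {
      gx <- offs[g$chrom] + (g$start + g$end) / 2
      graphics::mtext(g$symbol, side = 3, at = gx, cex = 0.6, line = 0)
    }
  }
  invisible(path)
}
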