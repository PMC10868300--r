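# Small programmatic fixtures shared across test files.

toy_genome <- function(n_chrom = 1, len = 300000, cen_frac = c(0.45, 0.55)) {
  genome_assembly(paste0("chr", seq_len(n_chrom)), rep(len, n_chrom),
                  cen_start = rep(floor(cen_frac[1] * len), n_chrom),
                  cen_end = rep(floor(cen_frac[2] * len), n_chrom))
}

# build a probe_manifest directly from vectors (bypasses file I/O)
toy_manifest <- function(chrom, pos, genome, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("p%04d", seq_along(pos))
  m <- data.frame(probe_id = ids, chrom = chrom, pos = pos,
                  type = "II", excluded = FALSE, stringsAsFactors = FALSE)
  m <- m[order(factor(m$chrom, levels = genome$chrom), m$pos), ]
  rownames(m) <- NULL
  class(m) <- c("probe_manifest", "data.frame")
  attr(m, "genome") <- genome
  m
}

write_manifest_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a bin_profile built directly from per-bin values on one arm
toy_bin_profile <- function(values, weights = rep(1, length(values)),
                            n_probes = rep(20L, length(values)),
                            chrom = "chr1", arm = "p", bin_size = 50000,
                            sample_id = "toy") {
  n <- length(values)
  bp <- data.frame(chrom = chrom, arm = arm,
                   start = 1 + (seq_len(n) - 1) * bin_size,
                   end = 1 + seq_len(n) * bin_size,
                   n_probes = n_probes, width = bin_size, deficient = FALSE,
                   value = values, variance = 1 / weights, weight = weights,
                   stringsAsFactors = FALSE)
  attr(bp, "sample_id") <- sample_id
  attr(bp, "shift") <- 0
  class(bp) <- c("bin_profile", "data.frame")
  bp
}

# default simulated cohort with a couple of arm-scale events, cached per session
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cnvs <- data.frame(query = c(1, 2), chrom = c("chr1", "chr1"),
                         start = c(1e6, 6e6), end = c(4e6, 9.5e6),
                         cn = c(3, 1))
      cfg <- sim_config(n_queries = 2, cnvs = cnvs, seed = 7)
      sim <- simulate_manifest(cfg)
      coh <- simulate_cohort(cfg, sim$manifest)
      cache <<- list(cfg = cfg, manifest = sim$manifest, genome = sim$genome,
                     controls = coh$controls, queries = coh$queries,
                     truth = coh$truth)
    }
    cache
  }
})

# minimal segment table constructor
mk_seg <- function(sample, chrom, start, end, mean, n_probes = 10L) {
  st <- data.frame(sample = sample, chrom = chrom, arm = "p", start = start,
                   end = end, n_bins = 2L, n_probes = n_probes,
                   seg_mean = mean, stringsAsFactors = FALSE)
  class(st) <- c("segment_table", "data.frame")
  st
}

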