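test_that("simulated manifests meet their contracts", {
  cfg <- sim_config(seed = 5)
  sim <- simulate_manifest(cfg)
  expect_equal(nrow(sim$manifest), cfg$n_probes)
  expect_false(is.unsorted(match(sim$manifest$chrom, sim$genome$chrom)))
  for (ch in sim$genome$chrom) {
    p <- sim$manifest$pos[sim$manifest$chrom == ch]
    expect_false(is.unsorted(p))
    gi <- match(ch, sim$genome$chrom)
    expect_true(all(p < sim$genome$cen_start[gi] | p > sim$genome$cen_end[gi]))
  }
  # same seed, identical output; different seed, different placement
  sim2 <- simulate_manifest(cfg)
  expect_identical(sim$manifest, sim2$manifest)
  sim3 <- simulate_manifest(sim_config(seed = 6))
  expect_false(identical(sim$manifest$pos, sim3$manifest$pos))
})

test_that("zero clustering factor gives uniform probe spacing", {
  cfg <- sim_config(cluster_factor = 0, n_probes = 2000, n_chrom = 1, seed = 8)
  sim <- simulate_manifest(cfg)
  pos <- sim$manifest$pos
  gi <- 1
  # positions avoid the centromere: compare arms separately to a uniform law
  p_arm <- pos[pos < sim$genome$cen_start[gi]]
  ks <- suppressWarnings(stats::ks.test(p_arm, "punif", 1, sim$genome$cen_start[gi]))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort generation is reproducible and events act multiplicatively", {
  sim <- default_sim()
  coh2 <- simulate_cohort(sim$cfg, sim$manifest)
  expect_identical(coh2$queries$I, sim$queries$I)
  expect_identical(coh2$truth$probe_cn, sim$truth$probe_cn)
  # event outside bounds is a hard error
  bad <- sim$cfg
  bad$cnvs <- data.frame(query = 1, chrom = "chr1", start = 1, end = 99e6, cn = 3)
  expect_error(simulate_cohort(bad, sim$manifest), "outside chromosome bounds")
})

test_that("a copy-neutral query normalizes to a profile centered at zero", {
  cfg <- sim_config(n_queries = 1, seed = 17)
  sim <- simulate_manifest(cfg)
  coh <- simulate_cohort(cfg, sim$manifest)
  fit <- fit_tangent_log(unname(coh$queries$I[, 1]), coh$controls$I)
  prof <- log_ratio(unname(coh$queries$I[, 1]), fit, sim$manifest)
  expect_lt(abs(median(prof$R)), 0.05)
})

test_that("injected events recover their expected log2 levels end to end", {
  sim <- default_sim()
  res <- run_cohort(sim$queries, sim$controls, sim$manifest, sim$genome,
                    config = list(n_perm = 1000))
  # query 1 carries a 3 Mb single-copy gain on chr1: a segment near log2(3/2)
  st1 <- res$samples[["query01"]]$segments
  gain <- st1[st1$chrom == "chr1" & st1$seg_mean > 0.3, ]
  expect_gte(nrow(gain), 1)
  expect_equal(max(gain$seg_mean), log2(3 / 2), tolerance = 0.1)
  # query 2 carries a 3.5 Mb single-copy loss on chr1q near log2(1/2)
  st2 <- res$samples[["query02"]]$segments
  loss <- st2[st2$chrom == "chr1" & st2$seg_mean < -0.3, ]
  expect_gte(nrow(loss), 1)
  expect_equal(min(loss$seg_mean), log2(1 / 2), tolerance = 0.15)
})

test_that("a homozygous deletion drives the gene value below -2", {
  cnvs <- data.frame(query = 1, chrom = "chr2", start = 2e6, end = 2.2e6, cn = 0)
  cfg <- sim_config(n_queries = 1, cnvs = cnvs, seed = 23)
  sim <- simulate_manifest(cfg)
  coh <- simulate_cohort(cfg, sim$manifest)
  fit <- fit_tangent_log(unname(coh$queries$I[, 1]), coh$controls$I)
  prof <- log_ratio(unname(coh$queries$I[, 1]), fit, sim$manifest)
  genes <- gene_annotation("DEL1", "chr2", 2.02e6, 2.18e6)
  gv <- gene_values(prof, genes)
  expect_lt(gv$value, -2)
})

test_that("tangent residual noise decreases monotonically with panel size", {
  base <- sim_config(n_controls = 32, n_queries = 1, seed = 29)
  sim <- simulate_manifest(base)
  coh <- simulate_cohort(base, sim$manifest)
  q <- unname(coh$queries$I[, 1])
  noises <- vapply(c(4, 8, 16, 32), function(k) {
    fit <- suppressWarnings(fit_tangent_log(q, coh$controls$I[, seq_len(k)]))
    noise_parameter(log_ratio(q, fit, sim$manifest))
  }, numeric(1))
  expect_true(all(diff(noises) <= 1e-6))
})

test_that("evaluate_calls reproduces a hand-computed toy confusion matrix", {
  # 1-chromosome toy: 10 bins, truth = loss on bins 3-4, call = loss on 3-5
  genome <- genome_assembly("chr1", 1e6, 999000, 999500)
  pos <- seq(5000, 995000, by = 10000)[1:99]
  m <- toy_manifest(rep("chr1", length(pos)), pos, genome)
  bm <- build_bins(m, genome, bin_size = 100000, min_probes = 5, min_size = 50000)
  nb <- nrow(bm$bins)
  expect_equal(nb, 10L)
  truth_cn <- matrix(2, nrow(m), 1)
  b34 <- bm$probe_bin %in% c(3, 4)
  truth_cn[match(bm$probe_id[b34], m$probe_id), 1] <- 1
  truth <- list(events = data.frame(query = 1, chrom = "chr1",
                                    start = bm$bins$start[3],
                                    end = bm$bins$end[4] - 1, cn = 1),
                probe_cn = truth_cn)
  st <- mk_seg("q", "chr1", c(bm$bins$start[1], bm$bins$start[3], bm$bins$start[6]),
               c(bm$bins$end[2], bm$bins$end[5], bm$bins$end[10]),
               mean = c(0, -1, 0))
  st$arm <- bm$bins$arm[c(1, 3, 6)]
  ev <- evaluate_calls(truth, 1, st, bm, m)
  # hand count: true loss bins 3,4 called loss (2 TP); bin 5 called loss but
  # truly balanced (1 FP); bins 1,2,6..10 balanced both ways
  expect_equal(as.vector(ev$bin_confusion["loss", ]), c(2, 0, 0))
  expect_equal(as.vector(ev$bin_confusion["balanced", ]), c(1, 7, 0))
  # breakpoints: truth at 2|3 and 4|5; calls at 2|3 and 5|6 -> recall 1 (slack 1),
  # precision 1
  expect_equal(ev$breakpoint_recall, 1)
  expect_equal(ev$breakpoint_precision, 1)

  # degenerate contracts: perfect segmentation and no calls at all
  st_perfect <- mk_seg("q", "chr1",
                       c(bm$bins$start[1], bm$bins$start[3], bm$bins$start[5]),
                       c(bm$bins$end[2], bm$bins$end[4], bm$bins$end[10]),
                       mean = c(0, -1, 0))
  st_perfect$arm <- bm$bins$arm[c(1, 3, 5)]
  evp <- evaluate_calls(truth, 1, st_perfect, bm, m)
  expect_equal(evp$breakpoint_recall, 1)
  expect_equal(evp$breakpoint_precision, 1)
})
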