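test_that("state assignment separates well-separated levels deterministically", {
  set.seed(61)
  lv <- sample(c(-1, 0, 1), 120, replace = TRUE)
  bp <- toy_bin_profile(lv + rnorm(120, 0, 0.05))
  st <- assign_states(bp)
  expect_identical(st$state,
                   c("loss", "balanced", "gain")[match(lv, c(-1, 0, 1))])
  expect_equal(st$centers, c(-1, 0, 1), tolerance = 0.05)

  # degenerate: all equal values
  expect_warning(std <- assign_states(toy_bin_profile(rep(0.2, 10))),
                 "balanced")
  expect_true(all(std$state == "balanced"))
})

test_that("k-means centers are recovered on a seeded Gaussian mixture", {
  set.seed(62)
  v <- c(rnorm(600, -1, 0.1), rnorm(1000, 0, 0.1), rnorm(400, 0.58, 0.1))
  st <- assign_states(toy_bin_profile(v))
  expect_equal(st$centers, c(-1, 0, 0.58), tolerance = 0.05)
})

test_that("block bootstrap resamples within states and matches a seeded replica", {
  set.seed(63)
  v <- c(rnorm(30, 0, 0.05), rnorm(10, 1, 0.05), rnorm(20, 0, 0.05))
  bp <- toy_bin_profile(v, bin_size = 100000)
  st <- assign_states(bp)
  null <- block_bootstrap(bp, st, block_length = 500000, iterations = 4, seed = 99)
  expect_equal(dim(null$sequences), c(60L, 4L))
  # closure: every resampled value comes from bins of the matching state
  for (it in 1:4) {
    for (s in c("loss", "balanced", "gain")) {
      ix <- st$state == s
      if (!any(ix)) next
      expect_true(all(null$sequences[ix, it] %in% v[st$state == s]))
    }
  }

  # independent replica of the documented sampler, same seed
  arm_key <- paste(bp$chrom, bp$arm)
  run_id <- cumsum(c(TRUE, st$state[-1] != st$state[-60] |
                       arm_key[-1] != arm_key[-60]))
  runs <- split(seq_len(60), run_id)
  blocks <- list(loss = list(), balanced = list(), gain = list())
  for (r in seq_along(runs)) {
    ix <- runs[[r]]
    offs <- floor((bp$start[ix] - bp$start[ix[1]]) / 500000)
    sname <- st$state[ix[1]]
    for (g in split(ix, offs)) blocks[[sname]][[length(blocks[[sname]]) + 1]] <- v[g]
  }
  set.seed(99)
  replica <- matrix(NA_real_, 60, 4)
  for (it in 1:4) {
    for (r in seq_along(runs)) {
      ix <- runs[[r]]; pool <- blocks[[st$state[ix[1]]]]
      got <- numeric(0)
      while (length(got) < length(ix)) {
        got <- c(got, pool[[sample.int(length(pool), 1)]])
      }
      replica[ix, it] <- got[seq_along(ix)]
    }
  }
  expect_equal(null$sequences, replica)
})

test_that("bootstrap quantiles stabilize as iterations double", {
  sim <- default_sim()
  bm <- build_bins(sim$manifest, sim$genome)
  fit <- fit_tangent_log(unname(sim$queries$I[, 1]), sim$controls$I)
  prof <- log_ratio(unname(sim$queries$I[, 1]), fit, sim$manifest)
  bp <- bin_weights(baseline_correct(summarize_bins(prof, bm)))
  st <- assign_states(bp)
  n100 <- block_bootstrap(bp, st, iterations = 100, seed = 7)
  n200 <- block_bootstrap(bp, st, iterations = 200, seed = 7)
  q100 <- quantile(n100$pool, c(0.05, 0.95))
  q200 <- quantile(n200$pool, c(0.05, 0.95))
  expect_equal(unname(q100), unname(q200), tolerance = 0.01)
})

test_that("thresholds are the tail quantiles and widen with noise / smaller tails", {
  set.seed(64)
  pool <- rnorm(1e5)
  null <- structure(list(pool = pool), class = "bootstrap_null")
  thr <- derive_thresholds(null, tail = 0.005)
  expect_equal(thr$del_thr, -2.576, tolerance = 0.05)
  expect_equal(thr$amp_thr, 2.576, tolerance = 0.05)
  expect_error(derive_thresholds(null, tail = 0.5), "tail")
  expect_error(derive_thresholds(null, tail = 0), "tail")
  # monotone in tail
  thr2 <- derive_thresholds(null, tail = 0.05)
  expect_gt(thr$amp_thr, thr2$amp_thr)
  expect_lt(thr$del_thr, thr2$del_thr)
  # noisier pools give wider thresholds
  null2 <- structure(list(pool = pool * 2), class = "bootstrap_null")
  thrw <- derive_thresholds(null2, tail = 0.005)
  expect_gt(thrw$amp_thr, thr$amp_thr)
})

test_that("gene values are probe medians with inclusive boundaries", {
  genome <- toy_genome(len = 1e6, cen_frac = c(0.99, 0.995))
  m <- toy_manifest(rep("chr1", 5), c(100, 200, 300, 400, 500), genome)
  prof <- normalized_profile(m, c(-2.1, -1.9, -2.0, 0, 0.3))
  genes <- gene_annotation(c("G1", "G2", "G3"), "chr1",
                           start = c(100, 400, 900000), end = c(300, 400, 950000))
  gv <- suppressMessages(gene_values(prof, genes))
  expect_equal(gv$value[gv$symbol == "G1"], -2.0)
  # G2 spans exactly one probe at its end coordinate: inclusive
  expect_equal(gv$n_probes[gv$symbol == "G2"], 1L)
  # G3 has no probes: excluded with a logged count
  expect_false("G3" %in% gv$symbol)
})

test_that("focal calls respect strict thresholds and the add-one p-value rule", {
  pool <- seq(-1, 1, length.out = 1999)  # symmetric, known quantiles
  null <- structure(list(pool = pool), class = "bootstrap_null")
  thr <- derive_thresholds(null, tail = 0.005)
  vals <- data.frame(symbol = c("AT_THR", "DEL", "NEUTRAL"), chrom = "chr1",
                     start = c(1, 100, 200), end = c(10, 110, 210),
                     category = "other", n_probes = 3L,
                     value = c(thr$amp_thr, -2, 0))
  calls <- call_focal(vals, null, tail = 0.005)
  expect_equal(calls$direction, c("none", "deletion", "none"))
  expect_true(all(calls$p_empirical > 0))
  expect_equal(calls$p_empirical[2], 1 / (1 + length(pool)))
  expect_gt(calls$p_empirical[3], 0.05)
  expect_identical(calls$significant, c(FALSE, TRUE, FALSE))
})

test_that("fixing the seed fixes every call bit-exactly", {
  sim <- default_sim()
  bm <- build_bins(sim$manifest, sim$genome)
  fit <- fit_tangent_log(unname(sim$queries$I[, 1]), sim$controls$I)
  prof <- log_ratio(unname(sim$queries$I[, 1]), fit, sim$manifest)
  bp <- bin_weights(baseline_correct(summarize_bins(prof, bm)))
  st <- assign_states(bp)
  genes <- gene_annotation("G", "chr1", 2e6, 2.1e6)
  c1 <- call_focal(gene_values(prof, genes),
                   block_bootstrap(bp, st, iterations = 20, seed = 13))
  c2 <- call_focal(gene_values(prof, genes),
                   block_bootstrap(bp, st, iterations = 20, seed = 13))
  expect_identical(c1, c2)
})
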