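test_that("tangent fit recovers identity and exact linear structure", {
  set.seed(1)
  q <- rlnorm(50, log(2000), 0.5)
  # single control equal to the query: coefficient 1, zero residual
  fit <- suppressWarnings(fit_tangent_log(q, matrix(q, ncol = 1)))
  expect_equal(unname(fit$coefficients), 1, tolerance = 1e-10)
  expect_equal(fit$rmse, 0, tolerance = 1e-10)

  # query = geometric mean of two controls -> coefficients (0.5, 0.5)
  C <- cbind(rlnorm(50, log(2000), 0.5), rlnorm(50, log(2000), 0.5))
  qg <- sqrt(C[, 1] * C[, 2])
  fit2 <- suppressWarnings(fit_tangent_log(qg, C))
  expect_equal(unname(fit2$coefficients), c(0.5, 0.5), tolerance = 1e-8)
})

test_that("log and raw fits match the normal-equation oracle on random instances", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    k <- sample(2:4, 1)
    C <- matrix(rlnorm(n * k, log(1500), 0.6), n, k)
    q <- rlnorm(n, log(1500), 0.6)
    fl <- suppressWarnings(fit_tangent_log(q, C))
    expect_equal(unname(fl$coefficients),
                 lsq_oracle(log2(pmax(C, 1)), log2(pmax(q, 1))),
                 tolerance = 1e-8)
    fr <- suppressWarnings(fit_tangent_raw(q, C))
    expect_equal(unname(fr$coefficients), lsq_oracle(C, q), tolerance = 1e-8)
  }
})

test_that("raw-mode fitted control intensities are floored before the log", {
  # force a negative fitted value: control with negative coefficient
  q <- c(10, 10, 10, 10)
  C <- cbind(c(100, 100, 100, 100), c(120, 120, 120, 400))
  fit <- suppressWarnings(fit_tangent_raw(q, C, floor = 1))
  manual <- drop(C %*% fit$coefficients)
  expect_equal(fit$fitted, log2(pmax(manual, 1)))
})

test_that("log ratios behave as log2 fold changes", {
  genome <- toy_genome(len = 1e6, cen_frac = c(0.99, 0.995))
  m <- toy_manifest(rep("chr1", 60), seq(1000, 900000, length.out = 60), genome)
  set.seed(3)
  ctrl <- rlnorm(60, log(2000), 0.4)
  # with coefficient fixed at 1, a doubled query gives R = 1 everywhere
  fit <- structure(list(coefficients = 1, fitted = log2(ctrl),
                        mode = "log", floor = 1), class = "tangent_fit")
  prof <- log_ratio(ctrl * 2, fit, m)
  expect_equal(prof$R, rep(1, 60))
  # and an identical query gives R = 0 everywhere
  expect_equal(log_ratio(ctrl, fit, m)$R, rep(0, 60))

  # query = control except one probe at 4x: R ~ 2 there, near 0 elsewhere
  genome2 <- toy_genome(len = 1e7, cen_frac = c(0.99, 0.995))
  m2 <- toy_manifest(rep("chr1", 500), seq(1000, 9e6, length.out = 500), genome2)
  base <- rlnorm(500, log(2000), 0.4)
  C3 <- cbind(base * rlnorm(500, 0, 0.01), base * rlnorm(500, 0, 0.01),
              base * rlnorm(500, 0, 0.01))
  q2 <- base; q2[250] <- q2[250] * 4
  fit4 <- suppressWarnings(fit_tangent_log(q2, C3))
  prof4 <- log_ratio(q2, fit4, m2)
  # one perturbed probe barely moves the fit: R ~ 2 there, |R| small elsewhere
  expect_equal(prof4$R[250], 2, tolerance = 0.1)
  expect_lt(max(abs(prof4$R[-250])), 0.05)
})

test_that("mean-reference ratio matches its definition", {
  genome <- toy_genome(len = 1e6, cen_frac = c(0.99, 0.995))
  m <- toy_manifest(rep("chr1", 10), seq(1000, 9e5, length.out = 10), genome)
  set.seed(4)
  C <- matrix(rlnorm(20, log(1000), 0.3), 10, 2)
  prof <- mean_reference_ratio(C[, 1], C, m)
  expect_equal(prof$R, log2(C[, 1]) - rowMeans(log2(C)))
  prof1 <- mean_reference_ratio(C[, 1], C[, 1, drop = FALSE], m)
  expect_equal(prof1$R, rep(0, 10))
})

test_that("noise parameter follows its closed form and flags noisy samples", {
  genome <- toy_genome(len = 1e6, cen_frac = c(0.99, 0.995))
  m <- toy_manifest(rep("chr1", 40), seq(1000, 9e5, length.out = 40), genome)
  const <- normalized_profile(m, rep(0.3, 40))
  expect_equal(noise_parameter(const), 0)
  d <- 0.2
  alt <- normalized_profile(m, rep(c(d, -d), 20))
  expect_equal(noise_parameter(alt), sqrt(2) * d, tolerance = 1e-12)
  # adding a constant leaves the noise unchanged
  shifted <- normalized_profile(m, rep(c(d, -d), 20) + 5)
  expect_equal(noise_parameter(shifted), noise_parameter(alt))
  expect_true(flag_noisy_sample(normalized_profile(m, cumsum(rep(1, 40)))))
  expect_false(flag_noisy_sample(const))
})

test_that("noise pairs never cross chromosomes", {
  genome <- toy_genome(n_chrom = 2, len = 1e6, cen_frac = c(0.99, 0.995))
  m <- toy_manifest(rep(c("chr1", "chr2"), each = 5),
                    rep(seq(1000, 9e5, length.out = 5), 2), genome)
  # constant per chromosome but a big jump between chromosomes
  prof <- normalized_profile(m, c(rep(0, 5), rep(10, 5)))
  expect_equal(noise_parameter(prof), 0)
})

test_that("input guards: zero query, panel leakage, small panels, rank deficiency", {
  q <- rlnorm(20, log(1000), 0.3)
  C <- matrix(rlnorm(40, log(1000), 0.3), 20, 2)
  expect_error(suppressWarnings(fit_tangent_log(rep(0, 20), C)), "all-zero query")
  expect_warning(fit_tangent_log(q, C), "fewer than 16")
  Cn <- cbind(a = C[, 1], b = q)
  w <- capture_warnings(fit_tangent_log(q, Cn))
  expect_true(any(grepl("exact copy", w)))
  qid <- q; names(qid) <- rep("s1", 20)
  colnames(C) <- c("s1", "s2")
  expect_error(suppressWarnings(fit_tangent_log(qid, C)),
               "present in the control panel")
  Crd <- cbind(C[, 1], C[, 1])  # identical columns: rank 1 in log space
  w2 <- capture_warnings(fit_tangent_log(q, Crd))
  expect_true(any(grepl("rank-deficient", w2)))
})

test_that("a global query scale factor is absorbed as a near-constant shift", {
  # without an intercept the shift is exact only up to the projection of the
  # constant vector onto the control span; with a realistic panel the bulk
  # of the factor lands in the profile median and the noise barely moves
  sim <- default_sim()
  q <- sim$queries$I[, 1]
  C <- sim$controls$I
  fit1 <- fit_tangent_log(unname(q), C)
  p1 <- log_ratio(unname(q), fit1, sim$manifest)
  fit2 <- fit_tangent_log(unname(q) * 3, C)
  p2 <- log_ratio(unname(q) * 3, fit2, sim$manifest)
  # with this panel the constant is essentially inside the control span,
  # so the factor is absorbed by the fit rather than shifting R
  expect_lt(abs(median(p2$R - p1$R)), 0.1)
  expect_equal(noise_parameter(p2) / noise_parameter(p1), 1, tolerance = 0.1)
  # baseline correction absorbs the residual shift at bin level
  bm <- build_bins(sim$manifest, sim$genome)
  b1 <- baseline_correct(summarize_bins(p1, bm))
  b2 <- baseline_correct(summarize_bins(p2, bm))
  expect_equal(median(b2$value), median(b1$value), tolerance = 0.05)
})
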