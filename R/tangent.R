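#' Tangent normalization against a copy-number neutral control panel
#'
#' Technical noise in a query sample's combined intensities is approximated
#' by the least-squares linear combination of control samples and
#' subtracted. The fit operates on log2-transformed intensities (the
#' revised model); [fit_tangent_raw()] provides the legacy raw-intensity
#' variant for comparison. There is no intercept: global shifts are handled
#' later by baseline correction, and coefficients are unconstrained in sign.
#'
#' @param query Numeric vector of combined intensities of one query sample,
#'   probe-aligned with `controls`. Optionally named with the sample id.
#' @param controls Numeric matrix (probes x controls) of combined
#'   intensities of copy-number neutral samples.
#' @param floor Intensities are clamped to at least this value before
#'   taking log2 (default 1), keeping logs finite for zero-signal probes.
#' @return A `tangent_fit`: list with `coefficients` (one per control),
#'   `fitted` (fitted log2 intensity per probe), `rmse`, `mode`, `floor`,
#'   `rank`.
#' @export
fit_tangent_log <- function(query, controls, floor = 1) {
  check_tangent_inputs(query, controls)
  y <- log2(pmax(query, floor))
  X <- log2(pmax(as.matrix(controls), floor))
  a <- lstsq_minnorm(X, y)
  fitted <- drop(X %*% a$coef)
  structure(list(coefficients = a$coef, fitted = fitted,
                 rmse = sqrt(mean((y - fitted)^2)),
                 mode = "log", floor = floor, rank = a$rank),
            class = "tangent_fit")
}

#' Legacy tangent fit on raw intensities
#'
#' Fits the linear combination on untransformed intensities. The fitted
#' combined control intensity can then be negative for low-signal probes;
#' values below `floor` are clamped to `floor` before the log2 when forming
#' ratios, reproducing the legacy behavior.
#'
#' @inheritParams fit_tangent_log
#' @return A `tangent_fit` with `mode = "raw"`; `fitted` is on the log2
#'   scale after clamping.
#' @export
fit_tangent_raw <- function(query, controls, floor = 1) {
  check_tangent_inputs(query, controls)
  X <- as.matrix(controls)
  a <- lstsq_minnorm(X, query)
  fitted_raw <- drop(X %*% a$coef)
  n_clamped <- sum(fitted_raw < floor)
  if (n_clamped > 0) {
    mc_msg("fit_tangent_raw: ", n_clamped,
           " fitted control intensity value(s) below ", floor, " clamped")
  }
  fitted <- log2(pmax(fitted_raw, floor))
  y <- log2(pmax(query, floor))
  structure(list(coefficients = a$coef, fitted = fitted,
                 rmse = sqrt(mean((y - fitted)^2)),
                 mode = "raw", floor = floor, rank = a$rank),
            class = "tangent_fit")
}

check_tangent_inputs <- function(query, controls) {
  controls <- as.matrix(controls)
  if (ncol(controls) < 1L) mc_stop("tangent fit: need at least one control")
  if (length(query) != nrow(controls)) mc_stop("tangent fit: probe mismatch")
  if (all(query == 0)) mc_stop("tangent fit: all-zero query sample")
  if (ncol(controls) < 16L) {
    mc_warn("tangent fit: fewer than 16 control samples (", ncol(controls),
            "); at least 16 copy-number neutral controls are recommended")
  }
  qid <- names(query)[1L]
  cids <- colnames(controls)
  if (!is.null(qid) && !is.na(qid) && qid %in% cids) {
    mc_stop("tangent fit: query sample '", qid, "' is present in the control panel")
  }
  if (ncol(controls) > 1L && !is.null(cids)) {
    # an exact duplicate column usually means the query leaked into the panel
    dup <- which(colSums(abs(controls - query)) == 0)
    if (length(dup) > 0L) {
      mc_warn("tangent fit: control '", cids[dup[1L]],
              "' is an exact copy of the query")
    }
  }
  invisible(TRUE)
}

# minimum-norm least squares via SVD; warns on rank deficiency
lstsq_minnorm <- function(X, y) {
  s <- svd(X)
  tol <- max(dim(X)) * max(s$d) * .Machine$double.eps
  pos <- s$d > tol
  rank <- sum(pos)
  if (rank < ncol(X)) {
    mc_warn("tangent fit: rank-deficient control matrix (rank ", rank, " of ",
            ncol(X), "); using the minimum-norm solution")
  }
  dinv <- ifelse(pos, 1 / s$d, 0)
  coef <- drop(s$v %*% (dinv * crossprod(s$u, y)))
  names(coef) <- colnames(X)
  list(coef = coef, rank = rank)
}

#' Per-probe log2-ratios from a tangent fit
#'
#' In log mode, `R_i = log2(I_qi) - sum_c a_c log2(I_ci)`; in raw mode,
#' `R_i = log2(I_qi) - log2(max(sum_c a_c I_ci, floor))`. Both use the
#' clamped query intensity.
#'
#' @param query Combined intensity vector of the query (same probes as the
#'   fit).
#' @param fit A `tangent_fit` from [fit_tangent_log()] or
#'   [fit_tangent_raw()].
#' @param manifest A `probe_manifest` giving probe order, chromosome and
#'   position (its non-excluded probes must match the fitted probe set
#'   length).
#' @param sample_id Label stored with the profile.
#' @return A `normalized_profile` data frame with columns `probe_id`,
#'   `chrom`, `pos`, `R` and attributes `sample_id`, `mode`.
#' @export
log_ratio <- function(query, fit, manifest, sample_id = "query") {
  if (length(query) != length(fit$fitted)) mc_stop("log_ratio: probe mismatch with fit")
  y <- log2(pmax(query, fit$floor))
  R <- y - fit$fitted
  normalized_profile(manifest, R, sample_id = sample_id, mode = fit$mode)
}

#' Baseline log2-ratios against the control-panel mean
#'
#' Comparison baseline: `R_i = log2(I_qi) - mean_c(log2 I_ci)`. Used to
#' quantify how much tangent normalization reduces noise relative to simply
#' referencing the average control.
#'
#' @inheritParams fit_tangent_log
#' @inheritParams log_ratio
#' @return A `normalized_profile`.
#' @export
mean_reference_ratio <- function(query, controls, manifest, sample_id = "query",
                                 floor = 1) {
  controls <- as.matrix(controls)
  if (ncol(controls) < 1L) mc_stop("mean_reference_ratio: need at least one control")
  R <- log2(pmax(query, floor)) - rowMeans(log2(pmax(controls, floor)))
  normalized_profile(manifest, R, sample_id = sample_id, mode = "mean")
}

#' Construct a normalized profile
#'
#' @param manifest A `probe_manifest`; its non-excluded probes define order.
#' @param R Per-probe log2-ratio vector aligned to those probes.
#' @param sample_id,mode Labels stored as attributes.
#' @return A `normalized_profile` data frame.
#' @export
normalized_profile <- function(manifest, R, sample_id = "query", mode = "log") {
  m <- manifest[!manifest$excluded, , drop = FALSE]
  if (nrow(m) != length(R)) mc_stop("normalized_profile: length mismatch with manifest")
  if (any(!is.finite(R))) mc_stop("normalized_profile: non-finite log2-ratios")
  p <- data.frame(probe_id = m$probe_id, chrom = m$chrom, pos = m$pos, R = R,
                  stringsAsFactors = FALSE)
  attr(p, "sample_id") <- sample_id
  attr(p, "mode") <- mode
  class(p) <- c("normalized_profile", "data.frame")
  p
}

#' Noise parameter of a normalized profile
#'
#' Mean absolute difference of neighboring probes' log2-ratios divided by
#' sqrt(2), neighbors taken in genomic order within chromosomes (no
#' cross-chromosome pairs). Under i.i.d. Gaussian noise this estimates the
#' per-probe standard deviation. Samples with noise above
#' `noise_threshold` (default 0.6) should be excluded from analysis.
#'
#' @param profile A `normalized_profile`.
#' @return The noise estimate (nonnegative scalar).
#' @export
noise_parameter <- function(profile) {
  if (nrow(profile) < 2L) mc_stop("noise_parameter: need at least 2 probes")
  d <- unlist(lapply(split(profile$R, profile$chrom), diff), use.names = FALSE)
  if (length(d) == 0L) mc_stop("noise_parameter: no within-chromosome neighbor pairs")
  sum(abs(d)) / (sqrt(2) * length(d))
}

#' QC flag for a noisy sample
#'
#' @param profile A `normalized_profile`.
#' @param noise_threshold Exclusion threshold on [noise_parameter()]
#'   (default 0.6).
#' @return Logical: `TRUE` if the sample should be excluded.
#' @export
flag_noisy_sample <- function(profile, noise_threshold = 0.6) {
  noise_parameter(profile) > noise_threshold
}

#' Write a normalized profile as TSV
#'
#' Columns `probe_id  chrom  pos  R`, positions 1-based.
#'
#' @param profile A `normalized_profile`.
#' @param path Output path.
#' @export
write_ratios <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
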