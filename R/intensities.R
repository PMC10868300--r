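#' Combine methylated and unmethylated channel intensities
#'
#' The combined per-probe intensity `I = M + U` is the proxy for the local
#' DNA copy number on which the whole workflow operates.
#'
#' @param M,U Numeric matrices (probes x samples) of identical shape.
#' @return Elementwise sum `M + U`.
#' @export
combine_channels <- function(M, U) {
  M <- as.matrix(M); U <- as.matrix(U)
  if (!identical(dim(M), dim(U))) mc_stop("combine_channels: shape mismatch")
  I <- M + U
  nz <- sum(I == 0)
  if (nz > 0) mc_msg("combine_channels: ", nz, " zero combined intensity value(s)")
  I
}

#' Read an intensity matrix pair and combine channels
#'
#' Both files are TSVs whose first column is `probe_id` and whose remaining
#' columns are samples. Files are aligned by probe id and by sample name
#' (never by position); probes present in only one file are dropped with a
#' logged count.
#'
#' @param path_meth,path_unmeth Paths to the methylated / unmethylated
#'   signal TSVs.
#' @return An `intensity_matrix`: list with matrices `M`, `U`, `I`
#'   (probes x samples, probe ids as rownames).
#' @export
load_intensity_matrix <- function(path_meth, path_unmeth) {
  M <- read_intensity_tsv(path_meth)
  U <- read_intensity_tsv(path_unmeth)
  common <- intersect(rownames(M), rownames(U))
  if (length(common) == 0L) mc_stop("load_intensity_matrix: no overlapping probes")
  dropped <- (nrow(M) - length(common)) + (nrow(U) - length(common))
  if (dropped > 0) {
    mc_msg("load_intensity_matrix: dropped ", dropped,
           " probe row(s) absent from one of the two files")
  }
  samples <- intersect(colnames(M), colnames(U))
  if (length(samples) == 0L) mc_stop("load_intensity_matrix: no shared sample columns")
  M <- M[common, samples, drop = FALSE]
  U <- U[common, samples, drop = FALSE]
  intensity_matrix(M = M, U = U)
}

#' Construct an intensity matrix container
#'
#' Supply either both channels (`M`, `U`; combined signal is their sum) or a
#' precombined matrix `I`.
#'
#' @param M,U Optional channel matrices with probe rownames.
#' @param I Optional precombined matrix.
#' @return An `intensity_matrix` list with elements `M`, `U`, `I`.
#' @export
intensity_matrix <- function(M = NULL, U = NULL, I = NULL) {
  if (is.null(I)) {
    if (is.null(M) || is.null(U)) mc_stop("intensity_matrix: need M and U, or I")
    I <- combine_channels(M, U)
    rownames(I) <- rownames(M); colnames(I) <- colnames(M)
  }
  if (any(I < 0)) mc_stop("intensity_matrix: negative intensities")
  if (is.null(rownames(I))) mc_stop("intensity_matrix: probe ids (rownames) required")
  structure(list(M = M, U = U, I = I), class = "intensity_matrix")
}

read_intensity_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot_cols(d, "probe_id", "intensity TSV")
  if (anyDuplicated(d$probe_id)) mc_stop("intensity TSV: duplicate probe ids in ", path)
  m <- as.matrix(d[, setdiff(names(d), "probe_id"), drop = FALSE])
  if (!is.numeric(m)) mc_stop("intensity TSV: non-numeric values in ", path)
  if (any(m < 0)) mc_stop("intensity TSV: negative intensities in ", path)
  rownames(m) <- d$probe_id
  m
}

#' Write a combined intensity matrix as TSV
#'
#' @param im An `intensity_matrix` (its `I` component is written).
#' @param path Output path.
#' @export
write_intensity_tsv <- function(im, path) {
  out <- data.frame(probe_id = rownames(im$I), im$I, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align an intensity matrix to a probe manifest
#'
#' Rows are reordered to manifest (genomic) order; probes lacking either
#' intensity data or annotation are dropped with logged counts. Idempotent.
#'
#' @param im An `intensity_matrix`.
#' @param manifest A `probe_manifest`.
#' @return The aligned `intensity_matrix`; attribute `probe_idx` holds the
#'   row indices of the manifest probes that were matched.
#' @export
align_to_manifest <- function(im, manifest) {
  ids <- manifest$probe_id
  common <- ids[ids %in% rownames(im$I)]
  if (length(common) == 0L) mc_stop("align_to_manifest: disjoint probe sets")
  frac <- length(common) / length(ids)
  if (frac < 0.5) {
    mc_warn(sprintf("align_to_manifest: only %.1f%% of manifest probes matched",
                    100 * frac))
  }
  n_drop_int <- nrow(im$I) - length(common)
  n_drop_man <- length(ids) - length(common)
  if (n_drop_int > 0) mc_msg("align_to_manifest: dropped ", n_drop_int,
                             " intensity row(s) without annotation")
  if (n_drop_man > 0) mc_msg("align_to_manifest: ", n_drop_man,
                             " manifest probe(s) without intensity data")
  out <- list(M = if (!is.null(im$M)) im$M[common, , drop = FALSE],
              U = if (!is.null(im$U)) im$U[common, , drop = FALSE],
              I = im$I[common, , drop = FALSE])
  structure(out, class = "intensity_matrix")
}
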