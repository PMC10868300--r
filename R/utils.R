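#' @useDynLib methylcnv, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median quantile var rnorm runif rlnorm rbeta setNames
#' @importFrom utils read.delim write.table head tail modifyList
#' @importFrom graphics plot
NULL

# internal: consistent condition messages with a "methylcnv" prefix
mc_msg <- function(...) message("[methylcnv] ", ...)
mc_warn <- function(...) warning(paste0(...), call. = FALSE)
mc_stop <- function(...) stop(paste0(...), call. = FALSE)

# internal: order chromosomes as they appear in the genome table so that
# "chr10" does not sort before "chr2"
chrom_factor <- function(x, genome) {
  factor(as.character(x), levels = genome$chrom)
}

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    mc_stop(what, ": missing required column(s): ", paste(miss, collapse = ", "))
  }
}

# internal: weighted mean that tolerates zero-length input
wmean <- function(x, w) {
  if (length(x) == 0L) return(NA_real_)
  sum(w * x) / sum(w)
}
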