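#' Construct a genome assembly table
#'
#' A genome assembly records, per chromosome, the total length and the
#' centromere interval. Chromosome arms derived from the centromere are the
#' units within which genomic bins and copy-number segments are formed;
#' neither ever spans a centromere.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in bases (> 0).
#' @param cen_start,cen_end 1-based inclusive bounds of the centromere
#'   interval of each chromosome; must lie inside the chromosome.
#' @return A `genome_assembly` data frame with columns `chrom`, `length`,
#'   `cen_start`, `cen_end`.
#' @export
genome_assembly <- function(chrom, length, cen_start, cen_end) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) mc_stop("genome_assembly: duplicated chromosome names")
  if (any(length <= 0)) mc_stop("genome_assembly: chromosome lengths must be > 0")
  if (any(cen_start < 1 | cen_end > length | cen_start > cen_end)) {
    mc_stop("genome_assembly: centromere interval must be contained in the chromosome")
  }
  g <- data.frame(chrom = chrom, length = as.numeric(length),
                  cen_start = as.numeric(cen_start), cen_end = as.numeric(cen_end),
                  stringsAsFactors = FALSE)
  class(g) <- c("genome_assembly", "data.frame")
  g
}

#' Read a genome assembly from a tab-separated file
#'
#' Expected header: `chrom  length  cen_start  cen_end`, centromere bounds
#' 1-based inclusive.
#'
#' @param path Path to the TSV file.
#' @return A [genome_assembly()] table.
#' @export
read_genome <- function(path) {
  g <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot_cols(g, c("chrom", "length", "cen_start", "cen_end"), "read_genome")
  genome_assembly(g$chrom, g$length, g$cen_start, g$cen_end)
}

#' Chromosome-arm table of a genome assembly
#'
#' Arms are half-open intervals on 1-based positions: the p arm covers
#' positions `[1, cen_start + 1)` and the q arm `[cen_end + 1, length + 1)`,
#' so positions inside the centromere belong to no arm.
#'
#' @param genome A [genome_assembly()].
#' @return Data frame with columns `chrom`, `arm`, `start`, `end`.
#' @export
genome_arms <- function(genome) {
  p <- data.frame(chrom = genome$chrom, arm = "p",
                  start = 1, end = genome$cen_start + 1,
                  stringsAsFactors = FALSE)
  q <- data.frame(chrom = genome$chrom, arm = "q",
                  start = genome$cen_end + 1, end = genome$length + 1,
                  stringsAsFactors = FALSE)
  arms <- rbind(p, q)
  arms <- arms[arms$end > arms$start, , drop = FALSE]
  arms <- arms[order(chrom_factor(arms$chrom, genome), arms$start), , drop = FALSE]
  rownames(arms) <- NULL
  arms
}

#' Load a probe manifest
#'
#' Reads a tab-separated probe manifest (`probe_id  chrom  pos  type`,
#' positions 1-based) and validates it against a genome assembly. Probes on
#' chromosomes absent from the genome, probes beyond the chromosome length,
#' and probes inside a centromere are dropped with a logged count. The
#' result is sorted by genomic coordinate in the genome's chromosome order.
#'
#' @param path Path to the manifest TSV. A `type` column (`I`/`II`) is
#'   optional and carried through unused by the numeric pipeline.
#' @param genome A [genome_assembly()].
#' @return A `probe_manifest` data frame with columns `probe_id`, `chrom`,
#'   `pos`, `type`, `excluded`.
#' @export
load_manifest <- function(path, genome) {
  raw <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  stopifnot_cols(raw, c("probe_id", "chrom", "pos"), "load_manifest")
  pos <- suppressWarnings(as.numeric(raw$pos))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1L]
    mc_stop("load_manifest: unparseable position at data line ", bad,
            " (probe ", raw$probe_id[bad], ")")
  }
  if (anyDuplicated(raw$probe_id)) {
    dup <- raw$probe_id[duplicated(raw$probe_id)][1L]
    mc_stop("load_manifest: duplicate probe id: ", dup)
  }
  m <- data.frame(probe_id = raw$probe_id, chrom = raw$chrom, pos = pos,
                  type = if ("type" %in% names(raw)) raw$type else NA_character_,
                  stringsAsFactors = FALSE)
  known <- m$chrom %in% genome$chrom
  if (any(!known)) {
    mc_msg("load_manifest: dropped ", sum(!known),
           " probe(s) on chromosomes absent from the genome")
  }
  m <- m[known, , drop = FALSE]
  gi <- match(m$chrom, genome$chrom)
  inlen <- m$pos >= 1 & m$pos <= genome$length[gi]
  if (any(!inlen)) {
    mc_msg("load_manifest: dropped ", sum(!inlen),
           " probe(s) outside the chromosome bounds")
    m <- m[inlen, , drop = FALSE]
    gi <- gi[inlen]
  }
  incen <- m$pos >= genome$cen_start[gi] & m$pos <= genome$cen_end[gi]
  if (any(incen)) {
    mc_msg("load_manifest: dropped ", sum(incen),
           " probe(s) inside centromere intervals")
    m <- m[!incen, , drop = FALSE]
  }
  m <- m[order(chrom_factor(m$chrom, genome), m$pos), , drop = FALSE]
  m$excluded <- FALSE
  rownames(m) <- NULL
  class(m) <- c("probe_manifest", "data.frame")
  attr(m, "genome") <- genome
  m
}

#' Flag probes inside exclusion regions
#'
#' Probes whose position falls inside any supplied region (half-open
#' `[start, end)` on the same 1-based position scale as the manifest) are
#' flagged `excluded` and ignored by all downstream steps. Typical use:
#' masking polymorphic regions such as the HLA locus.
#'
#' @param manifest A `probe_manifest`.
#' @param regions Data frame with columns `chrom`, `start`, `end`
#'   (half-open), e.g. from [read_bed_regions()]. An empty region set is a
#'   no-op.
#' @return The manifest with updated `excluded` flags.
#' @export
apply_exclusions <- function(manifest, regions) {
  if (is.null(regions) || nrow(regions) == 0L) return(manifest)
  stopifnot_cols(regions, c("chrom", "start", "end"), "apply_exclusions")
  hit <- rep(FALSE, nrow(manifest))
  for (k in seq_len(nrow(regions))) {
    hit <- hit | (manifest$chrom == regions$chrom[k] &
                    manifest$pos >= regions$start[k] &
                    manifest$pos < regions$end[k])
  }
  if (any(hit)) mc_msg("apply_exclusions: flagged ", sum(hit), " probe(s) as excluded")
  manifest$excluded <- manifest$excluded | hit
  manifest
}

#' Read exclusion regions from a BED file
#'
#' BED intervals (0-based half-open) are converted to half-open intervals on
#' 1-based positions, i.e. BED `[s, e)` covers positions `s+1 .. e` and is
#' returned as `start = s + 1`, `end = e + 1`.
#'
#' @param path Path to a BED file.
#' @return Data frame with columns `chrom`, `start`, `end` suitable for
#'   [apply_exclusions()].
#' @export
read_bed_regions <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr) + 1,
             stringsAsFactors = FALSE)
}

#' Read a gene annotation
#'
#' Accepts either a BED file (gene symbol in column 4; coordinates converted
#' to 1-based inclusive) or a tab-separated table with header
#' `symbol  chrom  start  end` and an optional `category` column
#' (`oncogene`, `tumor_suppressor` or `other`). Gene intervals are 1-based
#' inclusive; a probe exactly at the start or end coordinate overlaps the
#' gene.
#'
#' @param path Path to a `.bed` file or TSV.
#' @return A `gene_annotation` data frame with columns `symbol`, `chrom`,
#'   `start`, `end`, `category`.
#' @export
read_genes <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    sym <- if (!is.null(gr$name)) as.character(gr$name) else paste0("gene", seq_along(gr))
    g <- data.frame(symbol = sym,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    category = "other",
                    stringsAsFactors = FALSE)
  } else {
    g <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot_cols(g, c("symbol", "chrom", "start", "end"), "read_genes")
    if (!"category" %in% names(g)) g$category <- "other"
  }
  gene_annotation(g$symbol, g$chrom, g$start, g$end, g$category)
}

#' Construct a gene annotation table
#'
#' @param symbol Unique gene symbols.
#' @param chrom,start,end 1-based inclusive gene intervals.
#' @param category Per-gene category, one of `oncogene`,
#'   `tumor_suppressor`, `other`.
#' @return A `gene_annotation` data frame.
#' @export
gene_annotation <- function(symbol, chrom, start, end, category = "other") {
  if (anyDuplicated(symbol)) mc_stop("gene_annotation: duplicated gene symbols")
  if (any(start > end)) mc_stop("gene_annotation: start > end")
  g <- data.frame(symbol = as.character(symbol), chrom = as.character(chrom),
                  start = as.numeric(start), end = as.numeric(end),
                  category = rep_len(as.character(category), length(symbol)),
                  stringsAsFactors = FALSE)
  class(g) <- c("gene_annotation", "data.frame")
  g
}

#' Build the genomic bin map
#'
#' Tiles every chromosome arm into windows of `bin_size` bases, drops
#' windows containing no probes, then iteratively merges any bin with fewer
#' than `min_probes` probes or a genomic span below `min_size` into
#' whichever same-arm neighbor holds fewer probes (ties merge leftward),
#' until every bin satisfies both minima or the arm has collapsed into a
#' single bin. Merging never crosses an arm boundary. The bin map depends
#' only on the manifest, genome and parameters, never on intensities, so it
#' is identical across samples.
#'
#' @param manifest A `probe_manifest` (excluded probes are ignored).
#' @param genome A [genome_assembly()].
#' @param bin_size Tiling window size in bases (default 50 kb).
#' @param min_probes Minimum probes per bin (default 15).
#' @param min_size Minimum genomic span per merged bin in bases (default 50 kb).
#' @return A `bin_map`: list with `bins` (data frame `chrom`, `arm`,
#'   `start`, `end` half-open on 1-based positions, `n_probes`, `width`,
#'   `deficient`), `probe_id` and `probe_bin` (bin index of every retained
#'   probe), and `params`. An arm whose probes cannot reach the minima
#'   yields one bin flagged `deficient`.
#' @export
build_bins <- function(manifest, genome, bin_size = 50000, min_probes = 15,
                       min_size = 50000) {
  if (bin_size <= 0 || min_probes <= 0 || min_size <= 0) {
    mc_stop("build_bins: parameters must be positive")
  }
  keep <- !manifest$excluded
  probes <- manifest[keep, , drop = FALSE]
  arms <- genome_arms(genome)
  out_bins <- list()
  probe_bin <- integer(nrow(probes))
  probe_seen <- logical(nrow(probes))
  nbin_total <- 0L
  for (a in seq_len(nrow(arms))) {
    sel <- which(probes$chrom == arms$chrom[a] &
                   probes$pos >= arms$start[a] & probes$pos < arms$end[a])
    if (length(sel) == 0L) next
    pos <- probes$pos[sel]
    astart <- arms$start[a]; aend <- arms$end[a]
    nwin <- ceiling((aend - astart) / bin_size)
    win <- pmin(floor((pos - astart) / bin_size), nwin - 1L)  # 0-based window index
    occupied <- sort(unique(win))
    b_start <- astart + occupied * bin_size
    b_end <- pmin(astart + (occupied + 1) * bin_size, aend)
    b_n <- as.integer(table(factor(win, levels = occupied)))
    memb <- match(win, occupied)  # bin index per probe within this arm
    # iterative merge: repeatedly resolve the first deficient bin in
    # coordinate order; restart the scan after each merge
    repeat {
      defic <- which(b_n < min_probes | (b_end - b_start) < min_size)
      if (length(defic) == 0L || length(b_n) == 1L) break
      i <- defic[1L]
      if (i == 1L) {
        j <- 2L
      } else if (i == length(b_n)) {
        j <- i - 1L
      } else {
        j <- if (b_n[i + 1L] < b_n[i - 1L]) i + 1L else i - 1L  # tie -> left
      }
      lo <- min(i, j); hi <- max(i, j)
      b_end[lo] <- b_end[hi]
      b_n[lo] <- b_n[lo] + b_n[hi]
      b_start <- b_start[-hi]; b_end <- b_end[-hi]; b_n <- b_n[-hi]
      memb[memb >= hi] <- memb[memb >= hi] - 1L
    }
    bins <- data.frame(chrom = arms$chrom[a], arm = arms$arm[a],
                       start = b_start, end = b_end, n_probes = b_n,
                       width = b_end - b_start,
                       deficient = b_n < min_probes | (b_end - b_start) < min_size,
                       stringsAsFactors = FALSE)
    out_bins[[length(out_bins) + 1L]] <- bins
    probe_bin[sel] <- memb + nbin_total
    probe_seen[sel] <- TRUE
    nbin_total <- nbin_total + nrow(bins)
  }
  if (length(out_bins) == 0L) mc_stop("build_bins: no probes fall on any chromosome arm")
  bins <- do.call(rbind, out_bins)
  rownames(bins) <- NULL
  structure(list(bins = bins,
                 probe_id = probes$probe_id[probe_seen],
                 probe_bin = probe_bin[probe_seen],
                 params = list(bin_size = bin_size, min_probes = min_probes,
                               min_size = min_size)),
            class = "bin_map")
}

#' @export
print.bin_map <- function(x, ...) {
  cat("bin_map:", nrow(x$bins), "bins over",
      length(unique(paste(x$bins$chrom, x$bins$arm))), "arms;",
      length(x$probe_id), "probes;",
      sum(x$bins$deficient), "deficient bin(s)\n")
  invisible(x)
}

#' Write a bin map as TSV (1-based inclusive coordinates)
#'
#' @param bm A `bin_map`.
#' @param path Output path.
#' @export
write_bins <- function(bm, path) {
  b <- bm$bins
  out <- data.frame(chrom = b$chrom, arm = b$arm, start = b$start,
                    end = b$end - 1, n_probes = b$n_probes,
                    deficient = b$deficient)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
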