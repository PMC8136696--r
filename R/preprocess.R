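# Read preprocessing: demultiplexing by hexamer index read, quality
# trimming, and removal of the primer-derived read prefix (N-run + anchor).

#' Demultiplex reads by their hexamer index reads
#'
#' Assigns each read to the unique sample barcode within Hamming distance
#' `max_mismatch` of the first 6 bases of its index read.  Ties (more than
#' one barcode within tolerance) and no-matches go to the undetermined
#' stream.  Counts are conserved exactly: per-sample counts plus
#' undetermined equal the input count.
#'
#' @param reads data frame of reads (`id`, `seq`, `qual`) as from
#'   [read_fastq()].
#' @param index_reads data frame of index reads, positionally paired with
#'   `reads`; index sequences must be at least 6 bases.
#' @param sheet sample sheet (`sample_name`, `barcode`), validated with
#'   [validate_sample_sheet()] before any read is processed.
#' @param max_mismatch allowed mismatches between index and barcode (0 or 1;
#'   default 1).
#' @return list with `samples` (named list of read data frames),
#'   `undetermined` (read data frame) and `counts` (named integer vector
#'   including an `undetermined` entry).
#' @export
demultiplex <- function(reads, index_reads, sheet, max_mismatch = 1L) {
  stopifnot(nrow(reads) == nrow(index_reads))
  validate_sample_sheet(sheet, max_mismatch)
  if (any(nchar(index_reads$seq) < 6L)) {
    stopf("index reads must be at least 6 bases long")
  }
  idx6 <- toupper(substr(index_reads$seq, 1L, 6L))
  bcs <- toupper(sheet$barcode)
  d <- vapply(bcs, function(b) hamming_to(idx6, b),
              numeric(nrow(reads)))
  d <- matrix(d, nrow = nrow(reads))
  within <- d <= max_mismatch
  nhit <- rowSums(within)
  assign <- ifelse(nhit == 1L, max.col(within, ties.method = "first"), NA_integer_)

  samples <- lapply(seq_along(bcs), function(j) {
    reads[which(!is.na(assign) & assign == j), , drop = FALSE]
  })
  names(samples) <- sheet$sample_name
  undet <- reads[is.na(assign), , drop = FALSE]
  counts <- c(vapply(samples, nrow, integer(1L)), undetermined = nrow(undet))
  stopifnot(sum(counts) == nrow(reads))
  list(samples = samples, undetermined = undet, counts = counts)
}

#' Trim low-quality leading and trailing bases
#'
#' Removes leading and trailing bases whose Phred score is below `q_min`
#' (the conventional Q20 cutoff by default); reads shorter than `min_len`
#' after trimming are dropped and counted.  Retained bases are an
#' unmodified contiguous substring of the input read.
#'
#' @param reads read data frame (`id`, `seq`, `qual`).
#' @param q_min minimum Phred score kept at the read ends (default 20).
#' @param min_len minimum post-trim length to keep a read (default 36).
#' @return list with `reads` (trimmed survivors) and `dropped` (count).
#' @export
quality_trim <- function(reads, q_min = 20L, min_len = 36L) {
  stopifnot(q_min >= 0L)
  if (nrow(reads) == 0L) return(list(reads = reads, dropped = 0L))
  bounds <- t(vapply(phred_to_int(reads$qual), function(q) {
    ok <- which(q >= q_min)
    if (length(ok) == 0L) c(NA_integer_, NA_integer_) else range(ok)
  }, integer(2L)))
  keep <- !is.na(bounds[, 1L]) & (bounds[, 2L] - bounds[, 1L] + 1L) >= min_len
  out <- reads[keep, , drop = FALSE]
  if (nrow(out) > 0L) {
    lo <- bounds[keep, 1L]; hi <- bounds[keep, 2L]
    out$seq <- substr(out$seq, lo, hi)
    out$qual <- substr(out$qual, lo, hi)
  }
  list(reads = out, dropped = sum(!keep))
}

#' Trim the primer-derived prefix from reads
#'
#' Each sequencing read begins inside the pre-amplification primer: the
#' `n_random` random bases then the 3-base anchor (GGG/TTT).  These
#' `n_random + 3` bases are primer-derived, not template, and are removed
#' before placement.  Whether the anchor positions matched a known tail is
#' recorded per read (`anchor_tag`: `"GGG"`, `"TTT"` or `"unrecognized"`);
#' a mismatched anchor is tolerated, only recorded.  Reads not longer than
#' the prefix are dropped and counted.
#'
#' @param reads read data frame (`id`, `seq`, `qual`).
#' @param design a [make_primer_design()] object.
#' @return list with `reads` (trimmed, plus column `anchor_tag`) and
#'   `dropped` (count of too-short reads).
#' @export
trim_primer_prefix <- function(reads, design) {
  stopifnot(inherits(design, "primer_design"))
  plen <- design$n_random + 3L
  keep <- nchar(reads$seq) > plen
  out <- reads[keep, , drop = FALSE]
  if (nrow(out) > 0L) {
    tag <- substr(out$seq, design$n_random + 1L, plen)
    out$anchor_tag <- ifelse(tag %in% design$anchor_tails, tag, "unrecognized")
    out$seq <- substr(out$seq, plen + 1L, nchar(out$seq))
    out$qual <- substr(out$qual, plen + 1L, nchar(out$qual))
  } else {
    out$anchor_tag <- character(0)
  }
  list(reads = out, dropped = sum(!keep))
}
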