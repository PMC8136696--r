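# FASTQ and sample-sheet I/O (Biostrings-backed, gzip-transparent).
#
# Reads are carried through the preprocessing stages as a plain data frame
# with columns id / seq / qual (Phred+33 string), which keeps per-base
# trimming logic transparent; Biostrings does the file-format work.

#' Read a FASTQ file
#'
#' @param path FASTQ file, optionally gzip-compressed.
#' @return data frame with columns `id`, `seq`, `qual` (Phred+33 encoded,
#'   same length as `seq`).
#' @export
read_fastq <- function(path) {
  # Biostrings warns about (empty) metadata columns during construction
  x <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"))
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads data frame with columns `id`, `seq`, `qual`.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)),
            all(nchar(reads$seq) == nchar(reads$qual)))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(reads$qual))
  names(x) <- reads$id
  # Biostrings warns about dropping (empty) metadata columns on write
  suppressWarnings(
    Biostrings::writeQualityScaledXStringSet(x, path,
                                             compress = grepl("\\.gz$", path)))
  invisible(path)
}

#' Read a sample sheet mapping hexamer barcodes to sample names
#'
#' @param path TSV with columns `sample_name`, `barcode`.
#' @return data frame with those two columns, validated for uniqueness and
#'   barcode alphabet/length.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_name", "barcode") %in% names(df)))
  validate_sample_sheet(df[, c("sample_name", "barcode")], max_mismatch = 0L)
  df[, c("sample_name", "barcode")]
}

#' Validate a sample sheet against a demultiplexing mismatch tolerance
#'
#' Barcodes must be unique length-6 ACGT strings; when `max_mismatch > 0`
#' every pair must additionally be at Hamming distance
#' `>= 2 * max_mismatch + 1` so that assignment within the tolerance is
#' unambiguous.
#'
#' @param sheet data frame with `sample_name`, `barcode`.
#' @param max_mismatch intended mismatch tolerance (0 or 1).
#' @return the sheet, invisibly, on success; otherwise an error.
#' @export
validate_sample_sheet <- function(sheet, max_mismatch = 1L) {
  stopifnot(all(c("sample_name", "barcode") %in% names(sheet)),
            max_mismatch %in% c(0L, 1L))
  bc <- toupper(sheet$barcode)
  if (anyDuplicated(bc)) stopf("sample sheet has duplicate barcodes")
  if (anyDuplicated(sheet$sample_name)) stopf("sample sheet has duplicate sample names")
  if (any(nchar(bc) != 6L)) stopf("all barcodes must be length 6")
  if (any(!grepl("^[ACGT]+$", bc))) stopf("barcodes must contain only A/C/G/T")
  if (max_mismatch > 0L && nrow(sheet) > 1L) {
    need <- 2L * max_mismatch + 1L
    for (i in seq_len(nrow(sheet) - 1L)) {
      d <- hamming_to(bc[(i + 1L):nrow(sheet)], bc[i])
      if (any(d < need)) {
        j <- i + which(d < need)[1L]
        stopf("barcodes '%s' and '%s' are at Hamming distance %d < %d required for max_mismatch = %d",
              bc[i], bc[j], d[which(d < need)[1L]], need, max_mismatch)
      }
    }
  }
  invisible(sheet)
}
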