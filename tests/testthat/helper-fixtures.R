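# Shared fixture builders: everything is generated in code at test time.

toy_sizes <- function(n_chroms = 3L, len = 1e6) {
  setNames(rep(len, n_chroms),
           c(as.character(seq_len(min(n_chroms, 22L))),
             c("X", "Y"))[seq_len(n_chroms)])
}

# a small read data frame with uniform quality
toy_reads <- function(seqs, q = 30L) {
  data.frame(id = sprintf("r%03d", seq_along(seqs)),
             seq = seqs,
             qual = vapply(nchar(seqs),
                           function(n) strrep(intToUtf8(q + 33L), n),
                           character(1L)),
             stringsAsFactors = FALSE)
}

# random reads with per-base qualities given as integer lists
random_reads <- function(n, len, quals = NULL, seed = 1L) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1L))
  df <- toy_reads(seqs)
  if (!is.null(quals)) {
    df$qual <- vapply(quals, function(q) intToUtf8(q + 33L), character(1L))
  }
  df
}

# minimal SAM file for alignment-reading tests; returns the path
write_toy_sam <- function(records, chrom_lengths, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  body <- vapply(records, function(r) {
    seq <- strrep("A", r$len %||% 10L)
    paste(r$qname %||% "r", r$flag, r$chrom, r$pos1, r$mapq, paste0(nchar(seq), "M"),
          "*", 0, 0, seq, strrep("F", nchar(seq)), sep = "\t")
  }, character(1L))
  writeLines(c(hdr, body), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample sheet of well-separated barcodes (pairwise Hamming distance >= 3)
toy_sheet <- function(n) {
  pool <- c("AAACCC", "CCCGGG", "GGGTTT", "TTTAAA", "ACGACG", "CGTCGT",
            "GTAGTA", "TACTAC", "AATTGG", "CCAATT", "GGCCAA", "TTGGCC",
            "AGCAGC", "CTGCTG", "GATGAT", "TCATCA")
  stopifnot(n <= length(pool))
  data.frame(sample_name = sprintf("S%02d", seq_len(n)),
             barcode = pool[seq_len(n)], stringsAsFactors = FALSE)
}
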