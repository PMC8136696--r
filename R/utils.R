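# Internal helpers shared across modules.

CHROM_LEVELS <- c(as.character(1:22), "X", "Y")
AUTOSOMES <- as.character(1:22)
DNA_BASES <- c("A", "C", "G", "T")

# Normalize chromosome names: strip a leading "chr", keep canonical order.
norm_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x))
  x
}

chrom_factor <- function(x) {
  x <- norm_chrom(x)
  extra <- setdiff(unique(x), CHROM_LEVELS)
  factor(x, levels = c(CHROM_LEVELS, sort(extra)))
}

#' Is a chromosome an autosome?
#'
#' Anything that is not a sex chromosome (X, Y) or mitochondrial (M, MT)
#' counts as an autosome, with or without a `chr` prefix — so toy
#' references with arbitrary chromosome names normalize like autosomes.
#' Copy-number normalization and calling treat the groups differently
#' throughout the pipeline.
#'
#' @param chrom character or factor vector of chromosome names.
#' @return logical vector.
#' @export
is_autosome <- function(chrom) {
  !(norm_chrom(as.character(chrom)) %in% c("X", "Y", "M", "MT"))
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L)
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# Hamming distance between equal-length strings and one fixed pattern.
hamming_to <- function(strings, pattern) {
  pat <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  k <- length(pat)
  mat <- matrix(unlist(strsplit(strings, "", fixed = TRUE), use.names = FALSE),
                ncol = k, byrow = TRUE)
  rowSums(mat != matrix(pat, nrow = nrow(mat), ncol = k, byrow = TRUE))
}

phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

int_to_phred <- function(ints) {
  vapply(ints, function(i) intToUtf8(i + 33L), character(1L))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
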