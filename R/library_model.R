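# Library designs and the base-composition diversity audit.
#
# MALBAC-style pre-amplification primers end in a run of fully random bases
# ("N") followed by a 3-base anchor (GGG or TTT).  Because the sequencing
# primer sits immediately upstream of the N-run, the first cycles of every
# read are random: the base diversity the Illumina cluster-recognition step
# needs is built into the library, so no random spike-in (Phix) is required.
# The audit below quantifies that diversity from observed (or simulated)
# read prefixes.

.PRIMER_DESIGNS <- list(
  original    = list(constant_prefix = "GTGAGTGATGGTTGAGGTAGTGTGGAG", n_random = 5L),
  d1          = list(constant_prefix = "GCTCTTCCGATCT", n_random = 5L),
  d2          = list(constant_prefix = "GCTCTTCCGATCT", n_random = 6L),
  d3          = list(constant_prefix = "GCTCTTCCGATCT", n_random = 7L),
  d4          = list(constant_prefix = "GCTCTTCCGATCT", n_random = 8L),
  d5          = list(constant_prefix = "GCTCTTCCGATCT", n_random = 9L),
  takara_like = list(constant_prefix = "", n_random = 6L)
)

#' Construct a pre-amplification primer design
#'
#' Returns the primer family used for single-cell whole-genome
#' amplification: a constant prefix (the 3' end of the Illumina adapter, or
#' the original 27-bp MALBAC constant), a run of `n_random` fully random
#' bases, and a 3' anchor tail of `GGG` or `TTT` (each primer pool contains
#' both tails in equal parts). `"takara_like"` is a synthetic stand-in for a
#' two-letter flanking design whose read prefix draws only from `{G, T}`,
#' useful as a negative control for the diversity audit.
#'
#' @param design_id one of `"original"`, `"d1"`..`"d5"`, `"takara_like"`.
#'   Designs d1--d5 share the 13-bp adapter prefix and differ only in the
#'   number of random bases (5--9).
#' @return an object of class `primer_design` with fields `design_id`,
#'   `constant_prefix`, `n_random`, `anchor_tails` and `prefix_alphabet`.
#' @examples
#' d <- make_primer_design("d2")
#' d$n_random     # 6
#' d$anchor_tails # "GGG" "TTT"
#' @export
make_primer_design <- function(design_id) {
  if (length(design_id) != 1L || !design_id %in% names(.PRIMER_DESIGNS)) {
    stopf("unknown design_id %s; valid ids: %s",
          deparse(substitute(design_id)),
          paste(names(.PRIMER_DESIGNS), collapse = ", "))
  }
  base <- .PRIMER_DESIGNS[[design_id]]
  structure(
    list(design_id = design_id,
         constant_prefix = base$constant_prefix,
         n_random = base$n_random,
         anchor_tails = if (design_id == "takara_like") character(0) else c("GGG", "TTT"),
         prefix_alphabet = if (design_id == "takara_like") c("G", "T") else DNA_BASES),
    class = "primer_design")
}

#' @export
print.primer_design <- function(x, ...) {
  cat(sprintf("primer design '%s': prefix %s + N%d + {%s}\n",
              x$design_id,
              if (nzchar(x$constant_prefix)) x$constant_prefix else "<none>",
              x$n_random,
              if (length(x$anchor_tails)) paste(x$anchor_tails, collapse = ",")
              else paste(x$prefix_alphabet, collapse = "/")))
  invisible(x)
}

#' Simulate sequencing-read prefixes for a primer design
#'
#' Draws the first `n_random + 3` cycles of a read as the library chemistry
#' produces them: `n_random` i.i.d. uniform bases followed by one anchor
#' tail (`GGG` or `TTT`) chosen with probability 1/2 each.  The
#' `takara_like` design instead draws every position uniformly from
#' `{G, T}`.
#'
#' @param design a [make_primer_design()] object.
#' @param n number of prefixes to draw.
#' @param seed optional integer seed for reproducibility.
#' @return character vector of `n` prefixes, each of length `n_random + 3`.
#' @export
simulate_read_prefix <- function(design, n = 1L, seed = NULL) {
  stopifnot(inherits(design, "primer_design"), n >= 1L)
  set_seed_if(seed)
  len <- design$n_random + 3L
  if (design$design_id == "takara_like") {
    mat <- matrix(sample(design$prefix_alphabet, n * len, replace = TRUE),
                  nrow = n)
    return(apply(mat, 1L, paste0, collapse = ""))
  }
  rand <- matrix(sample(DNA_BASES, n * design$n_random, replace = TRUE),
                 nrow = n)
  tails <- sample(design$anchor_tails, n, replace = TRUE)
  paste0(apply(rand, 1L, paste0, collapse = ""), tails)
}

#' Per-cycle base composition of read prefixes
#'
#' Tallies the fraction of A/C/G/T at each of the first `k` sequencing
#' cycles over a set of read prefixes, the quantity the sequencer's cluster
#' recognition depends on.
#'
#' @param prefixes character vector of nucleotide strings, each of length
#'   at least `k`.
#' @param k number of leading cycles to audit (1-based cycles `1..k`).
#' @return a `composition_matrix`: a `k x 4` numeric matrix of fractions
#'   with columns `A,C,G,T`, rows summing to 1; attribute `n` records the
#'   number of prefixes tallied.
#' @export
base_composition <- function(prefixes, k) {
  if (length(prefixes) == 0L) stopf("base_composition: empty prefix set")
  stopifnot(k >= 1L)
  if (any(nchar(prefixes) < k)) {
    stopf("base_composition: all prefixes must have length >= k = %d", k)
  }
  mat <- matrix(unlist(strsplit(substr(prefixes, 1L, k), "", fixed = TRUE),
                       use.names = FALSE),
                ncol = k, byrow = TRUE)
  bad <- matrix(!(mat %in% DNA_BASES), nrow = nrow(mat))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stopf("base_composition: non-ACGT character '%s' in prefix %d at position %d",
          mat[idx[1L], idx[2L]], idx[1L], idx[2L])
  }
  freq <- t(vapply(seq_len(k), function(p) {
    tab <- table(factor(mat[, p], levels = DNA_BASES))
    as.numeric(tab) / nrow(mat)
  }, numeric(4L)))
  dimnames(freq) <- list(position = seq_len(k), base = DNA_BASES)
  structure(freq, n = length(prefixes), class = c("composition_matrix", "matrix"))
}

#' Audit the base diversity of leading sequencing cycles
#'
#' A cycle passes when each of the four bases reaches at least `min_frac` of
#' reads; the library passes when every audited cycle passes.  A library
#' whose leading cycles fail this audit would need a random spike-in to
#' sequence reliably; the N-run primer designs are built to pass it.
#'
#' @param m a [base_composition()] matrix.
#' @param min_frac minimum per-base fraction required at each position, in
#'   `[0, 0.25]`.  The default 0.10 mirrors the conventional minimum random
#'   spike-in fraction (at least 10% of reads) that rescues low-diversity
#'   libraries.
#' @return a `diversity_audit`: data frame with columns `position`, `A`,
#'   `C`, `G`, `T`, `pass`, plus attributes `overall` (logical) and
#'   `min_frac`.
#' @export
diversity_check <- function(m, min_frac = 0.10) {
  stopifnot(inherits(m, "composition_matrix"),
            min_frac >= 0, min_frac <= 0.25)
  pass <- apply(m, 1L, function(row) all(row >= min_frac))
  out <- data.frame(position = seq_len(nrow(m)),
                    A = m[, "A"], C = m[, "C"], G = m[, "G"], T = m[, "T"],
                    pass = as.logical(pass), row.names = NULL)
  structure(out, overall = all(pass), min_frac = min_frac,
            class = c("diversity_audit", "data.frame"))
}

#' @export
print.diversity_audit <- function(x, ...) {
  cat(sprintf("diversity audit over %d cycles (min_frac = %.2f): %s\n",
              nrow(x), attr(x, "min_frac"),
              if (attr(x, "overall")) "PASS" else "FAIL"))
  print.data.frame(cbind(x[1L], round(x[2:5], 4L), x[6L]), row.names = FALSE)
  invisible(x)
}

#' Write / read a diversity audit as TSV
#'
#' Plain-text persistence of the per-cycle composition audit: columns
#' `position, A, C, G, T, pass`.
#'
#' @param audit a [diversity_check()] result.
#' @param path output path.
#' @export
write_diversity_audit <- function(audit, path) {
  stopifnot(inherits(audit, "diversity_audit"))
  write.table(as.data.frame(audit), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diversity_audit
#' @export
read_diversity_audit <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("position", "A", "C", "G", "T", "pass") %in% names(df)))
  structure(df, overall = all(df$pass), min_frac = NA_real_,
            class = c("diversity_audit", "data.frame"))
}
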