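# GC-bias correction in 1%-GC strata and the relative read number (RRN).
#
# Amplified single-cell read depth depends strongly and unimodally on a
# bin's GC fraction.  The correction is non-parametric: bins are stratified
# by floor(gc * 100) (one stratum per 1% of GC), each stratum's counts are
# rescaled by (global autosomal median) / (stratum median), and sparse
# strata are merged into their nearest populated neighbour before medians
# are taken.  Median ratios are robust at the few-thousand-bin resolution
# of 200 kb / 1 Mb grids, where fitted curves would chase noise in the GC
# tails.  The reference median uses autosomes only: sex-chromosome depth
# depends on the sample's sex and must not distort the correction.

#' Correct per-bin counts for GC bias in 1%-GC strata
#'
#' @param profile a [bin_profile()] with `raw_count` and `gc` filled.
#' @param min_bins_per_stratum strata with fewer unmasked autosomal bins
#'   than this are merged with the nearest populated stratum (ties broken
#'   toward lower GC) before correction factors are computed (default 5).
#' @return the profile with `corrected` filled on unmasked bins (masked
#'   bins untouched) and the fitted model attached as attribute
#'   `gc_model`; retrieve it with [gc_model()].
#' @seealso [compute_rrn()]
#' @export
gc_correct <- function(profile, min_bins_per_stratum = 5L) {
  stopifnot(inherits(profile, "bin_profile"), min_bins_per_stratum >= 1L)
  un <- !profile$mask
  auto <- un & is_autosome(profile$chrom)
  if (!any(auto)) stopf("gc_correct: no unmasked autosomal bins")
  global_med <- median(profile$raw_count[auto])
  if (global_med <= 0) {
    stopf("gc_correct: global autosomal median count is zero; increase depth (or simulated total_reads)")
  }

  stratum <- ifelse(un, pmin(floor(profile$gc * 100), 100L), NA_integer_)
  auto_tab <- table(stratum[auto])
  present <- sort(unique(stratum[un]))
  n_auto <- setNames(rep(0L, length(present)), present)
  n_auto[names(auto_tab)] <- as.integer(auto_tab)

  populated <- as.integer(names(n_auto)[n_auto >= min_bins_per_stratum])
  if (length(populated) == 0L) {
    # every stratum sparse: collapse onto the best-populated one
    populated <- as.integer(names(n_auto)[which.max(n_auto)])
  }
  # merge map: every present stratum -> nearest populated (ties to lower GC)
  merged_into <- vapply(present, function(s) {
    d <- abs(populated - s)
    cand <- populated[d == min(d)]
    min(cand)
  }, integer(1L))
  names(merged_into) <- present

  eff <- merged_into[as.character(stratum[un])]
  # per effective stratum: median of autosomal unmasked raw counts
  eff_auto <- merged_into[as.character(stratum[auto])]
  med <- tapply(profile$raw_count[auto], eff_auto, median)
  factor_tab <- global_med / med
  bad <- !is.finite(factor_tab) | factor_tab <= 0
  if (any(bad)) {
    warnf("gc_correct: %d stratum/strata with zero median left uncorrected", sum(bad))
    factor_tab[bad] <- 1
  }
  # strata present only on sex chromosomes fall back to the nearest stratum
  # that has an autosomal median
  have <- as.integer(names(factor_tab))
  fac_of <- function(s) {
    d <- abs(have - s)
    factor_tab[[as.character(min(have[d == min(d)]))]]
  }
  fac <- vapply(eff, fac_of, numeric(1L))
  profile$corrected[un] <- profile$raw_count[un] * fac

  model <- data.frame(
    stratum = present,
    n_bins = as.integer(n_auto),
    median = as.numeric(vapply(as.character(merged_into), function(s) {
      if (s %in% names(med)) med[[s]] else NA_real_
    }, numeric(1L))),
    factor = vapply(merged_into, fac_of, numeric(1L)),
    merged_into = as.integer(merged_into),
    row.names = NULL)
  attr(profile, "gc_model") <- structure(model,
                                         global_median = global_med,
                                         class = c("gc_model", "data.frame"))
  profile
}

#' Retrieve the GC model fitted by [gc_correct()]
#'
#' @param profile a corrected [bin_profile()].
#' @return a `gc_model` data frame: `stratum` (1% GC bin index), `n_bins`
#'   (unmasked autosomal bins), `median` (pooled raw-count median of the
#'   effective stratum), `factor` (multiplicative correction), and
#'   `merged_into` (effective stratum after sparse-stratum merging).
#' @export
gc_model <- function(profile) {
  m <- attr(profile, "gc_model")
  if (is.null(m)) stopf("profile has no GC model; run gc_correct() first")
  m
}

#' Write a GC model as TSV
#'
#' Columns: `stratum, n_bins, median, factor, merged_into`.
#' @param model a [gc_model()] data frame.
#' @param path file path.
#' @export
write_gc_model <- function(model, path) {
  write.table(as.data.frame(model), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compute the GC-corrected relative read number (RRN)
#'
#' RRN rescales corrected counts so that the mean over unmasked autosomal
#' bins is exactly 2 — the diploid copy number.  A bin's RRN is therefore
#' directly interpretable as its copy number: disomic bins sit near 2,
#' trisomic near 3, monosomic near 1; the X and Y of a male profile sit
#' near 1.  Sex-chromosome bins share the autosomal scaling.
#'
#' @param profile a [bin_profile()] with `corrected` filled (see
#'   [gc_correct()]).
#' @return the profile with `rrn` filled on unmasked bins.
#' @export
compute_rrn <- function(profile) {
  stopifnot(inherits(profile, "bin_profile"))
  un <- !profile$mask
  auto <- un & is_autosome(profile$chrom)
  if (!any(auto) || !any(is.finite(profile$corrected[auto]))) {
    stopf("compute_rrn: corrected counts missing; run gc_correct() first")
  }
  m <- mean(profile$corrected[auto])
  if (!is.finite(m) || m <= 0) stopf("compute_rrn: autosomal mean of corrected counts is zero")
  profile$rrn[un] <- 2 * profile$corrected[un] / m
  profile
}
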