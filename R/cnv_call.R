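# Whole-chromosome copy-number summaries and aneuploidy calls.
#
# Chromosome copy number is the median RRN over the chromosome's unmasked
# bins; autosomes are called gained at >= gain_threshold and lost at
# <= loss_threshold (defaults 2.5 / 1.5, the midpoints between integer copy
# states).  Sex chromosomes are judged against a sex-inferred baseline
# (XX: X ~ 2, Y ~ 0; XY: X ~ 1, Y ~ 1) and deviations are flagged rather
# than silently dropped.

#' Per-chromosome copy number from a bin profile
#'
#' @param profile a [bin_profile()] with `rrn` filled.
#' @param min_bins_for_call chromosomes with fewer unmasked bins are
#'   flagged no-call (default 10).
#' @return a `chrom_calls` data frame: `chrom`, `n_unmasked_bins`,
#'   `median_rrn`, `is_sex_chrom`, `no_call`.
#' @export
chrom_copy_number <- function(profile, min_bins_for_call = 10L) {
  stopifnot(inherits(profile, "bin_profile"))
  if (!any(is.finite(profile$rrn))) stopf("chrom_copy_number: rrn not filled; run compute_rrn() first")
  chroms <- as.character(unique(profile$chrom))
  rows <- lapply(chroms, function(ch) {
    sel <- profile$chrom == ch & !profile$mask
    n <- sum(sel)
    data.frame(chrom = ch,
               n_unmasked_bins = n,
               median_rrn = if (n > 0L) median(profile$rrn[sel]) else NA_real_,
               is_sex_chrom = !is_autosome(ch),
               no_call = n < min_bins_for_call)
  })
  out <- do.call(rbind, rows)
  out$chrom <- chrom_factor(out$chrom)
  out <- out[order(out$chrom), ]
  rownames(out) <- NULL
  structure(out, class = c("chrom_calls", "data.frame"))
}

#' Call whole-chromosome aneuploidy from per-chromosome copy numbers
#'
#' Autosomes: gain iff `median_rrn >= gain_threshold`, loss iff
#' `<= loss_threshold`.  Sex chromosomes are compared against the inferred
#' sex baseline — the sample is taken as XX when the Y median is below 0.5
#' (or Y is no-call and X is near 2), otherwise XY — and a sex chromosome
#' departing from its baseline by 0.5 or more is reported through the
#' `sex_flagged` verdict, never as a silent autosomal-style call.
#' Intermediate (mosaic-like) medians are assigned the nearest state; the
#' raw median is always retained in the output.
#'
#' @param calls a [chrom_copy_number()] result.
#' @param gain_threshold,loss_threshold autosomal call thresholds; must
#'   satisfy `loss_threshold < 2 < gain_threshold` (defaults 2.5 / 1.5).
#' @param segments optional segmental-event table from
#'   [detect_segments()]; any event makes the sample aneuploid.
#' @param sample_name label carried into the verdict.
#' @return a `sample_verdict` list: `sample_name`, `calls` (with a `state`
#'   column: `loss`/`normal`/`gain`/`no_call`), `sex` (`"XX"`/`"XY"`),
#'   `segments`, `overall` (`"euploid"`, `"aneuploid"` or `"sex_flagged"`).
#' @export
call_aneuploidy <- function(calls, gain_threshold = 2.5, loss_threshold = 1.5,
                            segments = NULL, sample_name = "sample") {
  stopifnot(inherits(calls, "chrom_calls"))
  if (!(loss_threshold < 2 && 2 < gain_threshold)) {
    stopf("thresholds must satisfy loss_threshold < 2 < gain_threshold")
  }
  med <- setNames(calls$median_rrn, as.character(calls$chrom))
  x_med <- if ("X" %in% names(med)) med[["X"]] else NA_real_
  y_med <- if ("Y" %in% names(med)) med[["Y"]] else NA_real_
  sex <- if (!is.na(y_med)) {
    if (y_med < 0.5) "XX" else "XY"
  } else if (!is.na(x_med)) {
    if (x_med >= 1.5) "XX" else "XY"
  } else "XX"   # no sex chromosomes in the profile; baseline unused

  baseline <- function(ch) {
    if (ch == "X") return(if (sex == "XX") 2 else 1)
    if (ch == "Y") return(if (sex == "XX") 0 else 1)
    2
  }
  state <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    ch <- as.character(calls$chrom[i])
    if (calls$no_call[i] || !is.finite(calls$median_rrn[i])) {
      state[i] <- "no_call"; next
    }
    b <- baseline(ch)
    m <- calls$median_rrn[i]
    if (calls$is_sex_chrom[i]) {
      state[i] <- if (m >= b + 0.5) "gain" else if (b > 0 && m <= b - 0.5) "loss" else "normal"
    } else {
      state[i] <- if (m >= gain_threshold) "gain" else if (m <= loss_threshold) "loss" else "normal"
    }
  }
  calls$state <- state
  autosomal_hit <- any(!calls$is_sex_chrom & state %in% c("gain", "loss"))
  seg_hit <- !is.null(segments) && nrow(segments) > 0L
  sex_hit <- any(calls$is_sex_chrom & state %in% c("gain", "loss"))
  overall <- if (autosomal_hit || seg_hit) "aneuploid" else if (sex_hit) "sex_flagged" else "euploid"
  structure(list(sample_name = sample_name, calls = calls, sex = sex,
                 segments = segments, overall = overall),
            class = "sample_verdict")
}

#' @export
print.sample_verdict <- function(x, ...) {
  cat(sprintf("sample '%s': %s (inferred sex %s)\n",
              x$sample_name, x$overall, x$sex))
  ab <- x$calls[x$calls$state %in% c("gain", "loss"), ]
  if (nrow(ab)) {
    for (i in seq_len(nrow(ab))) {
      cat(sprintf("  chr%s %s (median RRN %.2f)\n",
                  ab$chrom[i], ab$state[i], ab$median_rrn[i]))
    }
  }
  if (!is.null(x$segments) && nrow(x$segments)) {
    cat(sprintf("  %d segmental event(s)\n", nrow(x$segments)))
  }
  invisible(x)
}

#' Detect sub-chromosomal runs of deviant copy number
#'
#' Scans each chromosome for maximal runs of at least `min_bins`
#' consecutive unmasked bins whose RRN all lie beyond one threshold.
#' Chromosomes whose whole-chromosome median already crosses a threshold
#' are skipped (the event is whole-chromosome, not segmental).
#'
#' @param profile a [bin_profile()] with `rrn` filled.
#' @param min_bins minimum run length in bins (default 10; about 10 Mb at
#'   1 Mb bins).
#' @param gain_threshold,loss_threshold per-bin thresholds (defaults
#'   2.5 / 1.5).
#' @return data frame of events: `chrom`, `start_bin`, `end_bin` (1-based
#'   indices among the chromosome's unmasked bins), `start`, `end`
#'   (base coordinates), `n_bins`, `direction` (`gain`/`loss`),
#'   `median_rrn`.
#' @export
detect_segments <- function(profile, min_bins = 10L,
                            gain_threshold = 2.5, loss_threshold = 1.5) {
  stopifnot(inherits(profile, "bin_profile"))
  events <- list()
  for (ch in as.character(unique(profile$chrom))) {
    sel <- which(profile$chrom == ch & !profile$mask & is.finite(profile$rrn))
    if (length(sel) < min_bins) next
    rr <- profile$rrn[sel]
    chrom_med <- median(rr)
    if (chrom_med >= gain_threshold || chrom_med <= loss_threshold) next
    state <- ifelse(rr >= gain_threshold, "gain",
                    ifelse(rr <= loss_threshold, "loss", "normal"))
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (r$values[j] == "normal" || r$lengths[j] < min_bins) next
      i0 <- sel[starts[j]]; i1 <- sel[ends[j]]
      events[[length(events) + 1L]] <- data.frame(
        chrom = ch, start_bin = starts[j], end_bin = ends[j],
        start = profile$start[i0], end = profile$end[i1],
        n_bins = r$lengths[j], direction = r$values[j],
        median_rrn = median(rr[starts[j]:ends[j]]))
    }
  }
  if (length(events) == 0L) {
    return(data.frame(chrom = character(0), start_bin = integer(0),
                      end_bin = integer(0), start = numeric(0),
                      end = numeric(0), n_bins = integer(0),
                      direction = character(0), median_rrn = numeric(0)))
  }
  do.call(rbind, events)
}

#' Convenience: profile to verdict in one call
#'
#' Runs [chrom_copy_number()], [detect_segments()] and [call_aneuploidy()]
#' with shared thresholds.
#'
#' @inheritParams call_aneuploidy
#' @inheritParams detect_segments
#' @param profile a [bin_profile()] with `rrn` filled.
#' @param min_bins_for_call minimum unmasked bins for a chromosome call.
#' @return a `sample_verdict`.
#' @export
call_sample <- function(profile, gain_threshold = 2.5, loss_threshold = 1.5,
                        min_bins_for_call = 10L, min_bins = 10L,
                        sample_name = "sample") {
  calls <- chrom_copy_number(profile, min_bins_for_call)
  segs <- detect_segments(profile, min_bins, gain_threshold, loss_threshold)
  call_aneuploidy(calls, gain_threshold, loss_threshold,
                  segments = segs, sample_name = sample_name)
}

#' Genome-ordered plot table for a copy-number profile
#'
#' Emits the table behind the per-sample profile figure: unmasked bins in
#' genome order with a running bin index, their RRN, and the chromosome
#' median overlay.  Rendering an image is a thin layer over this table
#' (see [plot.bin_profile()]).
#'
#' @param profile a [bin_profile()] with `rrn` filled.
#' @param calls optional [chrom_copy_number()] result (computed if absent).
#' @return data frame: `bin_index`, `chrom`, `start`, `end`, `rrn`,
#'   `chrom_median`, `chrom_boundary` (logical, first bin of each
#'   chromosome).
#' @export
profile_plot_data <- function(profile, calls = NULL) {
  stopifnot(inherits(profile, "bin_profile"))
  if (is.null(calls)) calls <- chrom_copy_number(profile, min_bins_for_call = 1L)
  keep <- !profile$mask & is.finite(profile$rrn)
  df <- as.data.frame(profile)[keep, c("chrom", "start", "end", "rrn")]
  df <- df[order(chrom_factor(df$chrom), df$start), ]
  df$bin_index <- seq_len(nrow(df))
  med <- setNames(calls$median_rrn, as.character(calls$chrom))
  df$chrom_median <- med[as.character(df$chrom)]
  df$chrom_boundary <- c(TRUE, df$chrom[-1L] != df$chrom[-nrow(df)])
  rownames(df) <- NULL
  df[, c("bin_index", "chrom", "start", "end", "rrn", "chrom_median", "chrom_boundary")]
}

#' Plot a copy-number profile
#'
#' Base-graphics rendering of [profile_plot_data()]: per-bin RRN in genome
#' order (chromosomes 1--22 then X, Y), chromosome boundaries, and the
#' per-chromosome median overlaid, with the y axis on the chromosomal
#' copy-number scale.
#'
#' @param x a [bin_profile()] with `rrn` filled.
#' @param main plot title.
#' @param ylim y-axis range (copy-number scale).
#' @param ... further arguments passed to [plot()].
#' @export
plot.bin_profile <- function(x, main = "copy-number profile", ylim = c(0, 5), ...) {
  pd <- profile_plot_data(x)
  plot(pd$bin_index, pd$rrn, pch = 16, cex = 0.3, col = "grey40",
       xlab = "genomic bin", ylab = "chromosomal copy number",
       main = main, ylim = ylim, xaxt = "n", ...)
  bounds <- pd$bin_index[pd$chrom_boundary]
  abline(v = bounds, col = "grey85")
  abline(h = 2, col = "grey70", lty = 2)
  for (ch in unique(as.character(pd$chrom))) {
    sel <- pd$chrom == ch
    segments(min(pd$bin_index[sel]), pd$chrom_median[sel][1L],
             max(pd$bin_index[sel]), pd$chrom_median[sel][1L],
             col = "red", lwd = 2)
  }
  mids <- tapply(pd$bin_index, as.character(pd$chrom), function(i) mean(range(i)))
  axis(1, at = mids[order(chrom_factor(names(mids)))],
       labels = names(mids)[order(chrom_factor(names(mids)))],
       cex.axis = 0.6, las = 2, tick = FALSE)
  invisible(pd)
}

#' Write per-chromosome calls as TSV and a JSON verdict summary
#'
#' @param verdict a `sample_verdict`.
#' @param tsv_path,json_path output paths (either may be `NULL` to skip).
#' @export
write_verdict <- function(verdict, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(verdict, "sample_verdict"))
  if (!is.null(tsv_path)) {
    df <- data.frame(sample = verdict$sample_name,
                     chrom = as.character(verdict$calls$chrom),
                     median_rrn = verdict$calls$median_rrn,
                     state = verdict$calls$state)
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(sample = verdict$sample_name, overall = verdict$overall,
           sex = verdict$sex,
           calls = data.frame(chrom = as.character(verdict$calls$chrom),
                              median_rrn = verdict$calls$median_rrn,
                              state = verdict$calls$state),
           segments = verdict$segments),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(verdict)
}
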