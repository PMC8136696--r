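# Per-sample and cohort QC: read-fate rates, cohort coefficient of
# variation (the uniformity measure for equal-volume library pooling), and
# the minimum-read adequacy check.

#' Per-sample sequencing QC rates
#'
#' From the raw / high-quality / mapped / unique read counts of one sample,
#' derives the standard read-fate rates: high-quality-of-raw, mapping rate
#' (mapped / high-quality), mapped-of-raw and unique-of-raw, all in percent
#' rounded to 2 decimals; raw counts are preserved unrounded.  The counts
#' must be nested: `unique <= mapped <= hq <= raw`.
#'
#' @param sample_name sample label.
#' @param raw_reads,hq_reads,mapped_reads,unique_reads read counts.
#' @param gc_pct mean GC percent of high-quality reads (reported 0 d.p.).
#' @return a `sample_qc` one-row data frame with counts and rates.
#' @export
sample_qc <- function(sample_name, raw_reads, hq_reads, mapped_reads,
                      unique_reads, gc_pct = NA_real_) {
  if (raw_reads <= 0) stopf("sample_qc: raw_reads must be positive")
  if (!(unique_reads <= mapped_reads && mapped_reads <= hq_reads &&
        hq_reads <= raw_reads && unique_reads >= 0)) {
    stopf("sample_qc: counts must satisfy 0 <= unique <= mapped <= hq <= raw")
  }
  structure(data.frame(
    sample_name = sample_name,
    raw_reads = raw_reads, hq_reads = hq_reads,
    mapped_reads = mapped_reads, unique_reads = unique_reads,
    gc_pct = round(gc_pct),
    hq_of_raw = round(100 * hq_reads / raw_reads, 2L),
    mapping_rate = round(100 * mapped_reads / hq_reads, 2L),
    mapped_of_raw = round(100 * mapped_reads / raw_reads, 2L),
    unique_of_raw = round(100 * unique_reads / raw_reads, 2L)),
    class = c("sample_qc", "data.frame"))
}

#' Cohort coefficient of variation (percent)
#'
#' `CV = 100 * sd(x) / mean(x)` with the sample (n-1) standard deviation —
#' the library-yield uniformity statistic reported for equal-volume pooled
#' sequencing runs.
#'
#' @param values positive numeric vector, length at least 2.
#' @return CV in percent.
#' @export
cohort_cv <- function(values) {
  if (length(values) < 2L) stopf("cohort_cv: need at least 2 values")
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stopf("cohort_cv: mean must be positive")
  100 * sd(values) / m
}

#' Minimum-read adequacy check
#'
#' A sample passes when its raw read count reaches `threshold`.  The
#' default of 500,000 reads is the working minimum for confident
#' genome-wide whole-chromosome aneuploidy screening at 1 Mb bins.
#'
#' @param samples a `sample_qc`-style data frame with a `raw_reads` column,
#'   or a numeric vector of raw read counts.
#' @param threshold minimum raw reads (default 5e5).
#' @return named logical vector, `TRUE` = pass.
#' @export
min_reads_check <- function(samples, threshold = 5e5) {
  stopifnot(threshold >= 0)
  if (is.data.frame(samples)) {
    setNames(samples$raw_reads >= threshold,
             if (!is.null(samples$sample_name)) samples$sample_name else samples$sample)
  } else {
    samples >= threshold
  }
}

#' Read a QC table (one row per sample)
#'
#' Reads the TSV layout used by the bundled run fixtures and by
#' [write_qc_report()]: columns `sample`/`sample_name`, `raw_reads`,
#' `gc_pct`, `hq_of_raw`, `mapping_rate`, `mapped_of_raw`, optionally
#' `unique_reads`, and `unique_of_raw`.
#'
#' @param path TSV path; the two bundled fixtures are available as
#'   `system.file("extdata", "qc_lymphocyte_run.tsv", package = "chrominst")`
#'   (15 single lymphocytes, one MiSeq run) and `"qc_embryo_run.tsv"`
#'   (14 embryo biopsies plus negative and positive controls).
#' @return data frame.
#' @export
read_qc_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if ("sample" %in% names(df) && !"sample_name" %in% names(df)) {
    names(df)[names(df) == "sample"] <- "sample_name"
  }
  df$sample_name <- as.character(df$sample_name)
  df
}

#' Cohort QC summary with CV footer
#'
#' Computes the per-metric cohort coefficient of variation across the
#' included samples.  Control samples can be excluded by name (a negative
#' control's near-empty library would otherwise dominate every CV).
#'
#' @param qc QC data frame (see [read_qc_table()]).
#' @param exclude sample names excluded from the CV row (default none).
#' @param metrics columns to summarize; defaults to every numeric column.
#' @return list with `qc` (included rows), `cv` (named numeric, percent)
#'   and `excluded` (character).
#' @export
cohort_qc <- function(qc, exclude = character(0), metrics = NULL) {
  inc <- !(qc$sample_name %in% exclude)
  if (sum(inc) < 2L) stopf("cohort_qc: need at least 2 included samples")
  if (is.null(metrics)) {
    metrics <- names(qc)[vapply(qc, is.numeric, logical(1L))]
  }
  cv <- vapply(metrics, function(m) cohort_cv(qc[[m]][inc]), numeric(1L))
  list(qc = qc[inc, , drop = FALSE], cv = cv, excluded = qc$sample_name[!inc])
}

#' Write a QC report as TSV with a CV footer row
#'
#' @param qc QC data frame.
#' @param path output TSV.
#' @param exclude sample names excluded from the CV row.
#' @export
write_qc_report <- function(qc, path, exclude = character(0)) {
  cq <- cohort_qc(qc, exclude)
  out <- qc
  footer <- as.list(rep(NA, ncol(out)))
  names(footer) <- names(out)
  footer$sample_name <- if (length(exclude)) {
    sprintf("CV (except %s)", paste(exclude, collapse = ","))
  } else "CV"
  for (m in names(cq$cv)) footer[[m]] <- round(cq$cv[[m]], 1L)
  out <- rbind(out, as.data.frame(footer, stringsAsFactors = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
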