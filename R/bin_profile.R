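# Genome binning: fixed-width grids, unique-read filtering, per-bin read
# counts and GC fractions.  Coordinates are 0-based half-open throughout;
# SAM/BAM input (1-based) is converted on read.

#' Read a chromosome-size table
#'
#' @param path 2-column TSV (`chrom`, `length`); a header row is detected.
#' @return named numeric vector of chromosome lengths in canonical order
#'   (1..22, X, Y, then others).
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("chrom", "length") %in% names(df))) {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(df)[1:2] <- c("chrom", "length")
  }
  lens <- setNames(as.numeric(df$length), norm_chrom(df$chrom))
  lens[order(chrom_factor(names(lens)))]
}

#' Chromosome sizes of the hg19 human reference
#'
#' Convenience accessor for the bundled hg19 chromosome-length table
#' (chromosomes 1--22, X, Y), used for genome-scale simulations.
#'
#' @return named numeric vector of lengths.
#' @export
hg19_chrom_sizes <- function() {
  read_chrom_sizes(system.file("extdata", "hg19_chrom_sizes.tsv",
                               package = "chrominst", mustWork = TRUE))
}

#' Partition a genome into fixed-width bins
#'
#' Each chromosome is tiled with `ceil(length / bin_size)` half-open
#' intervals `[i*bin_size, min((i+1)*bin_size, length))`; the terminal bin
#' may be shorter.  Terminal bins shorter than 25% of `bin_size` are
#' flagged `short` and masked downstream, so depressed counts at
#' chromosome ends cannot bias chromosome medians.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bases).
#' @param bin_size bin width in bases (200 kb and 1 Mb are the usual
#'   choices for shallow single-cell profiles).
#' @return a `bin_grid`: data frame with columns `chrom` (ordered factor),
#'   `start`, `end`, `width`, `short`; attribute `bin_size`.
#' @export
make_bin_grid <- function(chrom_lengths, bin_size = 1e6) {
  if (length(chrom_lengths) == 0L) stopf("empty chromosome table")
  stopifnot(bin_size > 0, all(chrom_lengths > 0), !is.null(names(chrom_lengths)))
  chroms <- norm_chrom(names(chrom_lengths))
  rows <- lapply(seq_along(chroms), function(i) {
    len <- chrom_lengths[[i]]
    n <- ceiling(len / bin_size)
    start <- (seq_len(n) - 1) * bin_size
    end <- pmin(start + bin_size, len)
    data.frame(chrom = chroms[i], start = start, end = end)
  })
  grid <- do.call(rbind, rows)
  grid$chrom <- chrom_factor(grid$chrom)
  grid$width <- grid$end - grid$start
  grid$short <- grid$width < 0.25 * bin_size
  structure(grid, bin_size = bin_size, class = c("bin_grid", "data.frame"))
}

#' Read alignments from SAM/BAM or a bed-like TSV
#'
#' SAM/BAM files are read through Rsamtools (SAM is converted to BAM in a
#' temporary file first); 1-based leftmost positions become 0-based starts
#' and flag bits are decoded.  A `.bed`/`.tsv` file is read as four
#' headerless columns `chrom, start, end, mapq` with 0-based half-open
#' coordinates used as-is, all reads treated as mapped primary
#' non-duplicates.
#'
#' @param path alignment file (`.sam`, `.bam`, `.bed` or `.tsv`).
#' @return data frame of aligned reads: `chrom`, `start` (0-based), `mapq`,
#'   `unmapped`, `secondary`, `supplementary`, `duplicate`.
#' @export
read_alignments <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sam", "bam")) {
    bam <- path
    if (ext == "sam") {
      bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                              indexDestination = FALSE)
    }
    res <- Rsamtools::scanBam(bam,
      param = Rsamtools::ScanBamParam(what = c("rname", "pos", "mapq", "flag")))[[1L]]
    flag <- res$flag
    data.frame(chrom = norm_chrom(as.character(res$rname)),
               start = ifelse(is.na(res$pos), NA_real_, res$pos - 1),
               mapq = ifelse(is.na(res$mapq), 0L, res$mapq),
               unmapped = bitwAnd(flag, 4L) > 0L,
               secondary = bitwAnd(flag, 256L) > 0L,
               supplementary = bitwAnd(flag, 2048L) > 0L,
               duplicate = bitwAnd(flag, 1024L) > 0L,
               stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    stopifnot(ncol(df) >= 4L)
    data.frame(chrom = norm_chrom(df[[1L]]), start = as.numeric(df[[2L]]),
               mapq = as.integer(df[[4L]]),
               unmapped = FALSE, secondary = FALSE,
               supplementary = FALSE, duplicate = FALSE,
               stringsAsFactors = FALSE)
  }
}

#' Extract unique mapped reads
#'
#' Retains reads that are mapped, primary, non-supplementary,
#' non-duplicate, and have mapping quality at least `mapq_min` — the
#' "unique mapped" reads counted per bin.  Also reports the primary mapped
#' count before the mapq/duplicate filter, as used in QC rates.
#'
#' @param reads aligned-read data frame (see [read_alignments()]); missing
#'   flag columns default to `FALSE`.
#' @param mapq_min minimum mapping quality (default 1).
#' @return list with `reads` (retained), `mapped` (primary mapped count)
#'   and `unique` (retained count).
#' @export
filter_unique <- function(reads, mapq_min = 1L) {
  stopifnot(mapq_min >= 0L)
  for (col in c("unmapped", "secondary", "supplementary", "duplicate")) {
    if (is.null(reads[[col]])) reads[[col]] <- FALSE
  }
  primary <- !reads$unmapped & !reads$secondary & !reads$supplementary
  keep <- primary & !reads$duplicate & reads$mapq >= mapq_min
  list(reads = reads[keep, , drop = FALSE],
       mapped = sum(primary),
       unique = sum(keep))
}

#' Count reads per bin
#'
#' Each read is assigned to exactly one bin by its 0-based leftmost mapped
#' coordinate (half-open bins, so a start exactly at a boundary falls in
#' the following bin).  Reads on chromosomes absent from the grid are
#' tallied as discarded with a single warning.
#'
#' @param reads filtered aligned-read data frame.
#' @param grid a [make_bin_grid()] grid.
#' @return integer vector of per-bin counts, one per grid row, with
#'   attribute `discarded` (reads on unknown chromosomes).
#' @export
count_bins <- function(reads, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  bin_size <- attr(grid, "bin_size")
  chrom <- norm_chrom(reads$chrom)
  known <- chrom %in% as.character(unique(grid$chrom))
  if (any(!known)) {
    warnf("count_bins: %d read(s) on chromosomes absent from the grid were discarded",
          sum(!known))
  }
  counts <- integer(nrow(grid))
  if (any(known)) {
    key <- paste0(grid$chrom, ":", grid$start %/% bin_size)
    rkey <- paste0(chrom[known], ":", floor(reads$start[known] / bin_size))
    idx <- match(rkey, key)
    bad <- is.na(idx)
    if (any(bad)) {
      # starts beyond the chromosome's last bin: should not occur for valid input
      warnf("count_bins: %d read(s) beyond chromosome bounds discarded", sum(bad))
    }
    tab <- tabulate(idx[!bad], nbins = nrow(grid))
    counts <- as.integer(tab)
    attr(counts, "discarded") <- sum(!known) + sum(bad)
  } else {
    attr(counts, "discarded") <- sum(!known)
  }
  counts
}

#' Per-bin GC fraction from a reference sequence
#'
#' GC fraction is `(G + C) / (A + C + G + T)` over the bin; bins whose
#' N-fraction exceeds `max_n_frac`, or with no counted bases at all, are
#' masked.
#'
#' @param reference a named `DNAStringSet` (names are chromosomes) or a
#'   FASTA path.
#' @param grid a [make_bin_grid()] grid; every grid chromosome must be
#'   present in the reference.
#' @return list with `gc` (numeric per bin, `NA` where masked) and `mask`
#'   (logical per bin, `TRUE` = masked).
#' @export
bin_gc <- function(reference, grid, max_n_frac = 0.2) {
  stopifnot(inherits(grid, "bin_grid"))
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  names(reference) <- norm_chrom(names(reference))
  missing <- setdiff(as.character(unique(grid$chrom)), names(reference))
  if (length(missing)) {
    stopf("reference is missing chromosome(s): %s", paste(missing, collapse = ", "))
  }
  gc <- numeric(nrow(grid))
  nfrac <- numeric(nrow(grid))
  for (ch in as.character(unique(grid$chrom))) {
    rows <- which(grid$chrom == ch)
    v <- Biostrings::Views(reference[[ch]],
                           start = grid$start[rows] + 1L,
                           end = grid$end[rows])
    counts <- Biostrings::letterFrequency(v, c("A", "C", "G", "T", "N"))
    acgt <- rowSums(counts[, 1:4, drop = FALSE])
    gc[rows] <- ifelse(acgt > 0, rowSums(counts[, c("C", "G"), drop = FALSE]) / acgt, NA_real_)
    nfrac[rows] <- counts[, "N"] / grid$width[rows]
  }
  mask <- is.na(gc) | nfrac > max_n_frac
  gc[mask] <- NA_real_
  list(gc = gc, mask = mask)
}

#' Assemble a per-bin read-depth profile
#'
#' Combines a bin grid with raw counts, GC fractions and a mask into the
#' central container of the pipeline.  Masked bins (N-rich or short
#' terminal bins) are excluded from every downstream statistic.  The
#' `corrected` and `rrn` columns are filled by [gc_correct()] and
#' [compute_rrn()].
#'
#' @param grid a [make_bin_grid()] grid.
#' @param raw_count integer per-bin counts (see [count_bins()] or
#'   [simulate_bin_counts()]).
#' @param gc per-bin GC fraction (`NA` allowed on masked bins).
#' @param mask optional extra logical mask; combined with the grid's
#'   short-bin flag and missing GC.
#' @return a `bin_profile`: data frame with columns `chrom`, `start`,
#'   `end`, `width`, `gc`, `raw_count`, `mask`, `corrected`, `rrn`;
#'   attribute `bin_size`.
#' @export
bin_profile <- function(grid, raw_count, gc, mask = NULL) {
  stopifnot(inherits(grid, "bin_grid"),
            length(raw_count) == nrow(grid),
            length(gc) == nrow(grid),
            all(raw_count >= 0, na.rm = TRUE))
  m <- grid$short | is.na(gc)
  if (!is.null(mask)) m <- m | mask
  out <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                    width = grid$width, gc = gc,
                    raw_count = as.numeric(raw_count), mask = m,
                    corrected = NA_real_, rrn = NA_real_)
  structure(out, bin_size = attr(grid, "bin_size"),
            class = c("bin_profile", "data.frame"))
}

#' Write / read a bin profile as TSV
#'
#' Columns: `chrom, start, end, width, gc, raw_count, mask, corrected, rrn`.
#'
#' @param profile a [bin_profile()].
#' @param path file path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "bin_profile"))
  df <- as.data.frame(profile)
  df$chrom <- as.character(df$chrom)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "gc", "raw_count", "mask") %in% names(df)))
  df$chrom <- chrom_factor(df$chrom)
  if (is.null(df$width)) df$width <- df$end - df$start
  if (is.null(df$corrected)) df$corrected <- NA_real_
  if (is.null(df$rrn)) df$rrn <- NA_real_
  bin_size <- max(df$width)
  structure(df, bin_size = bin_size, class = c("bin_profile", "data.frame"))
}
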