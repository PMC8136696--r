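# Synthetic data with known ground truth: toy references, overdispersed
# bin counts under planted karyotypes and GC bias, cohorts, and
# library-structured FASTQ with true-position records.
#
# The count model: a bin's expected depth is proportional to
# (copy_number / 2) * bin_width * g(gc), with a unimodal multiplicative
# GC-bias curve g(gc) = exp(-(gc - mu)^2 / (2 sigma^2)), normalized so the
# expectations sum to the sample's total read count; observed counts are
# negative-binomial with that mean and size (dispersion) r, emulating the
# super-Poisson noise of MALBAC-amplified read depth.  Defaults mu = 0.45,
# sigma = 0.12, r = 20 give a per-bin CV of roughly 0.22 at 1 Mb bins and
# 500K reads, at which integer copy states separate cleanly.

#' Simulation parameters
#'
#' @param total_reads reads to distribute over bins (default 1e6; real
#'   per-sample totals in a pooled overnight run span roughly 0.5--2.5 M).
#' @param bin_size bin width in bases (default 1e6).
#' @param gc_mu,gc_sigma mode and width of the unimodal GC-bias curve
#'   (defaults 0.45 and 0.12).
#' @param dispersion negative-binomial size parameter r; larger is closer
#'   to Poisson (default 20).
#' @param unique_fraction,hq_fraction fractions of raw reads surviving to
#'   unique-mapped and high-quality, used when deriving QC-style counts
#'   from simulations (defaults 0.8 and 0.96).
#' @param seed optional integer seed.
#' @return a `sim_params` list.
#' @export
sim_params <- function(total_reads = 1e6, bin_size = 1e6,
                       gc_mu = 0.45, gc_sigma = 0.12, dispersion = 20,
                       unique_fraction = 0.8, hq_fraction = 0.96,
                       seed = NULL) {
  stopifnot(total_reads > 0, bin_size > 0, gc_sigma > 0, dispersion > 0,
            unique_fraction > 0, unique_fraction <= 1,
            hq_fraction > 0, hq_fraction <= 1)
  structure(list(total_reads = total_reads, bin_size = bin_size,
                 gc_mu = gc_mu, gc_sigma = gc_sigma,
                 dispersion = dispersion,
                 unique_fraction = unique_fraction,
                 hq_fraction = hq_fraction, seed = seed),
            class = "sim_params")
}

#' Karyotype specification
#'
#' Per-chromosome integer copy numbers with optional segmental events.
#' Autosomes default to 2 copies; X and Y follow the declared sex.
#'
#' @param sex `"XX"` or `"XY"`.
#' @param gains,losses chromosome names gaining / losing one whole copy
#'   (e.g. `gains = "21"` for trisomy 21).
#' @param copies optional named vector of explicit copy numbers overriding
#'   the above.
#' @param segments optional data frame of segmental events with columns
#'   `chrom`, `start`, `end` (bases, 0-based half-open) and `cn`;
#'   segments must lie within chromosome bounds and not overlap on a
#'   chromosome.
#' @param chroms chromosome set (default 1..22, X, Y).
#' @return a `karyotype_spec` list with `copies` (named integer vector),
#'   `segments` and `sex`.
#' @export
karyotype_spec <- function(sex = c("XX", "XY"), gains = NULL, losses = NULL,
                           copies = NULL, segments = NULL,
                           chroms = CHROM_LEVELS) {
  sex <- match.arg(sex)
  cn <- setNames(rep(2L, length(chroms)), chroms)
  if ("X" %in% chroms) cn[["X"]] <- if (sex == "XX") 2L else 1L
  if ("Y" %in% chroms) cn[["Y"]] <- if (sex == "XX") 0L else 1L
  for (g in norm_chrom(gains)) cn[[g]] <- cn[[g]] + 1L
  for (l in norm_chrom(losses)) cn[[l]] <- cn[[l]] - 1L
  if (!is.null(copies)) cn[norm_chrom(names(copies))] <- as.integer(copies)
  if (any(cn < 0L)) stopf("karyotype_spec: copy numbers must be >= 0")
  if (!is.null(segments)) {
    stopifnot(all(c("chrom", "start", "end", "cn") %in% names(segments)))
    segments$chrom <- norm_chrom(segments$chrom)
    if (any(segments$cn < 0)) stopf("karyotype_spec: segment copy numbers must be >= 0")
    for (ch in unique(segments$chrom)) {
      s <- segments[segments$chrom == ch, ]
      s <- s[order(s$start), ]
      if (any(s$start >= s$end)) stopf("karyotype_spec: empty segment on chr%s", ch)
      if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)])) {
        stopf("karyotype_spec: overlapping segments on chr%s", ch)
      }
    }
  }
  structure(list(copies = cn, segments = segments, sex = sex),
            class = "karyotype_spec")
}

#' Generate a toy reference genome with controlled GC content
#'
#' Per chromosome, bases are drawn i.i.d. with `P(G) = P(C) = gc/2` where
#' the target `gc` is constant, or varies linearly along the chromosome
#' when a `c(from, to)` gradient is given.  Realized per-bin GC then
#' tracks the target to within binomial noise (about +/- 0.03 at 200 kb).
#'
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param gc_profile a single GC target in (0,1) for all chromosomes, a
#'   per-chromosome named vector, or a length-2 vector `c(from, to)` for a
#'   genome-wide linear gradient along each chromosome.
#' @param seed integer seed (the sequence is a pure function of seed and
#'   arguments).
#' @return list with `sequences` (named `DNAStringSet`) and `chrom_sizes`
#'   (named numeric vector).
#' @export
make_toy_reference <- function(chrom_lengths, gc_profile = 0.4, seed = 1L) {
  stopifnot(all(chrom_lengths > 0), !is.null(names(chrom_lengths)))
  set_seed_if(seed)
  chroms <- norm_chrom(names(chrom_lengths))
  gradient <- length(gc_profile) == 2L && is.null(names(gc_profile))
  seqs <- lapply(seq_along(chroms), function(i) {
    len <- as.integer(chrom_lengths[[i]])
    gc <- if (gradient) {
      gc_profile[1L] + (gc_profile[2L] - gc_profile[1L]) * (seq_len(len) - 0.5) / len
    } else if (!is.null(names(gc_profile))) {
      rep(gc_profile[[chroms[i]]], len)
    } else rep(gc_profile[[1L]], len)
    is_gc <- runif(len) < gc
    is_first <- runif(len) < 0.5  # G vs C, A vs T
    base <- ifelse(is_gc, ifelse(is_first, "G", "C"),
                   ifelse(is_first, "A", "T"))
    paste0(base, collapse = "")
  })
  sequences <- Biostrings::DNAStringSet(unlist(seqs))
  names(sequences) <- chroms
  list(sequences = sequences,
       chrom_sizes = setNames(as.numeric(chrom_lengths), chroms))
}

#' Synthetic per-bin GC fractions for count-level simulation
#'
#' When simulating at genome scale, carrying a multi-gigabase sequence is
#' unnecessary: per-bin GC values are drawn directly from a truncated
#' normal and reused across samples.  The default spread (mean 0.40,
#' sd 0.07) is wide enough that the unimodal amplification bias produces a
#' clearly visible depth-GC correlation above the overdispersed
#' amplification noise, as it does in real shallow single-cell profiles.
#'
#' @param grid a [make_bin_grid()] grid.
#' @param mean,sd mean and spread of bin GC (defaults 0.40, 0.07).
#' @param range truncation bounds (default `c(0.25, 0.65)`).
#' @param seed integer seed.
#' @return numeric vector of per-bin GC fractions.
#' @export
simulate_bin_gc <- function(grid, mean = 0.40, sd = 0.07,
                            range = c(0.25, 0.65), seed = NULL) {
  stopifnot(inherits(grid, "bin_grid"))
  set_seed_if(seed)
  pmin(pmax(stats::rnorm(nrow(grid), mean, sd), range[1L]), range[2L])
}

# Per-bin copy number implied by a karyotype (segments override the
# whole-chromosome copy number on bins whose midpoint they contain).
bin_copy_number <- function(karyotype, grid) {
  stopifnot(inherits(karyotype, "karyotype_spec"), inherits(grid, "bin_grid"))
  cn <- as.numeric(karyotype$copies[as.character(grid$chrom)])
  if (any(is.na(cn))) stopf("karyotype missing chromosomes present in grid")
  if (!is.null(karyotype$segments)) {
    mid <- (grid$start + grid$end) / 2
    for (i in seq_len(nrow(karyotype$segments))) {
      s <- karyotype$segments[i, ]
      hit <- as.character(grid$chrom) == s$chrom & mid >= s$start & mid < s$end
      cn[hit] <- s$cn
    }
  }
  cn
}

#' Simulate overdispersed bin counts under a planted karyotype
#'
#' @param karyotype a [karyotype_spec()].
#' @param grid a [make_bin_grid()] grid.
#' @param gc per-bin GC fractions (`NA` allowed; such bins take the
#'   bias-curve mode, i.e. no relative penalty).
#' @param params a [sim_params()]; `total_reads`, the GC-bias curve and
#'   the dispersion come from here.
#' @param seed integer seed (overrides `params$seed` when given).
#' @return list with `raw_count` (integer per bin), `lambda` (the expected
#'   counts), `cn` (per-bin true copy number) and `karyotype`.
#' @export
simulate_bin_counts <- function(karyotype, grid, gc, params = sim_params(),
                                seed = NULL) {
  stopifnot(inherits(params, "sim_params"), length(gc) == nrow(grid))
  set_seed_if(if (is.null(seed)) params$seed else seed)
  cn <- bin_copy_number(karyotype, grid)
  g <- exp(-((ifelse(is.na(gc), params$gc_mu, gc)) - params$gc_mu)^2 /
             (2 * params$gc_sigma^2))
  lambda <- (cn / 2) * grid$width * g
  tot <- sum(lambda)
  if (tot <= 0) stopf("simulate_bin_counts: all-zero expected counts")
  lambda <- lambda * params$total_reads / tot
  counts <- rnbinom(length(lambda), size = params$dispersion, mu = lambda)
  list(raw_count = as.integer(counts), lambda = lambda, cn = cn,
       karyotype = karyotype)
}

#' Default 14-sample cohort karyotypes (8 aneuploid, 6 euploid)
#'
#' A fixed mix mirroring the composition of a typical embryo-biopsy run:
#' 8 samples carry one or two whole-chromosome autosomal events (trisomies
#' and monosomies over a spread of chromosome sizes) and 6 are euploid,
#' with both sexes represented.
#'
#' @return named list of [karyotype_spec()] objects.
#' @export
default_cohort_karyotypes <- function() {
  list(
    S01 = karyotype_spec("XY", gains = "21"),
    S02 = karyotype_spec("XX"),
    S03 = karyotype_spec("XY"),
    S04 = karyotype_spec("XX", losses = "16"),
    S05 = karyotype_spec("XY", gains = "16"),
    S06 = karyotype_spec("XX", losses = "22"),
    S07 = karyotype_spec("XY", gains = "13"),
    S08 = karyotype_spec("XX", gains = "18", losses = "4"),
    S09 = karyotype_spec("XY", losses = "15"),
    S10 = karyotype_spec("XX"),
    S11 = karyotype_spec("XY"),
    S12 = karyotype_spec("XX"),
    S13 = karyotype_spec("XX", gains = "2"),
    S14 = karyotype_spec("XY")
  )
}

#' Simulate a multi-sample cohort of bin counts
#'
#' Each sample's total reads are drawn uniformly within `read_range`
#' (default 541,000--1,421,000, the spread observed across an equal-volume
#' pooled overnight run) and its counts simulated with
#' [simulate_bin_counts()] under its planted karyotype.  Bin GC is drawn
#' once and shared by all samples (one genome).
#'
#' @param specs named list of [karyotype_spec()] (default
#'   [default_cohort_karyotypes()]).
#' @param grid a [make_bin_grid()] grid (default hg19 at 1 Mb).
#' @param params shared [sim_params()].
#' @param read_range per-sample total-read range.
#' @param gc optional per-bin GC (drawn via [simulate_bin_gc()] if absent).
#' @param seed integer seed driving totals, GC and all counts.
#' @return list with `counts` (bins x samples matrix), `totals`, `gc`,
#'   `grid`, `specs` and `truth` (data frame of planted whole-chromosome
#'   events: `sample`, `chrom`, `cn`, `type`).
#' @export
simulate_cohort <- function(specs = default_cohort_karyotypes(),
                            grid = make_bin_grid(hg19_chrom_sizes(), 1e6),
                            params = sim_params(),
                            read_range = c(541000, 1421000),
                            gc = NULL, seed = 1L) {
  stopifnot(length(specs) >= 1L)
  if (is.null(names(specs))) names(specs) <- sprintf("S%02d", seq_along(specs))
  set_seed_if(seed)
  if (is.null(gc)) gc <- simulate_bin_gc(grid, seed = NULL)
  totals <- runif(length(specs), read_range[1L], read_range[2L])
  counts <- matrix(0L, nrow = nrow(grid), ncol = length(specs),
                   dimnames = list(NULL, names(specs)))
  for (i in seq_along(specs)) {
    p <- params
    p$total_reads <- totals[i]
    sim <- simulate_bin_counts(specs[[i]], grid, gc, p, seed = NULL)
    counts[, i] <- sim$raw_count
  }
  truth <- do.call(rbind, lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    expected <- setNames(rep(2L, length(sp$copies)), names(sp$copies))
    if ("X" %in% names(expected)) expected[["X"]] <- if (sp$sex == "XX") 2L else 1L
    if ("Y" %in% names(expected)) expected[["Y"]] <- if (sp$sex == "XX") 0L else 1L
    dev <- names(sp$copies)[sp$copies != expected]
    if (length(dev) == 0L) return(NULL)
    data.frame(sample = nm, chrom = dev,
               cn = as.integer(sp$copies[dev]),
               type = ifelse(sp$copies[dev] > expected[dev], "gain", "loss"))
  }))
  if (is.null(truth)) {
    truth <- data.frame(sample = character(0), chrom = character(0),
                        cn = integer(0), type = character(0))
  }
  rownames(truth) <- NULL
  list(counts = counts, totals = totals, gc = gc, grid = grid,
       specs = specs, truth = truth)
}

#' Simulate library-structured FASTQ reads with true positions
#'
#' Draws genomic start positions proportional to copy number and the GC
#' bias (evaluated on fixed-size windows), prepends a simulated primer
#' prefix (random N-run plus GGG/TTT anchor), and emits positionally
#' paired index reads carrying the sample barcode.  True genomic intervals
#' of the template portion are returned (and optionally written as BED)
#' for round-trip oracles.  Base qualities are high (Q37) except for an
#' optional low-quality tail on a configurable fraction of reads.
#'
#' @param karyotype a [karyotype_spec()].
#' @param reference a [make_toy_reference()] result (or a list with
#'   `sequences` and `chrom_sizes`).
#' @param design a [make_primer_design()] object.
#' @param barcode length-6 sample barcode for the index reads.
#' @param n_reads number of reads (capped at 5e6).
#' @param read_len total read length including the primer prefix
#'   (default 55).
#' @param params a [sim_params()] (GC-bias curve reused here).
#' @param low_qual_tail_frac fraction of reads given a Q10 tail
#'   (default 0).
#' @param tail_len length of that low-quality tail (default 5).
#' @param window GC-weighting window in bases (default 10000).
#' @param seed integer seed.
#' @param out_prefix if given, writes `<prefix>_R1.fastq`,
#'   `<prefix>_I1.fastq` and `<prefix>_truth.bed`.
#' @return list with `reads`, `index` (read data frames) and `truth`
#'   (data frame `chrom`, `start`, `end`, `read_id`; 0-based half-open).
#' @export
simulate_fastq <- function(karyotype, reference, design, barcode,
                           n_reads, read_len = 55L, params = sim_params(),
                           low_qual_tail_frac = 0, tail_len = 5L,
                           window = 10000L, seed = 1L, out_prefix = NULL) {
  stopifnot(inherits(design, "primer_design"), nchar(barcode) == 6L)
  if (n_reads > 5e6) stopf("simulate_fastq: n_reads exceeds the 5e6 safety cap")
  plen <- design$n_random + 3L
  if (read_len <= plen) stopf("simulate_fastq: read_len must exceed the %d-base prefix", plen)
  glen <- read_len - plen
  set_seed_if(seed)

  sizes <- reference$chrom_sizes
  wgrid <- make_bin_grid(sizes, window)
  gcw <- bin_gc(reference$sequences, wgrid, max_n_frac = 1)$gc
  cnw <- bin_copy_number(karyotype, wgrid)
  g <- exp(-((ifelse(is.na(gcw), params$gc_mu, gcw)) - params$gc_mu)^2 /
             (2 * params$gc_sigma^2))
  # exclude windows too close to the chromosome end to fit a template
  fit <- (sizes[as.character(wgrid$chrom)] - wgrid$start) >= glen
  w <- (cnw / 2) * wgrid$width * g * fit
  if (sum(w) <= 0) stopf("simulate_fastq: no eligible windows")
  win <- sample.int(nrow(wgrid), n_reads, replace = TRUE, prob = w)
  maxs <- pmin(wgrid$end[win], sizes[as.character(wgrid$chrom[win])] - glen)
  start <- floor(wgrid$start[win] + runif(n_reads) * (maxs - wgrid$start[win]))
  chrom <- as.character(wgrid$chrom[win])

  genomic <- vapply(seq_len(n_reads), function(i) {
    as.character(Biostrings::subseq(reference$sequences[[chrom[i]]],
                                    start = start[i] + 1L,
                                    width = glen))
  }, character(1L))
  prefixes <- simulate_read_prefix(design, n = n_reads, seed = NULL)
  seqs <- paste0(prefixes, genomic)
  qual <- strrep("F", read_len)  # Q37
  quals <- rep(qual, n_reads)
  if (low_qual_tail_frac > 0) {
    hit <- runif(n_reads) < low_qual_tail_frac
    quals[hit] <- paste0(strrep("F", read_len - tail_len), strrep("+", tail_len))
  }
  ids <- sprintf("read%06d", seq_len(n_reads))
  reads <- data.frame(id = ids, seq = seqs, qual = quals,
                      stringsAsFactors = FALSE)
  index <- data.frame(id = ids, seq = rep(toupper(barcode), n_reads),
                      qual = rep(strrep("F", 6L), n_reads),
                      stringsAsFactors = FALSE)
  truth <- data.frame(chrom = chrom, start = start, end = start + glen,
                      read_id = ids, stringsAsFactors = FALSE)
  if (!is.null(out_prefix)) {
    write_fastq(reads, paste0(out_prefix, "_R1.fastq"))
    write_fastq(index, paste0(out_prefix, "_I1.fastq"))
    write.table(truth, paste0(out_prefix, "_truth.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  list(reads = reads, index = index, truth = truth)
}
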