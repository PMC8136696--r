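# Synthetic references, bin counts, cohorts and FASTQ with known truth.

test_that("toy references realize their target GC within binomial bounds", {
  ref <- make_toy_reference(c(A = 1e6), gc_profile = 0.40, seed = 5L)
  grid <- make_bin_grid(ref$chrom_sizes, bin_size = 2e5)
  gc <- bin_gc(ref$sequences, grid)$gc
  expect_true(all(abs(gc - 0.40) < 0.03))

  # same seed -> identical sequence; different seed -> different
  ref2 <- make_toy_reference(c(A = 1e6), gc_profile = 0.40, seed = 5L)
  expect_identical(as.character(ref$sequences), as.character(ref2$sequences))
  ref3 <- make_toy_reference(c(A = 1e6), gc_profile = 0.40, seed = 6L)
  expect_false(identical(as.character(ref$sequences),
                         as.character(ref3$sequences)))
})

test_that("a GC gradient produces monotone realized bin GC", {
  ref <- make_toy_reference(c(A = 1e6), gc_profile = c(0.3, 0.6), seed = 7L)
  grid <- make_bin_grid(ref$chrom_sizes, bin_size = 2e5)
  gc <- bin_gc(ref$sequences, grid)$gc
  expect_true(all(diff(gc) > 0))
  expect_lt(gc[1L], 0.40)
  expect_gt(gc[5L], 0.50)
})

test_that("karyotype_spec builds per-chromosome copies with validation", {
  k <- karyotype_spec("XY", gains = "21", losses = "16")
  expect_equal(unname(k$copies[["21"]]), 3L)
  expect_equal(unname(k$copies[["16"]]), 1L)
  expect_equal(unname(k$copies[["X"]]), 1L)
  expect_equal(unname(k$copies[["Y"]]), 1L)
  expect_equal(unname(k$copies[["1"]]), 2L)

  kx <- karyotype_spec("XX")
  expect_equal(unname(kx$copies[["X"]]), 2L)
  expect_equal(unname(kx$copies[["Y"]]), 0L)

  expect_error(karyotype_spec("XX", losses = c("1", "1", "1")), ">= 0")
  segs <- data.frame(chrom = "2", start = c(0, 5e5), end = c(6e5, 9e5), cn = 1)
  expect_error(karyotype_spec("XX", segments = segs), "overlap")
})

test_that("simulate_bin_counts respects copy number, totals and seeds", {
  grid <- make_bin_grid(setNames(rep(50e6, 5L), as.character(1:5)), 1e6)
  gc <- rep(0.45, nrow(grid))   # flat GC: no bias term
  params <- sim_params(total_reads = 5e5, dispersion = 1e6)  # ~Poisson
  k <- karyotype_spec("XX", chroms = as.character(1:5))
  sim <- simulate_bin_counts(k, grid, gc, params, seed = 9L)
  expect_equal(sum(sim$raw_count), 5e5, tolerance = 0.01)
  expect_equal(mean(sim$raw_count), 5e5 / nrow(grid), tolerance = 0.02)

  # trisomy bins average ~1.5x the disomic level
  k3 <- karyotype_spec("XX", gains = "3", chroms = as.character(1:5))
  sim3 <- simulate_bin_counts(k3, grid, gc, params, seed = 9L)
  tri <- grid$chrom == "3"
  ratio <- mean(sim3$raw_count[tri]) / mean(sim3$raw_count[!tri])
  expect_equal(ratio, 1.5, tolerance = 0.05)

  # determinism
  simA <- simulate_bin_counts(k, grid, gc, params, seed = 33L)
  simB <- simulate_bin_counts(k, grid, gc, params, seed = 33L)
  expect_identical(simA$raw_count, simB$raw_count)

  # segmental events override the chromosome level
  kseg <- karyotype_spec("XX", chroms = as.character(1:5),
                         segments = data.frame(chrom = "2", start = 10e6,
                                               end = 30e6, cn = 4))
  simS <- simulate_bin_counts(kseg, grid, gc, params, seed = 12L)
  inseg <- grid$chrom == "2" & grid$start >= 10e6 & grid$end <= 30e6
  expect_equal(mean(simS$raw_count[inseg]) /
                 mean(simS$raw_count[grid$chrom == "1"]),
               2, tolerance = 0.06)
})

test_that("overdispersion widens counts beyond Poisson", {
  grid <- make_bin_grid(c(`1` = 100e6), 1e6)
  gc <- rep(0.45, nrow(grid))
  k <- karyotype_spec("XX", chroms = "1")
  v <- vapply(c(5, 1e6), function(r) {
    sim <- simulate_bin_counts(k, grid, gc,
                               sim_params(total_reads = 2e5, dispersion = r),
                               seed = 13L)
    var(sim$raw_count) / mean(sim$raw_count)
  }, numeric(1L))
  expect_gt(v[1L], 3 * v[2L])       # size 5 is strongly super-Poisson
  expect_lt(abs(v[2L] - 1), 0.35)   # size 1e6 is Poisson-like
})

test_that("simulate_cohort returns congruent counts, totals and truth", {
  grid <- make_bin_grid(setNames(rep(40e6, 6L), c(as.character(1:4), "X", "Y")), 1e6)
  specs <- list(E1 = karyotype_spec("XX", chroms = c(as.character(1:4), "X", "Y")),
                A1 = karyotype_spec("XY", gains = "2",
                                    chroms = c(as.character(1:4), "X", "Y")))
  co <- simulate_cohort(specs, grid = grid,
                        params = sim_params(total_reads = 1e5), seed = 3L)
  expect_equal(dim(co$counts), c(nrow(grid), 2L))
  expect_equal(colnames(co$counts), c("E1", "A1"))
  expect_true(all(co$totals >= 541000 & co$totals <= 1421000))
  expect_equal(co$truth$sample, "A1")
  expect_equal(co$truth$chrom, "2")
  expect_equal(co$truth$type, "gain")

  # determinism
  co2 <- simulate_cohort(specs, grid = grid,
                         params = sim_params(total_reads = 1e5), seed = 3L)
  expect_identical(co$counts, co2$counts)

  # default cohort: 14 samples, 8 with planted autosomal events
  defaults <- default_cohort_karyotypes()
  expect_length(defaults, 14L)
  n_aneuploid <- sum(vapply(defaults, function(sp) {
    any(sp$copies[as.character(1:22)] != 2L)
  }, logical(1L)))
  expect_equal(n_aneuploid, 8L)
})

test_that("drawn cohort totals have a realistic uniformity CV", {
  # totals are uniform over the observed pooled-run range; across many
  # seeds the cohort CV stays within a wide plausible band
  grid <- make_bin_grid(c(`1` = 10e6), 1e6)
  spec <- list(S1 = karyotype_spec("XX", chroms = "1"))
  cvs <- vapply(1:100, function(s) {
    co <- simulate_cohort(rep(spec, 14L), grid = grid,
                          params = sim_params(total_reads = 1e4), seed = s)
    cohort_cv(co$totals)
  }, numeric(1L))
  expect_true(all(cvs > 10 & cvs < 40))
  expect_true(mean(cvs >= 15 & cvs <= 35) >= 0.9)
})

test_that("simulate_fastq emits structured reads, barcodes and true positions", {
  ref <- make_toy_reference(c(A = 2e5, B = 1e5), gc_profile = 0.45, seed = 15L)
  d2 <- make_primer_design("d2")
  k <- karyotype_spec("XX", chroms = c("A", "B"),
                      copies = c(A = 2L, B = 2L))
  sim <- simulate_fastq(k, ref, d2, barcode = "ACGTAC", n_reads = 400L,
                        read_len = 55L, seed = 16L)
  expect_equal(nrow(sim$reads), 400L)
  expect_true(all(nchar(sim$reads$seq) == 55L))
  expect_true(all(substr(sim$reads$seq, 7L, 9L) %in% c("GGG", "TTT")))
  expect_true(all(sim$index$seq == "ACGTAC"))
  expect_equal(sim$truth$end - sim$truth$start, rep(46, 400L))

  # the template portion equals the reference at the recorded coordinates
  for (i in c(1L, 57L, 400L)) {
    tr <- sim$truth[i, ]
    expect_equal(substr(sim$reads$seq[i], 10L, 55L),
                 as.character(Biostrings::subseq(ref$sequences[[tr$chrom]],
                                                 tr$start + 1L, width = 46L)))
  }

  # leading random cycles are near-uniform (links to the diversity audit)
  m <- base_composition(substr(sim$reads$seq, 1L, 6L), k = 6L)
  expect_true(all(m >= 0.25 - 3 * sqrt(0.25 * 0.75 / 400) &
                    m <= 0.25 + 3 * sqrt(0.25 * 0.75 / 400)))

  # files are written on request
  pre <- tempfile()
  simulate_fastq(k, ref, d2, "ACGTAC", n_reads = 20L, seed = 17L,
                 out_prefix = pre)
  expect_true(file.exists(paste0(pre, "_R1.fastq")))
  expect_true(file.exists(paste0(pre, "_I1.fastq")))
  expect_true(file.exists(paste0(pre, "_truth.bed")))
  expect_error(simulate_fastq(k, ref, d2, "ACGTAC", n_reads = 6e6), "cap")
})
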