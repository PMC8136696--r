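# Chromosome copy-number summaries, aneuploidy calls, segment detection.

# build an rrn-filled profile directly from per-chromosome target levels
level_profile <- function(levels_by_chrom, bins_per_chrom = 40L, noise_sd = 0,
                          seed = 81L) {
  sizes <- setNames(rep(bins_per_chrom * 1e6, length(levels_by_chrom)),
                    names(levels_by_chrom))
  grid <- make_bin_grid(sizes, bin_size = 1e6)
  set.seed(seed)
  gc <- runif(nrow(grid), 0.35, 0.55)
  rrn <- unlist(lapply(names(levels_by_chrom), function(ch) {
    rep(levels_by_chrom[[ch]], bins_per_chrom)
  }))
  if (noise_sd > 0) rrn <- rrn + rnorm(length(rrn), 0, noise_sd)
  prof <- bin_profile(grid, rep(100L, nrow(grid)), gc)
  prof$corrected <- prof$raw_count
  prof$rrn <- rrn
  prof
}

test_that("chrom_copy_number takes per-chromosome medians and flags thin chromosomes", {
  lv <- setNames(rep(2, 5L), as.character(1:5))
  prof <- level_profile(lv, noise_sd = 0.05)
  calls <- chrom_copy_number(prof)
  expect_equal(as.character(calls$chrom), as.character(1:5))
  expect_true(all(abs(calls$median_rrn - 2) < 0.05))
  expect_false(any(calls$no_call))

  # fully masked chromosome -> no-call
  prof2 <- level_profile(lv)
  prof2$mask[prof2$chrom == "5"] <- TRUE
  calls2 <- chrom_copy_number(prof2)
  expect_true(calls2$no_call[calls2$chrom == "5"])
  expect_true(is.na(calls2$median_rrn[calls2$chrom == "5"]))
})

test_that("call_aneuploidy applies >= / <= thresholds with strict interior", {
  lv <- setNames(rep(2, 22L), as.character(1:22))
  prof <- level_profile(c(lv, X = 2, Y = 0.02))
  v <- call_aneuploidy(chrom_copy_number(prof))
  expect_equal(v$overall, "euploid")
  expect_equal(v$sex, "XX")

  # monosomy 16 pattern
  lv16 <- lv; lv16[["16"]] <- 1.0
  v16 <- call_aneuploidy(chrom_copy_number(level_profile(c(lv16, X = 2, Y = 0.02))))
  expect_equal(v16$overall, "aneuploid")
  expect_equal(v16$calls$state[v16$calls$chrom == "16"], "loss")

  # boundary: 2.49 under a 2.5 gain threshold stays normal; 2.5 is a gain
  lvb <- lv; lvb[["21"]] <- 2.49
  vb <- call_aneuploidy(chrom_copy_number(level_profile(c(lvb, X = 2, Y = 0.02))))
  expect_equal(vb$calls$state[vb$calls$chrom == "21"], "normal")
  lvb[["21"]] <- 2.5
  vb2 <- call_aneuploidy(chrom_copy_number(level_profile(c(lvb, X = 2, Y = 0.02))))
  expect_equal(vb2$calls$state[vb2$calls$chrom == "21"], "gain")

  expect_error(call_aneuploidy(chrom_copy_number(prof),
                               gain_threshold = 1.4, loss_threshold = 1.5),
               "thresholds")
})

test_that("sex chromosomes are judged against the inferred sex baseline", {
  lv <- setNames(rep(2, 22L), as.character(1:22))
  # XY male: X ~ 1, Y ~ 1 is normal
  vm <- call_aneuploidy(chrom_copy_number(level_profile(c(lv, X = 1, Y = 1))))
  expect_equal(vm$sex, "XY")
  expect_equal(vm$overall, "euploid")

  # XXY-like: Y ~ 1 infers XY, X ~ 2 deviates from the male baseline
  vk <- call_aneuploidy(chrom_copy_number(level_profile(c(lv, X = 2, Y = 1))))
  expect_equal(vk$sex, "XY")
  expect_equal(vk$overall, "sex_flagged")
  expect_equal(vk$calls$state[vk$calls$chrom == "X"], "gain")

  # X-monosomy-like: Y ~ 0 infers XX, X ~ 1 deviates
  vt <- call_aneuploidy(chrom_copy_number(level_profile(c(lv, X = 1, Y = 0.02))))
  expect_equal(vt$sex, "XX")
  expect_equal(vt$overall, "sex_flagged")
  expect_equal(vt$calls$state[vt$calls$chrom == "X"], "loss")

  # an autosomal event outranks a sex flag in the overall verdict
  lv21 <- lv; lv21[["21"]] <- 3
  va <- call_aneuploidy(chrom_copy_number(level_profile(c(lv21, X = 1, Y = 0.02))))
  expect_equal(va$overall, "aneuploid")
})

test_that("calling is deterministic and monotone in simulated copy number", {
  lv <- setNames(rep(2, 22L), as.character(1:22))
  prof <- level_profile(c(lv, X = 2, Y = 0.02), noise_sd = 0.1)
  v1 <- call_sample(prof)
  v2 <- call_sample(prof)
  expect_identical(v1$calls$state, v2$calls$state)
  expect_identical(v1$overall, v2$overall)

  # raising chromosome 7's level can only move normal -> gain, never back
  states <- vapply(seq(2.0, 3.4, by = 0.2), function(level) {
    lv7 <- lv; lv7[["7"]] <- level
    v <- call_aneuploidy(chrom_copy_number(level_profile(c(lv7, X = 2, Y = 0.02))))
    v$calls$state[v$calls$chrom == "7"]
  }, character(1L))
  rank <- c(loss = 0L, normal = 1L, gain = 2L)
  expect_true(all(diff(rank[states]) >= 0L))
})

test_that("detect_segments finds planted runs and ignores whole-chromosome events", {
  lv <- setNames(rep(2, 4L), as.character(1:4))
  prof <- level_profile(lv, bins_per_chrom = 60L, noise_sd = 0.08, seed = 91L)
  # plant a 20-bin deletion on chromosome 2, bins 21..40
  sel <- which(prof$chrom == "2")[21:40]
  prof$rrn[sel] <- 1 + rnorm(20L, 0, 0.08)
  segs <- detect_segments(prof, min_bins = 10L)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$chrom, "2")
  expect_equal(segs$direction, "loss")
  expect_lte(abs(segs$start_bin - 21L), 2L)
  expect_lte(abs(segs$end_bin - 40L), 2L)

  # a chromosome already whole-chromosome aberrant yields no segmental event
  prof2 <- level_profile(lv, bins_per_chrom = 60L)
  prof2$rrn[prof2$chrom == "3"] <- 3
  segs2 <- detect_segments(prof2, min_bins = 10L)
  expect_equal(nrow(segs2), 0L)

  # min_bins larger than the chromosome bin count -> no events
  segs3 <- detect_segments(prof, min_bins = 100L)
  expect_equal(nrow(segs3), 0L)
})

test_that("diploid noise rarely produces segmental events (null simulation)", {
  grid <- make_bin_grid(setNames(rep(60e6, 5L), as.character(1:5)), 1e6)
  params <- sim_params(total_reads = 3e5, dispersion = 20)
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    gc <- runif(nrow(grid), 0.35, 0.55)
    sim <- simulate_bin_counts(karyotype_spec("XX", chroms = as.character(1:5)),
                               grid, gc, params, seed = s)
    prof <- compute_rrn(gc_correct(bin_profile(grid, sim$raw_count, gc)))
    if (nrow(detect_segments(prof, min_bins = 10L)) > 0L) hits <- hits + 1L
  }
  expect_lte(hits, 5L)   # >= 95% of seeds clean
})

test_that("profile_plot_data is genome-ordered and excludes masked bins", {
  lv <- setNames(rep(2, 3L), as.character(1:3))
  prof <- level_profile(lv, bins_per_chrom = 20L)
  prof$mask[5L] <- TRUE
  pd <- profile_plot_data(prof)
  expect_equal(nrow(pd), sum(!prof$mask))
  expect_equal(pd$bin_index, seq_len(nrow(pd)))
  expect_equal(sum(pd$chrom_boundary), 3L)
  expect_true(all(pd$rrn == 2))
  expect_true(all(pd$chrom_median == 2))
  # trisomy block is carried through
  prof$rrn[prof$chrom == "2"] <- 3
  pd2 <- profile_plot_data(prof)
  expect_true(all(pd2$rrn[pd2$chrom == "2"] == 3))
})

test_that("verdicts persist as TSV and JSON", {
  lv <- setNames(rep(2, 22L), as.character(1:22))
  lv[["9"]] <- 3
  v <- call_aneuploidy(chrom_copy_number(level_profile(c(lv, X = 2, Y = 0.02))),
                       sample_name = "demo")
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_verdict(v, tsv, js)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 24L)
  expect_equal(tab$state[tab$chrom == "9"], "gain")
  j <- jsonlite::read_json(js)
  expect_equal(j$overall, "aneuploid")
  expect_equal(j$sample, "demo")
})
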