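# chrominst

Shallow single-cell whole-genome sequencing pipeline for preimplantation
comprehensive chromosomal screening (PGT-A).

## What this is for

In IVF, a few-cell embryo biopsy can be screened genome-wide for
whole-chromosome gains and losses before transfer.  The measurement behind
the overnight variant of this assay is a MALBAC-derived amplification whose
primers double as Illumina adapter ends, producing pooled libraries that
are sequenced to roughly 0.5–2.5 million short single-end reads per sample.
Copy number is then read from binned depth of coverage.  `chrominst`
implements that analysis for the bioinformatician validating or re-running
such an assay:

* **demultiplexing and trimming** — hexamer-index demultiplexing with
  Hamming-distance tolerance, Q20 end trimming, primer-prefix removal;
* **binned read-depth profiling** — fixed-width genome bins (200 kb / 1 Mb),
  unique-mapped-read counting, per-bin GC;
* **GC correction and RRN** — per-1%-GC-stratum median-ratio correction,
  then the *relative read number*: corrected counts scaled so the
  autosomal mean is exactly 2, putting every bin on a copy-number scale

  `RRN_b = 2 · c_b / mean(c, autosomal unmasked bins)`,

  with the per-stratum factor
  `f_s = median(counts, autosomes) / median(counts, stratum s)`;
* **aneuploidy calling** — per-chromosome median RRN, gain/loss thresholds
  at the integer midpoints (2.5 / 1.5), sex-aware X/Y baselines, and a
  run-length detector for large segmental events;
* **QC** — per-sample read-fate rates, cohort coefficient of variation
  (the uniformity statistic for equal-volume pooling), and the 500K
  minimum-read adequacy check;
* **library diversity audit** — per-cycle base composition of the random
  read prefix that lets these libraries sequence without a Phix spike-in;
* **synthetic data** — toy references, negative-binomial bin counts under
  planted karyotypes and unimodal GC bias, 14-sample cohorts, and
  library-structured FASTQ with true-position records.

Two sequencing-run QC tables (15 single lymphocytes; 14 embryo biopsies
plus controls) ship as plain-TSV fixtures under `inst/extdata/`.

## Worked example

Simulate a 14-sample cohort (8 aneuploid, 6 euploid planted karyotypes;
hg19-length genome, 1 Mb bins, 541K–1.42M reads per sample), then profile
and call one sample that carries a planted trisomy 16:

```r
library(chrominst)

co   <- simulate_cohort(seed = 7)
prof <- bin_profile(co$grid, co$counts[, "S05"], co$gc)
prof <- compute_rrn(gc_correct(prof))
call_sample(prof, sample_name = "S05")
#> sample 'S05': aneuploid (inferred sex XY)
#>   chr16 gain (median RRN 2.99)

head(chrom_copy_number(prof), 4)
#>   chrom n_unmasked_bins median_rrn is_sex_chrom no_call
#> 1     1             250   1.987980        FALSE   FALSE
#> 2     2             243   1.926917        FALSE   FALSE
#> 3     3             198   1.942907        FALSE   FALSE
#> 4     4             191   1.920416        FALSE   FALSE
```

Disomic chromosomes sit at median RRN ≈ 2, the trisomic chromosome at ≈ 3,
and the male X/Y at ≈ 1; `plot(prof)` renders the genome-wide profile with
per-chromosome medians.  The cohort-uniformity statistic on the bundled
15-cell run table:

```r
lymph <- read_qc_table(system.file("extdata", "qc_lymphocyte_run.tsv",
                                   package = "chrominst"))
round(cohort_cv(lymph$raw_reads), 1)
#> 16.9
```

And the base-diversity audit of the production primer design (6 random
bases, then a GGG/TTT anchor):

```r
px  <- simulate_read_prefix(make_primer_design("d2"), n = 10000, seed = 1)
diversity_check(base_composition(px, k = 6))
#> diversity audit over 6 cycles (min_frac = 0.10): PASS
#>  position      A      C      G      T pass
#>         1 0.2539 0.2496 0.2445 0.2520 TRUE
#>         2 0.2552 0.2382 0.2568 0.2498 TRUE
#>         3 0.2451 0.2456 0.2536 0.2557 TRUE
#>         4 0.2503 0.2435 0.2553 0.2509 TRUE
#>         5 0.2499 0.2517 0.2492 0.2492 TRUE
#>         6 0.2443 0.2502 0.2531 0.2524 TRUE
```

A thin command-line wrapper with `audit-diversity`, `demux`, `profile`,
`call`, `qc` and `simulate-cohort` subcommands lives at
`inst/cli/chrominst.R`.  The methods vignette
(`vignettes/aneuploidy-screening-methods.Rmd`) documents the model,
parameter defaults, generator realism and limitations.

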