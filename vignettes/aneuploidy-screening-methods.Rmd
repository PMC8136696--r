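---
title: "Methods: shallow single-cell copy-number screening with chrominst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shallow single-cell copy-number screening with chrominst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chrominst)
```

## The problem

Preimplantation genetic testing for aneuploidy (PGT-A) screens a few-cell
embryo biopsy for whole-chromosome gains and losses before transfer.  The
measurement is shallow single-cell whole-genome sequencing: the biopsy's
genome is amplified by a MALBAC-derived chemistry whose primers double as
Illumina adapter ends, the pooled libraries are sequenced to roughly 0.5-2.5
million short single-end reads per sample, and copy number is read out from
the depth of coverage along the genome.  `chrominst` implements the analysis
side of this assay end to end, together with a synthetic-data generator that
makes every stage testable against planted ground truth.

## Read-depth model and the RRN

The genome is tiled with fixed-width bins (200 kb or 1 Mb; `make_bin_grid()`
uses half-open 0-based intervals and a ceiling rule, so terminal bins may be
short).  Unique mapped reads — primary, non-duplicate, mapping quality at
least 1 by default — are assigned to bins by their leftmost mapped
coordinate (`filter_unique()`, `count_bins()`).  With ~55 bp single-end
reads, start-coordinate assignment is unambiguous and strand-independent.

Amplified single-cell coverage depends strongly and unimodally on bin GC.
The correction (`gc_correct()`) is deliberately non-parametric: bins are
stratified by `floor(gc * 100)` — one stratum per 1% of GC — and each
stratum's counts are rescaled by

$$f_s = \frac{\mathrm{median}(\text{counts over unmasked autosomal bins})}
             {\mathrm{median}(\text{counts in stratum } s)}.$$

Strata with fewer than `min_bins_per_stratum = 5` unmasked autosomal bins
are merged into the nearest populated stratum (ties toward lower GC) before
medians are taken, which keeps the GC tails from contributing unstable
factors.  Median ratios were chosen over a fitted curve because at the
2,900-3,100 autosomal bins of a 1 Mb grid each percent-GC stratum holds tens
to hundreds of bins, where the median is robust to the heavy-tailed
amplification noise that would pull a least-squares fit.

The corrected counts are then scaled to the **relative read number (RRN)**:

$$\mathrm{RRN}_b = 2 \cdot \frac{c_b}{\overline{c}_{\text{autosomal, unmasked}}},$$

so the mean autosomal RRN is exactly 2 and a bin's RRN is directly its copy
number (disomy 2, trisomy 3, monosomy 1; a male X sits near 1).  Two
normalization choices are deliberate: the reference statistic is computed on
**autosomes only**, because sex-chromosome depth varies with the sample's
sex and would otherwise distort both the GC factors and the scale; and the
diploid anchor is 2, not 1, so profiles read in chromosomal copy-number
units.  RRN is invariant to global rescaling of counts (sequencing depth)
by construction.

## Calling

`chrom_copy_number()` summarizes each chromosome as the median RRN over its
unmasked bins (chromosomes with fewer than `min_bins_for_call = 10` bins
are no-calls).  Autosomes are called gained at median RRN >= 2.5 and lost
at <= 1.5 — the midpoints between integer copy states, exposed as
parameters because no thresholding rule is canonical in this assay.  The
comparisons use `>=`/`<=`, so a median of exactly 2.5 is a gain and 2.49
is not.

Sex chromosomes are never judged against the diploid baseline.  The
sample's sex is inferred from the Y median (below 0.5 reads as XX), the
X/Y baselines follow (XX: X ~ 2, Y ~ 0; XY: X ~ 1, Y ~ 1), and a sex
chromosome departing its baseline by 0.5 or more yields a `sex_flagged`
verdict rather than a silent drop or a spurious autosomal-style call.
Intermediate ("mosaic-like") medians are assigned the nearest state and the
raw median is kept in the output; the assay itself does not resolve
mosaicism and the package does not pretend to.

`detect_segments()` reports maximal runs of at least `min_bins = 10`
consecutive unmasked bins beyond a threshold (about 10 Mb at 1 Mb bins),
skipping chromosomes whose whole-chromosome median already crosses a
threshold.  This is a conservative run-length rule, not a breakpoint-precise
segmentation: the assay's validated endpoint is whole-chromosome
aneuploidy, and the segment detector exists to surface large sub-chromosomal
events, not to locate their boundaries.

One systematic effect is worth knowing: because RRN is anchored to the
autosomal **mean**, a genome carrying a trisomy has all its disomic
chromosomes sit slightly below 2 and the trisomic chromosome slightly below
3 (about 1.5% for one trisomic mid-size chromosome in a 22-autosome
genome).  The 2.5/1.5 midpoint thresholds leave ample margin for this
dilution at realistic event loads; a heavily rearranged genome would push
it further, which is a known limitation of mean anchoring.

## Preprocessing and the library audit

The library chemistry leaves the first `n_random + 3` bases of every read
primer-derived: a run of fully random bases (6 in the production design)
followed by a GGG or TTT anchor.  `demultiplex()` assigns reads to samples
by the first 6 bases of a separate index read, accepting the unique barcode
within Hamming distance `max_mismatch = 1`; the sample sheet is validated
up front (unique length-6 ACGT barcodes, pairwise distance >= 2·mm + 1), so
ties cannot occur with a valid sheet, and anything unassigned lands in an
`undetermined` stream — counts are conserved exactly.  `quality_trim()`
removes leading and trailing bases below Q20 and drops reads shorter than
36 bases; trimming is end-only (no sliding window) because the quality
criterion this mirrors names only the Q20 cutoff, and the simplest policy
satisfying it keeps retained bases an untouched substring.
`trim_primer_prefix()` removes the prefix and records whether the anchor
positions matched GGG/TTT (mismatches are tolerated and tagged, since the
anchor is primer-derived and its errors say nothing about the template).

The same random prefix is what lets these libraries be sequenced without a
random spike-in: Illumina cluster recognition uses the first few cycles and
needs all four bases well represented at each.  `base_composition()` tallies
per-cycle base fractions and `diversity_check()` passes a cycle when every
base reaches `min_frac`.  The default `min_frac = 0.10` reuses the one
quantitative anchor available — the conventional minimum random spike-in
fraction (10% of reads) below which low-diversity runs fail — and the
default audit covers cycles 1-6 only: the anchor cycles 7-9 are a two-state
GGG/TTT mixture by design and are reported but not judged.  How many cycles
the instrument truly uses is not public; `k` is therefore a parameter, not
a claim.

## What the generator emulates — and what it does not

`simulate_bin_counts()` draws a bin's count from a negative binomial with
mean

$$\lambda_b \propto \frac{\mathrm{cn}_b}{2} \cdot \ell_b \cdot
  \exp\!\left(-\frac{(\mathrm{gc}_b - \mu)^2}{2\sigma^2}\right),$$

normalized so expectations sum to the sample's total reads, with defaults
$\mu = 0.45$, $\sigma = 0.12$ and NB size $r = 20$.  At 1 Mb bins and 500K
reads this gives a per-bin coefficient of variation near 0.22 — profiles on
which integer copy states separate visually and statistically, emulating
the high-uniformity regime of MALBAC-style amplification.  Cohorts
(`simulate_cohort()`) draw per-sample totals uniformly over
541,000-1,421,000 reads, the span observed across an equal-volume pooled
overnight run, over a full-size 24-chromosome genome (the bundled hg19
lengths; ~3,100 bins at 1 Mb).  The default cohort plants 8 aneuploid and
6 euploid karyotypes across a spread of chromosome sizes and both sexes.

When no reference sequence is involved, per-bin GC is drawn from a
truncated normal (mean 0.40, sd 0.07 on [0.25, 0.65]).  The spread is set
wide enough — comparable to real fine-bin GC variation — that the unimodal
bias curve produces a clearly visible depth-GC correlation above the
overdispersed noise; with a much narrower spread the bias would be real but
unobservable against an amplification CV of ~0.22, and the
injection/removal closure (strong correlation before correction, none
after) could not be demonstrated.

`simulate_fastq()` exercises the file-level stages: reads are reference
substrings with a simulated primer prefix, paired with barcode index reads
and a true-position record, so demultiplexing, trimming and exact
re-placement can be checked read by read.  It deliberately bypasses real
alignment — positions are carried alongside — because the aligner is
external to this pipeline.

The generator does **not** emulate: locus-specific amplification dropout or
allele dropout, chimeric reads, mappability structure or blacklist regions,
barcode/sequencing errors (off by default, switchable), GC effects at
sub-bin scale, or mosaic cell mixtures.  Passing tests on synthetic data
therefore demonstrate the pipeline's arithmetic and its noise tolerance
under this model, not performance on any particular real library.

## Numerical and degenerate-input choices

* Masked bins (N-fraction above 0.2, no counted bases, or terminal bins
  shorter than 25% of the bin width) are excluded from every statistic and
  never receive corrected/RRN values.
* A stratum whose pooled median is zero would produce an infinite factor;
  such strata are left uncorrected with a warning.  An all-masked profile or
  a zero global median is an error with guidance to raise simulated depth.
* Sparse-stratum merge ties break toward lower GC, making the merge map
  deterministic.
* Sex inference prefers the Y median; if Y is absent the X median decides
  (>= 1.5 reads as XX).
* The QC cohort CV uses the sample (n-1) standard deviation; on the bundled
  run tables this reproduces the printed uniformity figures exactly, which
  the population form does not.  In the embryo-run table the CV row
  includes the positive control and excludes the negative control, the only
  reading consistent with its printed value.
* All simulators are pure functions of their seed and arguments.

## Problem sizes used in the test suite

The packaged tests run the full recovery study at its native scale — 25
replicate 14-sample cohorts on the hg19-length genome at 1 Mb bins with at
least 500K reads per sample — because count-level simulation makes this
cheap (a few hundred thousand negative-binomial draws).  Read-level FASTQ
round trips use toy references of a few hundred kilobases and a few hundred
reads, where exact-match placement is an honest oracle (46-mers are unique
in a random sequence of that size with overwhelming probability).  The
segment-detector null runs 100 seeds on a 300-bin genome.

## Known limitations

* Whole-chromosome calls rest on fixed RRN thresholds; no confidence
  measure or likelihood segmentation is provided.
* The assay class this models cannot see balanced structural
  rearrangements, and sub-bin events are invisible by construction.
* Mean-anchored normalization dilutes calls slightly in heavily aneuploid
  genomes (see above).
* The GC correction is one-dimensional; mappability is not modeled, which
  matches the upstream assay but limits transfer to real references
  without a blacklist step.
* SNP-level analyses (e.g. allele dropout) are out of scope for this
  read-depth pipeline.
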