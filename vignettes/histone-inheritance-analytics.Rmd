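---
title: "Models and methods behind histokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind histokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histokit)
```

`histokit` implements the analytical core of a replication-coupled
histone-inheritance study: strand-resolved bias of nascent chromatin around
replication origins, reprogramming of histone-mark peak landscapes,
genome-binned change-ratio correlations, enhancer and compartment
classification, lineage-barcode clone calling, and the small closed-form
statistics that go with the animal experiments. This vignette explains each
model, the tunable parameters and their defaults, what the synthetic-data
generators emulate (and what they do not), and the numerical decisions taken
where the underlying procedures are underspecified.

## Coordinates and containers

All genomic coordinates are 0-based, half-open (BED convention); any
1-based display is formatting only. Interval sets are plain data frames
validated by `validate_intervals()`; merging, intersection lengths and
midpoint containment are delegated to GenomicRanges/IRanges. Within any one
annotation track, intervals are merged before length computations so no
base pair is counted twice. Stranded reads are reduced to their 5'-most
aligned base: `pos5 = start` for plus-strand ("Watson", W) reads and
`pos5 = end - 1` for minus-strand ("Crick", C) reads. For paired SAM input
only primary, mapped first mates contribute, so each fragment is counted
once with an unambiguous strand; whether strand should be taken per read or
per fragment is not fixed by common practice, and the first-mate rule is
this package's explicit choice.

## eSPAN strand bias

At a replication origin the leading strand of the left-moving fork is the
Watson strand on the left flank and the Crick strand on the right flank.
If parental histones (or any protein captured by a strand-resolved
nascent-chromatin protocol) are transferred to the leading strand with
probability $p_{\mathrm{lead}}$, reads on the left flank are Watson with
probability $p_{\mathrm{lead}}$ and the right flank mirrors this. Counting
W and C reads into bins of `bin_size` (default 100 bp) across
`±half_window` (default 250 kb) around each origin gives per bin

$$\mathrm{Bias} = \frac{W - C}{W + C} \in [-1, 1].$$

Key choices:

- **Zero-coverage bins are undefined, not zero.** An empty bin carries no
  evidence of balance; `NA` bins are excluded from all means. The expected
  bias of a bin is $2q - 1$ (with $q$ the Watson probability) regardless of
  its depth, so undefined-aware averaging stays unbiased at any coverage.
- **Aggregation across origins.** `espan_pipeline()` defaults to pooling:
  W and C counts are summed across origins per bin before the ratio is
  formed (`pooled_bias_profile()`). At realistic depth (hundreds of reads
  per origin spread over thousands of bins) most individual (origin, bin)
  cells are empty; pooling uses every read, whereas averaging per-origin
  bias profiles (`aggregate = "mean"`, via `aggregate_origins()`) discards
  the information in how many reads support each bin. Both estimate the
  same expectation and both are available.
- **Normalization to the BrdU input is per-bin subtraction** of the
  control's bias profile. Subtraction removes additive technical strand
  bias (e.g. library-construction asymmetry) and keeps zero interpretable
  as "no preference"; values after subtraction lie in $[-2, 2]$. Division
  or depth scaling would not cancel an additive bias planted in both
  libraries, which is exactly the failure mode a strand-resolved input
  controls for.
- **Smoothing is for visualization.** The profile is smoothed with a
  centered moving average over `flank_bins` (default 1000) bins on each
  side, NA-aware and truncated at the profile edges (no padding — padding
  would invent data). Summary statistics are computed from the unsmoothed
  profile: a 1000-bin window inevitably bleeds the two flanks into each
  other near the origin and attenuates any flank summary by roughly
  `flank_bins / (2 K)` for a profile of `K` bins per side. Note the edge
  truncation means the global mean of a smoothed profile is preserved only
  up to an O(`flank_bins / length`) boundary term (exactly preserved for
  constant and linear profiles).
- **The folded score.** `leading_bias_score()` returns
  $(\overline{\mathrm{bias}}_{\mathrm{left}} -
  \overline{\mathrm{bias}}_{\mathrm{right}})/2$ over defined bins.
  Under the strand convention above this recovers $2 p_{\mathrm{lead}} - 1$;
  positive scores mean leading-strand preference. The sign convention is a
  package decision and is asserted by a cross-module test against the
  simulator.
- **Origins whose window crosses a chromosome edge are dropped** (with a
  warning), not clipped, keeping all count matrices rectangular.

The simulator (`simulate_espan_experiment()`) draws, per read, an origin, a
side (left/right, equal probability) and a uniform offset within the
half-window; leading-type reads (probability `p_lead`) map to W on the left
and C on the right. The control uses `p_lead = 0.5 + control_bias/2`, and
`control_bias/2` is also added to the eSPAN transfer probability (capped at
1) so control subtraction should cancel it. Uniform offsets are a
simplification — real nascent-chromatin coverage decays with distance from
the origin and is constrained by replication timing — so recovery tests
validate the estimator, not the realism of fork biology. Defaults
(200 origins × 500 reads per library) match the scale at which the recovery
tests are specified and run in well under a second per replicate.

## Differential peaks and annotation enrichment

`classify_peaks()` is deliberately not a reimplementation of a
dispersion-modelling differential-binding package: downstream statistics
depend only on the up/stable/down partition, so a transparent classifier is
used and labelled as such. Per peak,
$\log_2\mathrm{FC} = \log_2\frac{\overline{\mathrm{FPKM}}_{mut} + \varepsilon}
{\overline{\mathrm{FPKM}}_{wt} + \varepsilon}$ with pseudocount
$\varepsilon = 0.1$ FPKM (configurable), and the p-value is a two-sided
two-sample t-test on $\log_2(\mathrm{FPKM} + \varepsilon)$ across
replicates (p = 1 with a single replicate per side; if both groups are
exactly constant the t statistic is undefined and the classifier reports
p = 0 for unequal means, p = 1 for equal means, so noiseless simulations
are classified by fold change alone). Cutoffs: `up` iff
$\log_2\mathrm{FC} > 1$ and $p < 0.01$; `down` mirrored; else `stable`.

For each annotation type the enrichment of differential (DP) over stable
(SP) peaks is

$$\mathrm{Enrichment\ ratio(DP, SP)} =
\log_2\frac{\mathrm{obs}_d / \exp_d}{\mathrm{obs}_s / \exp_s},\qquad
\exp = \frac{L_{\mathrm{anno}}}{L_g}\, L_{\mathrm{set}},$$

where `obs` is the merged overlap length (bp) of the peak set with the
annotation track, $L_{\mathrm{anno}}$ the track length, $L_g$ the genome
length and $L_{\mathrm{set}}$ the merged peak-set length. The symbol
mapping of the expected-length formula is ambiguous as commonly printed
(the "length of peaks" could be the annotation track or the peak set); the
two readings differ only by a factor that cancels in the ratio, which
always equals $\log_2\frac{\mathrm{obs}_d / L_d}{\mathrm{obs}_s / L_s}$ —
an identity asserted on random instances. The ratio is reported undefined
(no pseudocount) when either observed overlap is zero. Point annotation of
peaks (`annotate_peaks()`) assigns the highest-priority type containing the
peak midpoint (promoter > 5'UTR > 3'UTR > exon > intron > TTS > CpG island
> repeat classes), a deterministic rule in the style of common annotation
tools; peaks hitting nothing are intergenic.

Compartment assignment (`compartment_proportions()`) gives each peak the
A/B label with the larger bp overlap; zero overlap or an exact tie leaves
it unassigned. The boundary-spanning rule is not fixed by convention, and
majority-overlap with ties-out is this package's choice; per-category
proportions sum to 1. Enhancer classification follows fixed rules:
H3K4me1 peaks overlapping H3K4me3 are not enhancers; remaining candidates
with midpoints within 2.5 kb of a TSS are excluded as promoter-proximal;
the rest are active if they overlap H3K27ac, otherwise repressed if they
overlap H3K27me3, otherwise poised. The rule set is validated against an
exhaustively enumerated 16-configuration truth table.

## Binned signal and change-ratio correlation

`genome_bins()` tiles each chromosome with 10-kb bins (final partial bin
kept); `region_fpkm()` computes
$\mathrm{FPKM} = \mathrm{count} / (\mathrm{kb} \times \mathrm{millions\
mapped})$ from 5' read positions. Change ratios are
$(\mathrm{mut} + \varepsilon)/(\mathrm{wt} + \varepsilon)$ with
$\varepsilon = 0.1$ FPKM; bins with zero signal in both samples are
undefined and pairwise-deleted. Correlations between mark pairs are Pearson
on $\log_2$ ratios — the log scale makes up- and down-changes symmetric,
and whether raw or log ratios should be used is left open by common
practice, so the choice is documented here — with the two-sided p-value
gating display at $p < 0.01$. Calibration of that gate (≈1% display rate
under a planted zero correlation) and recovery of a planted
$\rho = 0.8$ over 2,000 bins are part of the test suite.
`meta_profile()` scans ±10 kb around anchor centers in 100-bp bins
(FPKM-normalized, minus-strand anchors flipped, clipped windows dropped);
region mode rescales each region (e.g. TSS→TES gene bodies) onto 100
length-relative bins, since absolute-scale scans of unequal-length regions
do not average meaningfully across genes.

## Clone calling from lineage barcodes

Triples (cell barcode, UMI, lineage barcode) are filtered to ≥10 reads;
lineage barcodes are collapsed by greedy abundance-ranked clustering
(barcodes sorted by total read support, lexicographic tie-break; each joins
the earliest representative within hamming distance 3, else founds one) —
the greedy order and tie-break are fixed here for determinism, and the
implementation is matched against a brute-force restatement on all small
instances. Cells are assigned to the lineage with maximal distinct-UMI
support when that support is ≥3; exact ties leave the cell unassigned (a
doublet guard; the UMI threshold is applied per (cell, lineage) pair).
Clones are lineages with ≥2 assigned cells, grouped by size (2–10, 11–20,
>20) with >20 flagged dominant. `simulate_barcode_data()` plants clones
with geometric sizes (truncated at 1; mean 5 by default, chosen to populate
all three size groups), founder barcodes at pairwise hamming ≥ 8 so
distinct clones cannot merge at radius 3, and mutates each emitted barcode
copy at exactly one random position with probability `sub_rate` (default
0.1). The per-copy single-substitution model matches the regime in which
recovery is provable — real sequencing error is closer to i.i.d. per base
with occasional multi-error copies — so the end-to-end test demonstrates
threshold logic and collapse correctness, not robustness to arbitrary error
rates.

## Study statistics

`chi_square_2x2()` computes the uncorrected Pearson statistic
$X^2 = N(ad - bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$ with an upper-tail
$\chi^2_1$ p-value. For the 6/8-vs-2/8 incidence table this gives
$X^2 = 4$, $p = 0.0455$; the uncorrected test is the one whose p-value
matches the value reported for such a comparison (Yates-corrected:
$p = 0.13$; Fisher's exact two-sided: $p = 0.13$), which is why it is the
implemented default. Zero margins are an error, since the statistic is
undefined. `tumor_volume()` is the ellipsoid approximation
$0.52 \times \mathrm{length} \times \mathrm{width}^2$, with swapped
measurements corrected by convention.

## What the simulators do and do not establish

Every generator is seeded and deterministic, returns ground truth
consistent with its outputs (asserted by recount tests), and emits the
same formats the analysis functions read. They emulate the statistical
structure each stage assumes — strand-partition probabilities, planted
fold changes and annotation-placement fractions, planted log-ratio
correlation matrices, planted clone memberships with substitution noise —
but not sequencing realism: no fragment-length or GC models, no
replication-timing structure, uniform read offsets around origins, regular
feature placement, and a single-substitution barcode error model. Passing
recovery tests therefore shows the estimators are correct and calibrated
under their stated models, not that the pipeline is robust to every
artifact of real libraries.

Problem sizes used by the test suite and the acceptance script — 200
origins × 500 reads per library, 500–1,000 peaks per experiment, 2,000
bins per correlation replicate, tens of clones over ~100 cells — are the
scales at which the recovery properties are stated, and keep a full run in
the order of minutes on one core.

## Known limitations

- Peak calling, alignment, dispersion-based differential binding, Hi-C
  eigenvector computation and super-enhancer ranking are out of scope;
  their products (peaks, compartment intervals, FPKM tables) are inputs.
- The BrdU normalization is defined as bias subtraction; if a technical
  artifact scales multiplicatively with signal rather than adding to the
  strand ratio, subtraction of the input bias will not fully remove it.
- `leading_bias_score` folds flanks symmetrically and assumes origin
  centers are accurate; mis-centered origins blur but do not bias the
  score under the uniform-offset model.
- The clone caller assumes one lineage barcode per founding cell; cells
  carrying two integrations surface as ties and are left unassigned.
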