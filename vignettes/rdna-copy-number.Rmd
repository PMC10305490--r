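---
title: "Estimating relative 45S rDNA copy number and its methylation coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating relative 45S rDNA copy number and its methylation coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The 45S ribosomal DNA array is a tandem repeat on the human acrocentric
chromosomes, present in hundreds of copies per diploid genome and absent from
standard reference assemblies. Its copy number (CN) varies strongly between
individuals and may matter for disease, and its CpG methylation regulates
which copies are transcribed. Because the repeat is collapsed onto a single
reference unit, short-read depth over that unit is proportional to the number
of copies: dividing the average read depth over an rDNA segment by the depth
of single-copy regions yields a *relative* copy number,

$$\mathrm{CN} = \frac{\mathrm{ARD}_{\text{segment window}}}{\mathrm{BRD}},$$

where ARD is the mean per-base depth over a chosen 150-bp window of the 18S
or 28S segment and BRD (background read depth) is the mean of the upper-tail
trimmed average depths of single-copy exons and single-copy introns on the
acrocentric chromosomes. Bisulphite sequencing supports the same ratio while
additionally providing per-CpG methylation, so one dataset yields both CN and
methylation — the coupling between the two is the scientific question this
package serves.

## Coordinate model

All coordinates are **1-based closed intervals in the frame of the modified
45S reference**: the canonical repeat's last 1,979 bp joined to its first
14,000 bp (15,979 bp total), which places the promoter, external transcribed
spacers and all three rRNA genes on one contiguous sequence. The shipped
defaults put 18S at 5636–7506 and 28S at 9914–14948 (the canonical rRNA
annotation shifted by +1,979). Published quantification windows
(18S 6986–7135, 28S 11564–11713) are interpreted in this same frame — the
literature does not state the frame explicitly, and this assumption is
flagged here deliberately; both windows fall inside the shifted segment
annotations, which supports it. BED input/output is 0-based half-open on
disk and converted only at the I/O boundary.

## Window selection

Coverage along the 45S unit varies severalfold with position, and the first
900 bp of 18S cross-map with chr21/GL000220 sequence, so CN must be measured
in a window where depth is stable across samples. `window_scan()` slides a
150-bp window (step 1 bp by default; the step is not specified in the
literature and 1 bp is the exhaustive choice) over a segment, computes each
sample's window mean depth, and within each library group takes the
coefficient of variation — **population** SD divided by the mean — of those
means. Windows overlapping the homology zone are never scanned.
`select_window()` takes the window with the minimum mean CV across groups,
ties broken by the smaller start coordinate. The auxiliary "high R-squared"
criterion sometimes mentioned alongside minimum CV is not part of selection
here: it is not operationally defined, so minimum mean CV is the sole rule
and the published windows remain available as fixed defaults
(`fixed_windows = TRUE`).

Note an identifiability limit inherent to the statistic: the cross-sample CV
at any window contains the cohort's true CN spread as an irreducible floor,
so windows only *differ* through positional, sample-specific coverage
distortions. With few samples (around 10) a spurious window can win the scan
by chance anticorrelation between its local distortion and the cohort's CN
ranks; at cohort sizes around 30 the scan is reliable. Small cohorts should
use the fixed default windows.

## Background read depth

Per-base depths are pooled across all exon regions of a sample and the top
`ceiling(0.05 n)` values are discarded before averaging
(`trimmed_mean_depth()`), guarding against local alignment pile-ups; the same
for introns; BRD is the mean of the two trimmed averages. Pooling positions
(rather than trimming per region) is the simplest reading of trimming "the
upper 5% of these depth coverages", and the ceiling rule makes the trimmed
count explicit. The ARD over the rDNA window itself is *untrimmed* — trimming
is a background-only correction. Duplicate reads are assumed retained
upstream. Background candidates pass the single-copy filters first: regions
with an ambiguous cross-hit (E < 1e-6 to another region of the same kind) are
removed, only the largest region per gene is kept (tie: leftmost), and exons
must exceed 300 bp while introns must exceed 300 bp and not exceed 10 kb.
The homology search that produces the ambiguity annotation is upstream of
this package; the filter consumes its result.

## Methylation model

Bismark-style coverage files are parsed with the counts as the authority (the
percentage column is recomputed). Complementary-strand CpG records can be
merged into dyads (`merge_strand_cpgs()`). `bin_methylation()` partitions the
locus into 200-bp bins; a bin's mean methylation is the **unweighted** mean
of per-CpG percentages (the common binning convention; a coverage-weighted
mean is available behind `weighted = TRUE`), and a bin is analysed only if it
has at least 10 reads summed over its CpGs and at least 4 covered CpGs. The
10-read minimum is interpreted per bin; the stricter per-CpG reading is
implemented behind `per_cpg_reads = TRUE` since the wording admits both. The
final partial bin is emitted flagged and never passes. Global methylation is
the coverage-weighted pooled percentage.

## Association and inference

`per_bin_regression()` fits, per passing bin, ordinary least squares with CN
as the response — `cn ~ mean_meth + age + sex + group` — following the
field's stated model direction; only association is claimed, and the
symmetric direction is available (`meth_as_response = TRUE`). The
methylation coefficient's two-sided p-values are Benjamini–Hochberg adjusted
within the supplied family, i.e., per segment when driven by the pipeline
(18S and 28S adjusted separately); significance is called at q < 0.05. Bins
with too few complete samples or collinear design are reported with a reason
rather than dropped silently. `group_comparison()` is the case–control test:
logistic regression `group ~ cn + age + sex`, Wald p for the CN term, with
perfect separation and degenerate CN reported as non-estimable.
`platform_correlation()` validates one quantification route against another
with Spearman correlation (average ranks for ties; exact p below 10 tie-free
pairs, t-approximation otherwise) plus Pearson r².

## The synthetic cohort

`simulate_cohort()` writes a cohort in exactly the dialects the readers
consume, with ground truth. Its defaults are the package's statement of a
realistic WGBS brain cohort, chosen once:

* `n_samples = 30` — the scale of the cohorts the method is used on (27–53).
* true CN ~ LogNormal(log 200, 0.35) — central values and roughly 4–5-fold
  within-cohort spread matching reported ranges (e.g., 83–435 copies).
* background depth ~ NegBin(mean 30, size 20) per base — typical ~30x
  whole-genome coverage with mild overdispersion.
* a smooth per-sample positional multiplier `exp(amp(pos) · s_i(pos))`, with
  `s_i` a seeded spline through Gaussian knots every 500 bp and amplitude
  0.6 — multi-fold positional coverage variation, the reason a window scan is
  needed at all. The amplitude is exactly zero in a stable zone around each
  default window, and the field is constrained to ramp from zero there, so
  the minimum-CV window genuinely exists and is identifiable: windows
  straddling the zone edge carry distortion that vanishes together with
  their chance of winning the scan.
* a 3x depth boost over the first 900 bp of 18S emulating the cross-mapping
  artifact.
* optional multiplicative chemistry bias on rDNA depth (and CpG coverage)
  only — emulating the polymerase-dependent amplification bias that makes CN
  relative, not absolute.
* bin methylation mean `10 + 0.1·CN + 0.05·age + 1·sex + 0·group` percent,
  clamped to [0, 100], realized as binomial counts per CpG with coverage
  drawn from the rDNA depth model; 4–10 CpG dyads per 200-bp bin. The CN
  slope is carried by every bin except the first three (flat in observed
  data), giving designated null bins for calibration checks.

`thin_depth()` replaces each depth by a Binomial(depth, f) draw — the
depth-level equivalent of splitting a read file and keeping a fraction f,
exchangeable with it in expectation — and `stability_profile()` re-estimates
CN and global methylation at fractions 1.0 down to 0.1.

What a green simulation test does establish: the estimators invert this
generative model — ratio arithmetic, trimming, window selection, binning and
regression recover known truth under realistic noise. What it does not:
robustness to alignment artifacts, bisulphite conversion failure, m-bias,
GC-dependent coverage waves correlated between rDNA and background, or
cross-mapping structure beyond a single boost zone — none of which the
generator emulates.

## Numerical choices and degenerate inputs

* CV uses the population SD (divide by n); per-group CVs are averaged
  unweighted; zero-mean windows are skipped and counted, not returned.
* Trimming removes `ceiling(n·f)` values; `f = 0` is the plain mean; an
  empty pool is an error naming the pool.
* The noise-free simulator limit (`noise = FALSE`, `profile_sd = 0`)
  replaces draws by expectations and recovers true CN to machine precision —
  the anchor test for the whole estimation chain; with bias `b` it recovers
  exactly `b · CN`.
* BH adjustment enforces step-up monotonicity and preserves input order;
  q-values are capped at 1.
* Regressions require predictors + 2 complete samples per bin; collinear
  designs are skipped with a reason. Missing covariates error at analysis
  time, not load time.
* Depth tables are gap-filled with zeros by default because omitted
  zero-depth rows would inflate depth means.
* All randomness in a cohort derives from one master seed; identical seeds
  give byte-identical files. Sample-sheet paths are relative to the sheet.

## Known limitations

Only *relative* CN is estimated; chemistry bias makes absolute calibration
impossible from depth ratios alone. Differential methylation region calling
is out of scope. The scan's small-cohort instability is inherent (see window
selection). Coordinates assume the modified-reference frame throughout.
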