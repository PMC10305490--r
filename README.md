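# rdnacopy

Relative 45S rDNA copy number and CpG methylation coupling from read depth.

## What it does, and for whom

The human 45S ribosomal DNA array is a tandem repeat (hundreds of copies per
diploid genome) excluded from standard reference assemblies, which makes its
copy number (CN) invisible to ordinary variant pipelines. When reads are
aligned to a single collapsed repeat unit, depth over the unit scales with
copy number, so

```
CN = ARD(18S or 28S window) / BRD
```

where **ARD** is the mean per-base read depth over a depth-stable 150-bp
window of the 18S or 28S segment and **BRD** (background read depth) is the
mean of the upper-tail-trimmed average depths of single-copy exons and
introns on the acrocentric chromosomes. Whole-genome bisulphite sequencing
supports the same ratio while also giving per-CpG methylation, so one
dataset yields both CN and the methylation of the locus. The package is for
genomicists who have per-base depth tables (samtools-depth dialect) and
Bismark-style `.cov` files and want, reproducibly:

* sliding-window coefficient-of-variation selection of the quantification
  window (excluding the 18S region that cross-maps with chr21), or the
  published fixed windows (18S 6986–7135, 28S 11564–11713);
* trimmed background read depth from filtered single-copy regions
  (exons > 300 bp; introns > 300 bp and ≤ 10 kb; largest per gene; no
  ambiguous cross-hits);
* relative CN per sample and segment;
* 200-bp methylation bins (≥ 10 reads, ≥ 4 covered CpGs) and per-sample
  global methylation;
* per-bin linear models `cn ~ mean_meth + age + sex + group` with
  Benjamini–Hochberg FDR, a logistic case–control comparison, and
  cross-platform correlation validation;
* binomial depth thinning to check stability of CN down to 10% of reads;
* a synthetic cohort generator with known ground truth that drives the whole
  test suite.

See `vignettes/rdna-copy-number.Rmd` for the model, parameter meanings, and
the design decisions.

## Worked example

Simulate a 30-sample cohort with known truth, then run the full pipeline on
the files it wrote:

```r
library(rdnacopy)

cohort <- simulate_cohort(sim_config(seed = 42), out_dir = "cohort")
res <- run_pipeline(run_config(
  sample_sheet = "cohort/samples.csv",
  regions_bed  = "cohort/background_regions.bed",
  out_dir      = "results",
  seed         = 42))

res$windows
#> $`18S`
#> [1] 6659 6808
#> $`28S`
#> [1] 11085 11234

head(res$cn[res$cn$segment == "18S", ], 3)
#>   sample_id segment      ard      brd       cn
#> 1       S01     18S 8327.480 28.93161 287.8333
#> 3       S02     18S 5673.707 28.96752 195.8644
#> 5       S03     18S 6600.867 28.99836 227.6290

m <- merge(res$cn[res$cn$segment == "18S", ], cohort$truth, by = "sample_id")
cor(m$cn, m$true_cn, method = "spearman")
#> [1] 0.9684093

subset(res$association, segment == "18S" & start >= 7401 & start <= 7601)
#>    segment start  end  n     beta        se      p_value      q_value significant reason
#> 38     18S  7401 7600 30 9.293206 0.4155650 4.782888e-18 8.907926e-18        TRUE   <NA>
#> 39     18S  7601 7800 30 9.235744 0.4039235 2.814239e-18 8.907926e-18        TRUE   <NA>

res$group_test
#>   segment  n     coef_cn          se   p_value estimable note
#> 1     18S 30 0.006894461 0.005001720 0.1680742      TRUE <NA>
#> 2     28S 30 0.006185923 0.004548577 0.1738398      TRUE <NA>
```

Reading the output: the scan chose a 150-bp window per segment (here near,
not inside, the published defaults — selection is data-driven); `cn` is
ARD/BRD, e.g., sample S01 carries ~288 relative 18S copies against a ~29x
background. The estimated CN ranks the simulated truth at Spearman 0.97.
Each association row is one 200-bp bin: a beta of ~9.3 means the fitted CN
rises ~9.3 copies per additional percentage point of bin methylation after
age/sex/group adjustment, and `q_value < 0.05` marks the bin significant
(the simulator put a positive CN–methylation slope in all bins except the
first three, and those are exactly the non-significant ones). The group test
finds no case–control CN difference — the simulated group effect is zero.

The same pipeline runs from the shell:

```sh
Rscript -e 'rdnacopy::rdnacopy_main()' simulate --out cohort --seed 42
Rscript -e 'rdnacopy::rdnacopy_main()' all \
  --sample-sheet cohort/samples.csv --regions-bed cohort/background_regions.bed \
  --out results --seed 42
```

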