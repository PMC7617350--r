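# widcfoc

Cell-free DNA methylation scoring for ovarian cancer detection.

Tumour-shed cell-free DNA (cfDNA) in plasma carries tumour methylation
patterns. Targeted bisulfite sequencing of a small panel of ovarian-cancer
differentially methylated regions (amplicons in *ZNF154*, *C2CD4D* and
*WNT6*) turns that signal into a simple per-region statistic: the
**percentage of fully methylated reads** — reads in which *every* CpG of
the region is methylated — out of all reads mapped to the region. The
WID-cfOC score built on this statistic is aimed at two settings: triage of
women with a pelvic mass (diagnostic), and detection in high-risk women
before clinical diagnosis (early detection / screening), alone or combined
with the serum marker CA125.

`widcfoc` implements this analysis end to end as a tested, reusable R
pipeline, with a synthetic-data module standing in for patient samples:

* **simulation** — synthetic amplicon panels (FASTA+BED), case-control
  cohorts with CA125 histories, paired-end bisulfite reads with
  conversion-chemistry and sequencing error, and fragment-size profiles
  with a mononucleosome cfDNA peak plus a high-molecular-weight
  genomic-DNA (gDNA) component;
* **alignment & calling** — read-pair merging, ungapped reduced-alphabet
  (three-letter) bisulfite alignment, a 2% mapping-rate sample QC,
  read-level CpG methylation calls and per-region fully-methylated-read
  percentages;
* **fragment QC** — cfDNA/gDNA contamination ratios from fragment-size
  profiles and the cohort-median contamination split;
* **scoring** — per-region threshold calibration at a target specificity,
  the WID-cfOC call, CA125 classification with temporal imputation, and
  the combined (OR) score;
* **diagnostics** — exact Clopper-Pearson sensitivity/specificity
  intervals, empirical ROC/AUC, paired-difference t-intervals, stratified
  evaluation (risk class, contamination group, time to diagnosis, stage,
  BRCA status) and day/night concordance.

## The score

For sample *i* and region *j*, let

```
R_ij = 100 * (# reads with all CpGs of region j methylated) / (# reads mapped to region j)
```

Per-region cutoffs `tau_j` are calibrated on a labelled cohort by choosing,
among the observed values, the cutoff whose control specificity is closest
to the 97% target (positivity is *strictly above* the cutoff; with `n`
controls the achievable specificities are `k/n`, so 41 controls operate at
40/41 = 97.6%). Then

```
WID-cfOC positive  <=>  R_ij > tau_j for at least one region j
CA125 positive     <=>  CA125 >= 35 U/mL (with carry-forward/carry-back imputation)
combined positive  <=>  WID-cfOC positive OR CA125 positive
```

Sensitivity and specificity are reported with exact (Clopper-Pearson)
binomial intervals: the 95% interval for `x` of `n` is
`[qbeta(0.025; x, n-x+1), qbeta(0.975; x+1, n-x)]`, with the degenerate
bounds 0 (at x = 0) and 1 (at x = n).

## Worked example

```r
library(widcfoc)

panel  <- make_reference_panel(3, 150, 6, seed = 42)          # 3 amplicons, 6 CpGs each
cohort <- simulate_cohort(cohort_design_diagnostic(), seed = 42)  # 41 controls, 27 cancers
calls  <- run_cohort_pipeline(cohort, panel,
                              read_sim_params(depth_per_region = 150), seed = 43)
res    <- run_diagnostic(cohort, calls)                        # calibrate + evaluate

res$thresholds
#>   region_id threshold_pct achieved_specificity achieved_sensitivity
#> 1    EFC144             0            1.0000000            0.7037037
#> 2    EFC204             0            0.9756098            0.8148148
#> 3    EFC228             0            1.0000000            0.8148148

subset(res$estimates, stratum %in% c("all", "high_risk") & marker == "wid_cfoc")
#>     stratum   marker      metric  x  n point ci_lower ci_upper
#> 1       all wid_cfoc sensitivity 25 27 0.926    0.757    0.991
#> 2       all wid_cfoc specificity 40 41 0.976    0.871    0.999
#> 7 high_risk wid_cfoc sensitivity 20 20 1.000    0.832    1.000
#> 8 high_risk wid_cfoc specificity 40 41 0.976    0.871    0.999
```

The calibrated cutoffs sit at 0% fully methylated reads — in this
synthetic cohort background methylation rarely produces a fully methylated
read, so a single such read calls a sample positive. Specificity lands on
the 40/41 = 97.6% operating point that a 41-control calibration set can
achieve, and all 20 high-risk (grade 2/3) cancers are detected at this
simulated tumour-fraction and depth. `clopper_pearson(40, 41)` reproduces
the exact interval behind row 2: `(0.871, 0.999)`.

Thresholds transfer unchanged to an early-detection cohort with
`run_early_detection()`, which also stratifies by the cohort-median
cfDNA/gDNA contamination ratio; `run_simulation()` writes a complete
synthetic study (FASTA/BED/FASTQ/TSV/JSON plus an MD5 manifest) to disk.

## Vignette

`vignettes/widcfoc-methods.Rmd` documents the simulation model and its
assumptions, the alignment and calling contract, the calibration and
imputation rules, all numerical choices, and known limitations.
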