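---
title: "Methods: cfDNA methylation scoring for ovarian cancer detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cfDNA methylation scoring for ovarian cancer detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(widcfoc)
```

# The measurement

Tumours shed DNA fragments into plasma. At a region that is unmethylated in
normal cell-free DNA (cfDNA) but densely methylated in ovarian tumours, a
tumour-derived fragment is recognisable read by read: after bisulfite
conversion, every CpG on the read remains a C. The package's core statistic
for sample $i$ and amplicon region $j$ is therefore

$$R_{ij} = 100 \cdot \frac{\#\{\text{reads mapped to } j \text{ with all CpGs methylated}\}}{\#\{\text{reads mapped to } j\}}.$$

A read counts as *fully methylated* only if every CpG of the region is both
covered by the read and called methylated. The WID-cfOC score is positive
when $R_{ij}$ is strictly above the region's calibrated cutoff $\tau_j$ in
at least one region; only a sample negative in all regions is negative.

# Simulation model

The package analyses synthetic data; the generator is first-class, tested
code whose defaults define the study conditions.

## Amplicon panel

`make_reference_panel()` draws uniform-random amplicons (default: 3 regions
of 150 bp with 6 CpGs each, read length 150 bp, so a read pair always spans
the full amplicon) in which CpG dinucleotides occupy randomly chosen
non-overlapping positions and *no other* CG dinucleotide occurs. This makes
CpG coordinates recoverable from the sequence alone, so a panel round-trips
through FASTA+BED, and real amplicon references can be dropped in with
`read_panel()`. Only top-strand (C→T) chemistry is generated by default;
the aligner and caller also support the bottom strand (G→A) symmetrically.

## Cohorts

`cohort_design_diagnostic()` mirrors a 41-control / 27-cancer pelvic-mass
cohort (4 healthy volunteers, 37 benign pathologies; grades 5/1/19/2 for
1/2/3/unknown, hence 20 high-risk = grade 2/3 cancers; stages 3/1/10/7/6).
`cohort_design_early_detection()` mirrors a 29/29 matched screening cohort
(27 high-risk cancers; BRCA1/BRCA2/wild-type/unknown 17/5/6/1 in cases and
18/6/4/1 in controls) sampled *before* diagnosis. CA125 values are
log-normal per group with the median pinned to the design value by setting
the log-mean to its logarithm (diagnostic: 14 U/mL controls, 152 U/mL
cases; early detection: 12 and 34 U/mL); the log-SDs are set from the
published interquartile ranges. CA125 availability follows the designs:
at-index measurements for 39/41 controls and 24/27 cases (diagnostic) and
22/29 + 24/29 (early detection), with the remaining early-detection
subjects carrying only an earlier or later measurement, or none, to
exercise the temporal imputation rules.

Two generator choices deserve note:

* **Sampling-to-diagnosis interval.** The early-detection design draws the
  interval uniformly between 1 month and 4 years. Screening-trial
  "time-to-event" summaries measured from trial entry can be much longer,
  but a pre-diagnosis assay is only informative about samples taken within
  a few years of diagnosis, and the <1-year stratum must be populated for
  the stratified evaluation to be meaningful.
* **Tumour fraction.** Cases draw the fraction $\theta$ of tumour-derived
  cfDNA fragments from a log-normal: diagnostic high-risk cancers around
  4% (low-risk 0.2%), early-detection high-risk cancers around 0.8%
  (low-risk 0.1%), attenuated by $e^{-d/400}$ for $d$ days to diagnosis.
  These magnitudes reflect the common observation that clinically manifest
  tumours shed orders of magnitude more cfDNA than pre-clinical lesions.
  Controls have $\theta = 0$ by construction.

## Reads

For each region, `simulate_reads()` draws `depth_per_region` fragments
(default 300 — chosen as a problem size that keeps a full two-cohort study
around two minutes on one CPU while giving 1/3%-point score granularity; real
amplicon assays sequence far deeper, which only narrows the sampling noise
of $R_{ij}$). Each fragment is tumour-derived with probability $\theta$;
CpG methylation states are i.i.d. Bernoulli per CpG with probability
$m_t = 1$ (tumour) or $m_b$ (background; parameter default 0.01, and the
cohort generator gives each subject its own level, log-normal around 0.12,
capped at 0.5, to produce the between-subject spread of low but nonzero
background values seen in real score distributions). The conversion model:
an unmethylated C reads as T with probability $c = 0.995$; a methylated C
reads as T with probability $o = 0.005$; non-CpG cytosines are always
treated as unmethylated. Uniform substitution errors (default $10^{-3}$
per base) are applied to each mate independently.

Genomic-DNA contamination $g$ (the gDNA:cfDNA mass ratio, drawn log-normal
per subject: around 0.05 for fresh cfDNA-tube samples, around 1.2 with
log-SD 0.9 for archival samples) acts twice, via `contamination_effects()`:

* it dilutes the tumour fraction among amplifiable template,
  $\theta_\text{eff} = \theta / (1 + 0.5\,g)$ (gDNA template is assumed to
  amplify at half the efficiency of short cfDNA), and
* it adds off-target read pairs — bisulfite-converted uniform-random long
  fragments whose mates do not overlap — making up
  $\min(0.85,\, 0.6\,g/(1+g))$ of all pairs, which exercises the
  mapping-rate QC.

`simulate_fragment_profile()` renders $g$ as a two-component fragment-size
profile: a cfDNA mononucleosome peak at 167 bp (unit mass) and a gDNA
component above 700 bp (mass $g$), with 2% log-normal bin noise. The
quantification windows (cfDNA 50–700 bp, gDNA > 700 bp) are configurable;
the 167 bp mode and the 700 bp boundary are standard cfDNA biology.

## What the generator does not emulate

No indels, no PCR duplicates, no position- or cycle-dependent error
profiles, no CpG-CpG methylation correlation (background states are
i.i.d.), no real genomic sequence context for off-target reads, and no
electropherogram peak shapes beyond the two-component mixture. Passing
tests therefore demonstrate correctness of the *analysis* under a
well-specified generative model, not performance on real plasma data.

# Alignment and calling contract

A read pair is merged by reverse-complementing R2 and scanning overlap
shifts from the largest possible overlap downwards; the first shift whose
overlap (minimum 20 bp) reaches 90% identity is accepted. Disagreeing
overlap bases take the higher-quality base; quality ties become N. Pairs
with no acceptable overlap are processed as two sub-reads of one fragment
(their calls are combined; CpGs in the unsequenced gap stay uncovered).

Alignment is ungapped in the reduced three-letter alphabet (C→T for
top-strand chemistry, G→A for bottom): every region × offset placement is
scored by mismatch count and the minimum wins, ties broken toward the lower
region index, then the lower offset. A fragment maps if its best mismatch
rate is at most 10% — loose enough for the simulated error rates, far
below the ~37.5% reduced-alphabet identity of random sequence, and
configurable. Samples with a pair mapping rate below 2% fail QC; exactly
2% passes (the exclusion rule is strict). Beyond this QC no read filtering
is applied; tests assert count conservation.

Methylation is read from the *unreduced* merged fragment at each CpG
cytosine: C = methylated, T = unmethylated, anything else (including N)
ambiguous. Reads covering only part of the region's CpGs count in the
denominator but can never be fully methylated; they are flagged so users
can audit the partial-coverage rule. Ambiguous counts as not methylated. A
sample × region with zero mapped reads carries an undefined percentage and
a `no_amplification` flag rather than a 0.

# Threshold calibration and scoring

`calibrate_threshold()` considers the sorted unique observed values as
cutoff candidates (positivity strictly above the cutoff, so the achieved
specificity is interpretable as $k/n$ over $n$ controls), picks the
candidate with control specificity closest to the target (default 0.97),
and breaks ties toward higher specificity, then toward the lower cutoff.
Calibration is deterministic and idempotent; a threshold set serialises to
JSON and is applied *unchanged* to other cohorts (threshold transfer).
Samples undefined in every region score negative-by-absence, flagged.

CA125 is abnormal at ≥ 35 U/mL. When no measurement exists on the index
date, the nearest earlier *positive* carries forward and the nearest later
*negative* carries back; a nearest-earlier negative, nearest-later
positive, or no measurement at all leaves the index status unknowable and
the sample is excluded from CA125-based analyses (per analysis, not
globally). The combined marker is the OR of the two calls; its sensitivity
can only gain and its specificity only lose relative to each component —
an exact set inclusion asserted on every synthetic cohort.

# Statistics

* **Clopper-Pearson intervals** from beta quantiles, with the degenerate
  bounds 0 at $x=0$ and 1 at $x=n$ (and the analytic identity
  $\text{lower}(x{=}n) = (\alpha/2)^{1/n}$ used as a test oracle).
  Percentages are displayed to one decimal.
* **ROC/AUC**: empirical curve with tied scores grouped; AUC is the
  normalized Mann-Whitney statistic (ties counted ½), cross-checked in the
  tests against brute-force pair counting and `pROC::auc`.
* **Paired-difference interval**: $\Delta \pm t_{\alpha/2,\,N-1}\,S_D/\sqrt N$
  with $S_D$ the sample SD of the differences. Describing $S_D$ as a
  standard error while also dividing by $\sqrt N$ would double-discount the
  sample size, so the standard paired-t reading is the default; a
  `sd_is_se` switch restores the literal standard-error interpretation.
* **Day/night concordance**: Pearson correlation computed separately for
  pairs whose mean is above vs at/below 1% fully methylated reads, plus a
  discordant-call count; strata with fewer than 3 pairs or a constant
  member yield an undefined correlation rather than an error.
* **Contamination split**: cohort median of cfDNA/gDNA ratios (midpoint
  convention for even cohorts; an infinite ratio — no gDNA mass — sorts
  above all finite ratios); ratio ≤ median is the *higher*-contamination
  group. No multiple-testing correction is applied anywhere.

One cohort bookkeeping choice: when evaluating strata, case-only filters
(risk class, stage, time to diagnosis) restrict the case side and leave
controls untouched, while contamination group, BRCA status and the
CA125-negative subset restrict both sides — matching how such stratified
sensitivity/specificity tables are reported.

# Limitations

The aligner is ungapped and amplicon-scale by design: it is not a
genome-scale bisulfite aligner and will not handle indels or split reads.
The generator's i.i.d. background-methylation model understates the
read-level correlation of real background (where partially methylated
fragments cluster), so real-data thresholds would sit higher than the
near-zero cutoffs typical of these synthetic cohorts. Synthetic amplicons
share no sequence with the real target regions; analyses of real data must
supply their own panel. Finally, all performance figures computed here
describe the synthetic study conditions, not clinical performance.
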