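---
title: "Methods: senescence-signature prognostic scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: senescence-signature prognostic scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senoscan)
```

## The problem

Gene-expression signatures of cellular senescence (such as the SenMayo gene
set) summarize a transcriptional program into one per-sample number — the
mean expression of the signature's genes — and ask whether that number
predicts relapse-free survival (RFS) in breast cancer. Answering this on
public microarray data requires a chain of unglamorous but consequential
steps: merging cohorts profiled on related Affymetrix platforms (GPL96,
GPL570, GPL571 share a common probe-set core), putting arrays on a common
scale, removing samples deposited in more than one repository dataset,
excluding technically failed arrays, calling receptor status from
expression surrogates, and only then fitting survival models. `senoscan`
implements that chain as composable, tested functions, plus a synthetic
cohort generator so the whole pipeline can be validated without any
download.

## Preprocessing model

**Scaling normalization.** Inputs are MAS5-summarized linear intensities,
normalized per array upstream. Residual between-dataset scale differences
are removed by one multiplicative factor per array chosen so that the mean
over the designated *shared* (cross-platform) probe set equals a preset
target (default 1000). Using only the shared probes avoids platform bias
from the extra probes of larger arrays; applying the factor to all probes
preserves within-sample probe ratios exactly. The operation is idempotent,
and `target_mean` is a pure choice of units.

**Duplicate removal.** Identical tumors deposited in several datasets show
up as identical expression vectors after normalization. Samples are
compared over the shared probe set after rounding to 4 significant figures
(`precision`): true re-depositions agree to serialization precision,
whereas distinct biological samples essentially never collide on hundreds
of probes. Within a duplicate group the copy from the earliest dataset in
the caller's priority order (publication order) is retained, and each
removal is logged with its surviving twin.

**Quality control.** Five standard Affymetrix QC parameters are used:
background signal, raw Q (noise), percent present calls, bioB spike-in
detection, and the GAPDH/ACTB 3′:5′ degradation ratio. Each continuous
metric passes when it lies within a normal-theory 95% band,
mean ± 1.96 SD, computed across all samples of the merged batch (`z`
configurable); bioB passes when detected. The rule mapping failed-metric
counts to a status had to be fixed by design: the default excludes a sample
at ≥ 3 failures and flags (keeps, but reports) 1–2, treating isolated
excursions as warnings; the strict alternative — any failure excludes — is
`exclude_min_failures = 1`. The band is computed on the merged
post-normalization batch, not per cohort, since the point of the band is
comparability across the merged set.

## Annotation

Receptor status is called from expression surrogates on the normalized
scale: ER from probe set `205225_at` (ESR1) at a linear cutoff of 500, HER2
from `216836_s_at` (ERBB2) at 4800. A boundary convention is required and
values exactly at the cutoff call positive (≥). St Gallen surrogate
subtypes follow: ER−/HER2− basal-like, ER−/HER2+ HER2-enriched, ER+/HER2+
luminal B, and ER+/HER2− split into luminal A/B by a proliferation
criterion. No canonical proliferation probe/cutoff is bundled: callers may
supply `proliferation_high` (e.g. an MKI67 probe dichotomized at a cutoff
of their choosing); absent that, ER+/HER2− defaults to luminal A with a
warning, because the A/B boundary is then not identified. Progesterone
receptor is deliberately absent — these arrays lack a reliable PGR probe
set.

The signature score is the unweighted mean over genes of the gene's mean
probe intensity (probes → gene value → signature mean). Averaging within
genes first keeps multi-probe genes from being over-weighted; the score is
degree-1 homogeneous in intensity, which is why it is computed after
normalization. Genes without any available probe are excluded and reported,
never silently dropped.

## The cutoff scan

The prognostic statistic is a quartile-bounded minimum-p dichotomization.
Candidate cutoffs are the distinct observed score values between the lower
and upper quartiles (the only thresholds that change the partition; an
equally spaced grid would test duplicate partitions). At each candidate
`t`, samples with score > t form the high group, and a Cox proportional
hazards model on the indicator provides both the hazard ratio
HR = hazard(high)/hazard(low) and the Wald p-value — one model per cutoff,
so the reported HR and p are always mutually consistent (`p_source =
"logrank"` substitutes the log-rank p while keeping the Cox HR). Efron tie
handling is the default because month-resolution follow-up guarantees heavy
ties.

The selected cutoff minimizes p; ties are broken by the strongest effect,
formalized as the maximum |log HR| (symmetric in direction), and residual
ties take the lower cutoff. Equality is assessed to a relative tolerance of
1e-10 so that exactly symmetric designs tie cleanly in floating point.
Candidates that leave a group empty are skipped and reported, as are
candidates where the Cox fit is inestimable (separation); a scan with no
valid candidate is an error.

Two multiplicity facts shape the output. First, the minimum of many
correlated tests is anti-conservative: under the global null the selected
unadjusted p falls below 0.05 far more than 5% of the time (the test suite
demonstrates this at n = 200 over 500 replicates). Benjamini–Hochberg
q-values over the scanned family are therefore attached, with the family
defined as one scan; correcting across several signatures is a separate,
caller-level application of `bh_adjust()`. Second, the confidence interval
reported at the selected cutoff is the naive Wald interval, *not* adjusted
for having chosen the cutoff by minimum p; its coverage is nominal only at
a pre-specified cutoff. The validation suite checks coverage at the
generator's true cutoff and treats the selected-cutoff interval as
descriptive.

## Multivariate models

Clinical covariates in merged cohorts are missing for largely disjoint
subsets, so a single full model would discard most samples. Each covariate
is instead paired with the dichotomized signature group in a two-covariate
Cox model on the cases complete for that covariate, with the dropped count
logged. Categorical covariates are reference-coded (negative status, or
luminal A for subtype); age and size enter as continuous. The dichotomized
group (rather than the continuous score) is the default to match the
univariate presentation; fewer than 10 complete cases refuses with a
diagnostic. A pooled full model is intentionally not offered as a default.

The cohort summary table mirrors the mixed denominator convention of
clinical characteristics tables: event, ER and HER2 percentages use the
whole cohort as denominator, while node status, subtype and the continuous
variables use the patients with that variable observed. Percentages are
reported to one decimal and always recompute exactly from the table's own
counts.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis relies
on, with every parameter recorded in a `synthetic_truth` object:

- **Intensities** are log-normal per probe (per-probe level `N(log 500,
  0.5²)` on the log scale, within-probe noise SD 0.8), giving a median
  around 500 with a heavy right tail. Signature probes additionally load
  (loading 0.3) on one latent per-sample senescence factor — since the
  analysis uses only the mean score, a single factor suffices to induce a
  controllable score–hazard link.
- **Receptor probes** are drawn from two-component truncated log-normal
  mixtures placing the configured fractions (defaults 0.70 ER+, 0.23
  HER2+) above the 500/4800 cutoffs, with a 10% guard band around each
  cutoff so the small per-sample normalization wobble cannot flip a call,
  and an upper truncation in the tens of thousands emulating scanner
  saturation.
- **Scale structure.** Each sample's pre-scale shared-probe mean is made
  exactly 1000 by a per-sample rescale of the non-receptor probes; the raw
  deliverable then multiplies each dataset by its scale factor (defaults
  evenly spaced on [0.5, 2]). Scaling normalization therefore recovers the
  canonical data exactly, and injected duplicates — identical arrays
  re-deposited in the last dataset at a different raw scale — become
  identical again only after normalization, which is what makes the
  normalize-then-deduplicate order consequential.
- **Survival** follows a proportional-hazards model on the score: in
  `"group"` mode the hazard is multiplied by `exp(true_log_hr)` (default
  log 0.66) for samples above the true cutoff (default the median score);
  `"linear"` mode uses `true_log_hr` per SD of score. The baseline is
  exponential (a Weibull shape is exposed) with the baseline rate
  calibrated by root-finding so the expected event fraction matches the
  target (default 0.33) under independent exponential censoring (rate
  1/60 per month, i.e. ~5-year mean follow-up) plus an administrative cap
  at 120 months. Times are rounded to 0.1 month, producing realistic ties.
- **QC outliers** have background, raw Q and 3′:5′ ratio displaced by 8
  batch SDs and an undetected bioB spike (four failed metrics); the large
  displacement also inflates the empirical band enough that honest samples
  essentially never reach three failures, so exclusion sets are clean.
- **Clinical covariates** target the marginals of large merged
  breast-cancer cohorts: age `N(54.1, 12.5²)`, log-normal tumor size
  around 2.5 cm, 58% node-positive among the ~69% with known status, with
  missingness rates (31% node, 20% size, 10% age) chosen once as
  representative.

What the generator does *not* emulate: probe-level cross-correlation of
real arrays, batch effects beyond a multiplicative scale, informative
censoring, and any joint structure between clinical covariates and the
score. Passing tests therefore demonstrate that the machinery is correct
under the stated model, not that the biological conclusion transfers to any
particular real cohort.

## Numerical choices

- Quartiles use R's default quantile definition (type 7).
- The high group is `score > cutoff` (strict); receptor calls are
  `intensity ≥ cutoff`. Both boundary conventions are stated rather than
  assumed.
- Cox fits use `survival::coxph` (Newton–Raphson, Efron ties, convergence
  `eps = 1e-9`, 25 iterations); separation and non-convergence raise
  errors, never silent estimates. The two-group score statistic equals the
  log-rank chi-square on tie-free data, which the tests assert to 1e-8.
- KM medians are the smallest event time with S(t) ≤ 0.5, undefined (`NA`)
  when the curve never reaches 0.5.
- p/|log HR| ties in the scan are resolved at relative tolerance 1e-10.
- Missing clinical values are preserved as `NA` end to end; no imputation
  anywhere.

## Validation problem sizes

The shipped suite validates KM/log-rank/scan equivalence against
brute-force oracles on 200 random fixtures of up to 50 samples;
hazard-ratio recovery and naive CI coverage at the true cutoff on 200
synthetic cohorts of n = 600 (true HR 0.66); min-p anti-conservatism on
500 null scans of n = 200; and exact recovery of 5 injected duplicates and
3 QC outliers in a 200-sample cohort. These sizes were chosen to give
Monte-Carlo error well inside the asserted tolerances while keeping the
suite quick to run.

## A worked example

```{r example, eval = FALSE}
truth <- synthetic_truth(n_samples = 600, n_duplicates = 5,
                         n_qc_outliers = 3, seed = 1)
coh <- generate_cohort(truth)
res <- run_pipeline(coh$expression, coh$clinical, coh$qc, coh$signature)
res$accounting           # sample counts through the filters
res$scan                 # selected cutoff, HR, CI, p, q, KM medians
truth_report(coh$truth, scan = res$scan,
             removed = res$duplicates_removed,
             qc_result = res$qc_result, clinical = res$clinical)
```

## Limitations

MAS5 summarization itself, CEL-file handling, repository retrieval,
cross-platform probe matching beyond an explicit shared list, ComBat-style
batch correction, permutation-corrected selection p-values, time-dependent
covariates and competing risks are all out of scope. The luminal A/B split
without a proliferation input is conservative (everything ER+/HER2− goes
to luminal A), and the selected-cutoff confidence interval carries
selection bias by construction.
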