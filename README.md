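# senoscan

Prognostic analysis of senescence-associated gene signatures in merged
breast-cancer microarray cohorts.

Signatures such as the SenMayo senescence gene set are summarized per tumor
as the mean expression of their genes, and the question is whether that
score predicts relapse-free survival (RFS). Answering it on public
Affymetrix data (GPL96/GPL570/GPL571, which share a common probe-set core)
takes a chain of steps that `senoscan` implements as tested, composable
functions:

1. **Scaling normalization** — each MAS5-summarized array is rescaled by
   one factor so its mean over the shared probe set equals a preset target
   (default 1000), removing between-dataset scale differences.
2. **Duplicate removal** — samples deposited in more than one repository
   dataset are detected as identical post-normalization expression vectors
   (4 significant figures); the copy from the earliest dataset survives.
3. **Five-parameter QC** — background signal, raw Q, percent present
   calls, bioB spike detection and the GAPDH/ACTB 3′:5′ ratio; continuous
   metrics pass inside the batch band mean ± 1.96 SD, and samples failing
   ≥ 3 metrics are excluded (1–2 are flagged).
4. **Annotation** — expression-surrogate receptor calls (ER: probe
   `205225_at` ≥ 500; HER2: `216836_s_at` ≥ 4800), St Gallen surrogate
   subtypes, and the mean-expression signature score (probes → gene value
   → signature mean).
5. **Cutoff scan** — the core statistic. Every distinct score value `t`
   between the quartiles Q1 ≤ t ≤ Q3 is tried as a dichotomization
   (high: score > t); a Cox model per cutoff gives HR(high/low) and p; the
   minimum-p cutoff is selected (ties → max |log HR| → lower cutoff) and
   Benjamini–Hochberg q-values over the scanned family quantify the
   multiplicity of the min-p selection. Kaplan–Meier curves and medians
   for the selected split are attached.
6. **Paired multivariate Cox models** — the signature group plus one
   clinical covariate at a time (node, ER, HER2, size, age, subtype) on
   pairwise-complete cases, plus a Table-1-style cohort summary.

A synthetic-cohort generator (`synthetic_truth()` / `generate_cohort()`)
produces expression, clinical and QC inputs with known ground truth —
log-normal intensities with per-dataset scale factors, a latent senescence
factor driving the signature probes, receptor mixtures straddling the
500/4800 cutoffs, proportional-hazards RFS with calibrated ~33% events,
injected duplicates and QC outliers — so the whole pipeline is testable
end to end without any download.

## Worked example

```r
library(senoscan)

truth <- synthetic_truth(n_samples = 300, n_duplicates = 5,
                         n_qc_outliers = 3, seed = 7)
coh <- generate_cohort(truth)
res <- run_pipeline(coh$expression, coh$clinical, coh$qc, coh$signature)

res$accounting
#>                     stage n_samples n_removed
#> 1                   input       305         0
#> 2 after_duplicate_removal       300         5
#> 3      after_qc_exclusion       297         3

res$scan
#> cutoff scan: 149 candidates in [677.9, 1019] (0 skipped)
#> selected cutoff 796.79: HR (high vs low) = 0.620 [0.421, 0.914], p = 0.0156, q = 0.503
#> median RFS: low 48, high 85.4 months
```

The accounting shows the 5 injected duplicate arrays and the 3 QC-failed
arrays being removed before analysis. The scan then reports the selected
score cutoff, the hazard ratio of the high-expression group versus the
low-expression group with its naive 95% Wald interval and p-value, the BH
q-value within the scanned cutoff family, and the per-group Kaplan–Meier
median RFS: here high signature expression is protective (HR 0.62 < 1,
true simulated HR 0.66), with median relapse-free survival 48 months in
the low-score group versus 85.4 in the high-score group.
`truth_report(coh$truth, scan = res$scan, ...)` compares every estimate
against the generator's ground truth.

A thin command-line front end over the same functions lives in
`inst/scripts/senoscan.R` (subcommands `simulate`, `preprocess`,
`annotate`, `scan`, `multivariate`, `report`).

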