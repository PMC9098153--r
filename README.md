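# mhdual

Dual subjective–objective mental-health assessment in R.

Screening an occupational cohort (the motivating case is seafarers, whose
rates of depression, anxiety and stress run well above population
baselines) with a self-report Likert scale alone inherits the scale's
blind spot: respondents under-report. `mhdual` implements a dual design
for researchers building and validating such instruments:

* **Scale construction** — *fuzzy* exploratory factor analysis: the item
  correlation matrix is estimated with per-respondent Cauchy membership
  weights `U_k = 1 / (1 + (d_k/s)^2)` that down-weight outlying response
  vectors, iterating mean and memberships to a `1e-4` tolerance; factors
  are retained by the Kaiser rule (eigenvalues > 1) with loadings
  `L_j = sqrt(lambda_j) * e_j`, optional varimax rotation, and
  Kaiser–Meyer–Olkin / Bartlett sphericity screening.
* **Psychometric validation** — Cronbach's alpha, test–retest
  reliability, criterion validity against an established instrument,
  item discrimination by the critical-ratio (Welch *t*) method on 27%
  extreme groups, skew/kurtosis normality screening, Flesch reading
  ease, and vote-based weighting of candidate scale dimensions.
* **Subjective channels** — a from-scratch multinomial naive Bayes
  sentiment classifier (negative / objective / positive) strengthened by
  SAMME AdaBoost for interview text, and a pluggable Gaussian
  prosody-feature scorer over six emotion classes (neutral, happy, sad,
  angry, fearful, surprised) for speech, each mapped to a `[0, 1]`
  valence score; plus word-error-rate for the transcription front end.
* **Fusion** — convex combination of the objective scale score with the
  two subjective risk scores at weights `6 : 1.5 : 3.5` (normalised by
  their sum), a thresholded risk decision, and calibration metrics
  (relative accuracy gain over the scale alone) against interview ground
  truth.
* **Synthetic data** — every input is generated with planted structure:
  Likert responses from a latent factor model with outlier
  contamination, retest/criterion companions hitting target reliability
  and validity, class-conditional unigram corpora, and full cohorts
  whose three observation channels share one binary ground-truth state.

See `vignettes/dual-assessment-methods.Rmd` for the model details and the
design decisions.

## Worked example

```r
library(mhdual)

# a 283-respondent administration of an 18-item, 3-dimension instrument,
# with 5% contaminated respondents shifted by 4 latent SDs
cfg <- sim_config(283, 18, 3, outlier_fraction = 0.05,
                  outlier_magnitude = 4, seed = 42)
X <- simulate_responses(cfg)

fit <- fit_fuzzy_fa(X, rotation = "varimax")
fit
#> Fuzzy exploratory factor model
#>   items: 18, retained factors (Kaiser > 1): 3
#>   iterations: 5 (converged: TRUE)
#>   cumulative variance contribution at k: 53.5%
round(kmo_statistic(fit$fuzzy_cor), 3)
#> [1] 0.862
```

The fuzzy fit recovers the three planted dimensions; a KMO of 0.86 says
the correlation structure is dominated by shared variance and factoring
is warranted (0.5 would say the opposite). Validation against a simulated
retest (planted reliability 0.873) and a criterion scale (planted
validity 0.65):

```r
retest <- simulate_retest(X, 0.873, seed = 43)
crit   <- simulate_criterion(X, 0.65, seed = 44)
scale_report(X, retest = retest, criterion = crit,
             readability = flesch_reading_ease(968, 121, 1356))
#> Scale validation report
#>   Cronbach's alpha: 0.882
#>   test-retest reliability: 0.869
#>   criterion validity: 0.658
#>   items flagged for deletion: 0 of 18
#>   readability (Flesch reading ease): 80.2
```

Alpha above 0.8 indicates good internal consistency; the retest and
criterion correlations land on their planted targets, confirming the
generators and estimators agree. Finally, the dual system on a simulated
1000-subject cohort where the at-risk state drives all three channels:

```r
cohort <- simulate_cohort(cohort_config(1000), seed = 45)
assess_cohort(cohort)$calibration
#> Calibration against interview ground truth
#>   fused accuracy:      0.929
#>   scale-only accuracy: 0.705
#>   calibration rate:    +31.77%
#>   self-test error:     0.087
```

Fusing the text and speech channels lifts accuracy against interview
ground truth from 0.71 to 0.93 — a calibration rate of +32% relative to
the scale alone — because healthy subjects sitting near the scale's
decision boundary are pulled to the correct side by their positive
language.

A full pipeline run (simulate → factor analysis → validation → sentiment
ensemble → fusion) with all artifacts and a checksum manifest:

```r
cfg <- read_pipeline_config(
  system.file("extdata", "demo-config.json", package = "mhdual"))
cfg$out_dir <- "demo-out"
bundle <- run_pipeline(cfg)
```

A thin CLI over the same functions ships at
`inst/scripts/mhdual-cli.R` (subcommands `simulate`, `efa`, `validate`,
`affect`, `fuse`, `run`; exit code 0 on success, 2 on configuration
errors).

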