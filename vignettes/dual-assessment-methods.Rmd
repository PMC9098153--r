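---
title: "Methods: dual subjective-objective mental-health assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual subjective-objective mental-health assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhdual)
```

## The problem

Occupational cohorts such as seafarers face elevated rates of depression,
anxiety and stress, but self-report screening scales capture only what the
respondent is willing or able to endorse. `mhdual` implements a *dual*
assessment design: an objective channel (a Likert screening scale whose
dimensions are built by robust factor analysis and validated
psychometrically) is fused with two subjective channels extracted from the
respondent's own language — a text-sentiment score and a speech-emotion
score — and the fused decision is calibrated against interview ground
truth. Everything runs on synthetic data with planted structure, so every
stage can be checked against a known generating model.

## Fuzzy exploratory factor analysis

The objective scale's dimensions come from an exploratory factor analysis
of the item correlation matrix. Classical EFA is notoriously sensitive to
outlying respondents (careless responders, acquiescence sets): a handful of
extreme response vectors can distort the estimated means, inflate apparent
common variance, and bend the leading eigenvectors. The fuzzy variant
estimates the mean and covariance with per-respondent membership weights
$U_k \in (0, 1]$:

$$
FE = \frac{\sum_k U_k x_k}{\sum_k U_k}, \qquad
FCov = \frac{\sum_k U_k (x_k - FE)(x_k - FE)^\top}{\sum_k U_k},
$$

alternating the mean update with a membership update until the mean moves
by less than `tol` (default `1e-4`, i.e. one ten-thousandth on the response
scale) or `max_iter = 50` iterations elapse. Non-convergence is reported on
the returned object, never silently.

The membership update is deliberately simple: with $d_k$ the Euclidean
distance of the standardised response row from the current centre and $s$
the median of the $d_k$ (times a `scale` multiplier, default 1),

$$ U_k = \frac{1}{1 + (d_k / s)^2}. $$

This Cauchy-type weight is smooth, bounded, equal to 1 at the centre, 0.5
at the median distance and $1/10$ at three median distances; it
down-weights outliers quadratically without a hard rejection threshold and
without tuning constants. It is strictly decreasing in distance, which the
test suite verifies, along with the property that planted contaminated
rows always receive lower average membership than clean rows.

Factoring proceeds on the **fuzzy correlation matrix** (the fuzzy
covariance rescaled by fuzzy SDs) so that the Kaiser retention rule —
retain factors with eigenvalue strictly greater than 1 — is meaningful:
the rule presumes unit-variance items. Ties at exactly 1 are excluded,
with a `1e-8` epsilon so eigensolver round-off cannot promote an exact 1
(an exactly-identity input retains zero factors). Loadings are the
principal-component extraction $L_{\cdot j} = \sqrt{\lambda_j}\,e_j$;
per-factor variance contributions are $\lambda_j / p$ and their cumulative
sum is reported. With memberships pinned at 1 the whole procedure
collapses to a textbook PCA-extraction EFA of the sample correlation
matrix, which the suite checks to `1e-8` against an independent
eigendecomposition.

**Rotation.** No rotation is applied by default. One consequence matters
for recovery experiments: with equal-sized factor blocks the leading
eigenvalues are nearly degenerate and the unrotated eigenvectors are an
essentially arbitrary orthogonal mixture of the planted factors. Recovery
error against a simple-structure target is therefore measured on
varimax-rotated loadings (`rotation = "varimax"`); rotation here is a
measurement device for comparability, not a change to the model.

Sampling adequacy is screened the standard way: the Kaiser–Meyer–Olkin
statistic compares raw with anti-image partial correlations obtained from
the precision matrix, and Bartlett's sphericity test uses
$\chi^2 = -(n - 1 - (2p+5)/6)\log|R|$ on $p(p-1)/2$ degrees of freedom.
Both are cross-checked in the tests against independent oracles (a
Schur-complement partial-correlation computation, and scalar arithmetic).

Factor scores use the least-squares normal-equations solve
$F = (L^\top L)^{-1} L^\top (x - FE)$, falling back to a pseudo-inverse
with a warning if $L^\top L$ is rank-deficient.

## Psychometric validation

The validation suite implements the conventional battery:

* **Cronbach's alpha** $\frac{K}{K-1}\bigl(1 - \sum_i \sigma^2_{Y_i} /
  \sigma^2_X\bigr)$ with unbiased $(n-1)$ variances throughout. Using one
  convention in numerator and denominator makes alpha convention-free; on
  parallel items it agrees with the Spearman–Brown closed form, which the
  suite checks on constructed exact-covariance fixtures.
* **Test-retest reliability** and **criterion validity** are both the
  Pearson correlation of total scores (the suite asserts they share the
  kernel to `1e-12`).
* **Item discrimination** by the critical ratio method: for each item,
  respondents are ranked by their total over the *remaining* items, the
  top and bottom 27% (Kelley's convention) form the extreme groups, and a
  Welch $t$ (robust to unequal group variances) is the critical ratio;
  `p > 0.05` marks the item for deletion. Excluding the item from its own
  ranking total is the standard correction: an uninformative item
  otherwise appears to discriminate simply because it contributes to the
  total it is ranked by — with 10 items the self-inflation is strong
  enough to keep pure-noise items. Total ties are broken by the full
  response pattern, so verdicts are invariant to respondent order.
* **Normality screening** flags items with $|$skewness$| > 2$ or
  $|$excess kurtosis$| > 7$ (moment definitions), the conventional bounds
  for severe non-normality in questionnaire data; no distributional test
  is imposed.
* **Readability** is the Flesch reading-ease formula
  $206.835 - 1.015\,(T_w/T_{se}) - 84.6\,(T_{sy}/T_w)$. Note this is the
  reading-*ease* score (higher = easier, roughly 0–100), not the
  grade-level variant; applied reports sometimes quote a grade-like number
  for the same formula name, and the two should not be compared directly.
  The interface takes counts so the formula stays language-neutral; a
  vowel-group syllable heuristic is provided as a convenience.
* **Dimension vote weighting** turns 5-point grade counts into weights
  $\sum_g g\,c_g / (5 \sum_g c_g)$ and excludes dimensions with fewer than
  142 total votes or a largest single-grade mass below 80. The second
  threshold's operationalisation (the *largest* single-grade count) is a
  declared choice; the screening convention it implements gives no
  precise definition.

## Text channel (SSE)

Documents are lowercased, punctuation- and hyphen-split, and
whitespace-tokenised. The base classifier is a multinomial naive Bayes
over unigrams with additive smoothing (default 1): out-of-vocabulary
tokens are ignored (they contribute equal smoothing mass to every class),
so a document of unseen tokens falls back to the class priors. Posteriors
are computed in the log domain; on tiny vocabularies the suite checks them
against exhaustive plain-probability enumeration to `1e-12`.

Boosting uses multi-class SAMME: each round trains a naive Bayes weak
learner on a weight-proportional bootstrap resample (naive Bayes has no
native weighted fit), scores the weighted error $\epsilon_t$, and votes
with weight $\alpha_t = \log\frac{1-\epsilon_t}{\epsilon_t} + \log(K-1)$.
Misclassified documents have their weights multiplied by $e^{\alpha_t}$
and the weights are renormalised. Boosting halts when a learner is no
better than chance ($\epsilon_t \ge (K-1)/K$, i.e. $\alpha_t \le 0$) or
perfect ($\epsilon_t = 0$, clamped at $10^{-10}$ so $\alpha_t$ stays
finite). With $K = 2$ this is the classical binary AdaBoost, and the suite
verifies the classical bound: ensemble training error
$\le \prod_t 2\sqrt{\epsilon_t(1-\epsilon_t)}$.

The scalar sentiment score is the valence expectation of the
$\alpha$-weighted vote distribution under the declared map negative = 0,
objective = 0.5, positive = 1.

## Speech channel (SEE)

Trained acoustic emotion models are outside this package's scope; the
speech channel is a *pluggable scorer interface* over numeric prosody
features (intonation/pitch/energy summaries). The reference
implementation models six emotion classes — neutral, happy, sad, angry,
fearful, surprised — with independent Gaussian features and uniform
priors, and returns the class posterior plus a valence expectation under
the declared fixed order

sad 0 < angry 0.1 < fearful 0.2 < neutral 0.5 < surprised 0.8 < happy 1.

How emotion classes become a scalar is the largest interpolation in the
whole design — no convention exists — so the map is exposed as a plain
named vector on the scorer object and any monotone re-mapping can be
substituted. A real pretrained model can replace the Gaussian scorer by
supplying its class posteriors to the same valence expectation.

The default geometry places class $k$'s mean at `separation` times the
$k$-th unit vector (unit SDs), so any two class means are
$\sqrt{2}\cdot$`separation` apart. At the cohort default `separation = 2`
the Bayes-optimal 6-class accuracy is about 0.78; the tests verify the
scorer *is* the Bayes rule for the generating model (it matches a
nearest-mean oracle exactly) rather than asserting an accuracy the
geometry cannot deliver.

The word error rate — edit distance (substitutions + insertions +
deletions) over reference length — is provided for transcription-quality
reporting and is checked exactly against a full-matrix Wagner–Fischer
oracle.

## Fusion and calibration

Component scores live in $[0,1]$ with *risk* polarity: the objective
component is the min–max normalised scale total, and the subjective
components enter as $1 - \text{valence}$ (negative sentiment and
low-valence emotion indicate risk). Fusion is the convex combination with
default weights $6 : 1.5 : 3.5$, normalised by their sum (11): the
objective scale keeps $6/11$ of the mass, and the subjective remainder is
split between text and speech in proportion $1.5 : 3.5$ — the 38 : 55
auditory/visual split of the classic 7-38-55 communication-channel rule
applied to the subjective share. The same source convention is sometimes
stated as an objective : subjective ratio of 6 : 4; normalising by the sum
reconciles both readings as relative weights, which is why the weights are
normalised internally rather than taken as fractions of a fixed base.

Decisions threshold the fused score at 0.5 with an at-risk-on-tie rule
(both declared, since no convention fixes them). Calibration against
interview ground truth reports fused and scale-only accuracies and the
**calibration rate** — the relative accuracy improvement in percent,
$100(\mathrm{acc}_{fused} - \mathrm{acc}_{scale})/\mathrm{acc}_{scale}$ —
plus a **self-test error**, operationalised as the mean absolute
difference between fused scores and self-reported (scale) scores; the
quantity this figure mirrors in applied reports is defined only loosely,
so the operationalisation is named in the output rather than implied.

With weights $(1, 0, 0)$ the dual system collapses onto the scale and the
calibration rate is exactly 0, which the suite asserts.

## What the generators emulate — and what they do not

* **Likert responses** come from a latent common-factor model
  ($\Lambda$ loadings, unique variances, standard-normal factors)
  discretised at fixed global cutpoints, default
  $(-1.5, -0.5, 0.5, 1.5)$: global rather than per-item so item marginals
  stay comparable and the factor structure recoverable. The marginal
  distribution of real scale items is unknown — the cutpoints are a free,
  documented choice. Outliers are mean shifts in latent space (size in
  latent SD units), matching the outlier-interference framing that
  motivates the fuzzy estimator; exactly
  $\lfloor \text{fraction} \cdot n \rfloor$ rows are shifted and their
  indices returned.
* **Retest** administrations mix the standardised base responses with
  fresh noise drawn with the base's own inter-item correlation structure.
  The mixing weight is corrected in closed form for discretisation
  attenuation (computable from the cutpoints:
  $\sum_k \phi(t_k) / \mathrm{sd}(\text{score})\approx 0.955$ at the
  defaults) and for the base/retest total-variance ratio, so the
  *total-score* correlation converges to the requested reliability.
  Uncorrected per-item mixing overshoots badly (0.95 observed for a 0.85
  target) because cross-item covariances inflate the totals' correlation.
* **Criterion scores** are a noisy linear function of the base totals
  hitting the requested validity exactly in expectation.
* **Corpora** are class-conditional unigram draws over a small shared
  vocabulary; the default three sentiment classes overlap on neutral
  tokens. Real language has syntax, negation, topic drift and far larger
  vocabularies — none of which this emulates, so passing tests show the
  classifier machinery is correct, not that any particular accuracy will
  transfer to real interviews.
* **Cohorts** drive all three channels plus a noisy interview label from
  one binary state; per-channel child seeds are fixed offsets of the root
  seed, so channels are conditionally independent yet jointly
  reproducible. Healthy respondents sit at the scale midpoint and at-risk
  respondents shift upward, so a fixed 0.5 threshold gives chance-level
  accuracy when all effects are zero (which the tests check). Default
  effects (scale 1 SD, text mix 0.6, prosody 2 SD, interview noise 0) are
  one-time choices of a plausibly-sized planted signal; interviews are
  treated as ground truth by default because the design uses them as the
  reference standard.

## Problem sizes and numerical choices

The shipped demo configuration uses 283 scale respondents, 18 items, 3
factors, 5% contamination at 4 latent SDs, planted retest reliability
0.873 and criterion validity 0.65 (the mid-range of typical
subscale-validity bands), a 200-subject cohort, and 5 boosting rounds.
Recovery and robustness experiments use 500 respondents and 50
replicates; reliability/validity recovery uses $n = 2000$, where the
Fisher-z sampling band of a correlation is well inside the asserted
$\pm 0.05$/$\pm 0.06$. The full test suite runs in well under a minute on
one CPU.

Other numerical choices: weights normalised by $\sum U_k$ (not
$\sum U_k - 1$), matching the fuzzy-mean definition; eigenvector signs
fixed by making each vector's largest-magnitude entry positive;
deterministic tie-breaks everywhere (first class on vote ties, at-risk on
threshold ties, alphabetical on weight ties); all generators are pure
functions of `(config, seed)` and every pipeline artifact carries the seed
and a config hash, with no timestamps, so runs are byte-reproducible.

## Known limitations

* The fuzzy membership rule is one defensible robust-weighting scheme;
  the source convention this follows does not pin one down, and other
  bounded weights (Huber, bisquare) would behave similarly.
* Principal-component extraction over-estimates loadings slightly
  relative to true common-factor loadings (no communality iteration); the
  recovery tests budget for this.
* The text channel is unigram-only; the speech channel is a surrogate
  interface, not an acoustic model.
* Calibration experiments use simulated interviews; with 10-subject
  interview panels (a realistic field size) the calibration rate has
  enormous sampling variance, which is why the package reports it over
  large simulated cohorts instead.
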