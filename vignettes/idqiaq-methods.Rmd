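---
title: "Methods: models, algorithms and design choices in idqiaq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, algorithms and design choices in idqiaq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idqiaq)
```

This vignette documents the statistical models the package implements,
the numerical decisions behind them, and the reasoning for the design
choices that were genuinely open. It is the companion to the reference
documentation: `?irt_probit`, `?diagnose`, `?simulate_cohort`.

## Instruments and diagnostic algorithms

The IDQ (9 items) and IAQ (8 items) are answered on a five-point
frequency scale scored 0–4 (*Never*, *Only a few days*, *Half the days*,
*Most days*, *Every day*). Two scorings coexist:

* **Severity**: the plain sum of responses, 0–36 (IDQ) or 0–32 (IAQ).
  No severity cut-off is defined; severity and caseness are deliberately
  distinct.
* **Caseness**: an item is *endorsed* when its response is 3 or 4.
  A respondent is a case when (i) at least one of the two core items
  (depressed mood / loss of interest for the IDQ; apprehension / worry
  for the IAQ) is endorsed, (ii) the total number of endorsed items is
  at least 5 (IDQ) or 4 (IAQ), and (iii) the functional-impairment
  question is answered "Yes".

Two policies needed a decision and are worth stating explicitly:

* **Item-level missingness** is handled by complete-case exclusion *per
  scale*: a respondent missing any IDQ item contributes to no IDQ
  quantity but remains fully usable for the IAQ, the comparators and the
  demographic analyses. With nine (or eight) items and an algorithm that
  counts endorsements, any imputation rule would build assumptions about
  symptom co-occurrence directly into the diagnosis.
* **A missing impairment answer** with symptom criteria met makes the
  diagnosis *undetermined* (`NA`), reported separately — not imputed as
  "no". Imputing "no" would silently deflate prevalence by exactly the
  group most likely to be cases. Respondents who fail the symptom
  criteria are non-cases regardless of the impairment answer, since no
  impairment answer could change the outcome.

Prevalence intervals are **Wilson score intervals**
(`stats::prop.test(..., correct = FALSE)`). For proportions near 5–10%
at n ≈ 2000 the Wilson and Wald intervals differ visibly in the upper
bound; the Wilson interval is the standard recommendation for binomial
proportions of this size and is what `prevalence_ci()` reports at every
sample size.

## The normal-ogive IRT engine

`irt_probit()` fits the binary normal-ogive model
$P(X_j = 1 \mid \theta) = \Phi(a_j(\theta - b_j))$ with
$\theta \sim N(0,1)$ fixed for identification (items unstandardized).
The 1PL variant constrains all $a_j$ equal; difficulties are free in
both. The binary data are the endorsement recodes (response ≥ 3),
matching the fact that the diagnostic algorithm operates on
endorsements, not raw scores.

**Estimator.** Marginal maximum likelihood: the latent trait is
integrated out with Gauss–Hermite quadrature (default 61 nodes after a
change of variable to the N(0,1) density) and the marginal likelihood is
maximized by Bock–Aitkin EM — posterior weights per collapsed response
pattern in the E-step, damped per-item Newton probit updates on expected
counts in the M-step — followed by an L-BFGS-B polish of the marginal
log-likelihood using the analytic gradient obtained from Fisher's
identity. Standard errors come from the observed information matrix
(numerical Hessian of the marginal log-likelihood at the optimum), with
the delta method mapping from the internal slope/intercept
parameterization to $(a, b)$.

A limited-information route is available as a cross-check and supplies
the deterministic starting values: maximum-likelihood tetrachoric
correlations, a one-factor unweighted least-squares solution by iterated
principal factoring, and the standard conversions
$a = \lambda/\sqrt{1-\lambda^2}$, $b = \tau\sqrt{1+a^2}/a$. Because the
start is deterministic, estimation itself involves no randomness: seeds
affect only data generation, never fitting.

**Numerical decisions.**

* Convergence: relative log-likelihood change below $10^{-7}$ or 500 EM
  iterations, then the quasi-Newton polish (which also certifies a
  gradient-based optimum).
* Discriminations are bounded in $[10^{-3}, 10]$ during optimization.
  The upper cap contains Heywood-type divergence (e.g. duplicated
  items); items at the cap are flagged in `boundary_items` and a warning
  is raised. Newton steps in the M-step are damped to at most 1 per
  coordinate — an undamped step from a near-flat region can overshoot
  into the $a = 0$ saddle point and stall there.
* Item probabilities are clamped to $[10^{-12}, 1-10^{-12}]$ inside the
  likelihood; information curves use `pnorm(z, lower.tail = FALSE)` for
  the upper tail, since forming $1 - \Phi(z)$ in double precision fails
  long before $\phi(z)^2$ underflows.
* Tetrachoric 2×2 tables with a zero cell receive a continuity
  correction (+0.5 to every cell) with a warning; a zero margin is an
  error because the correlation is then unidentified.
* Items without variation are excluded with a warning; a model needs at
  least two varying items.

**Model comparison.** The 1PL/2PL comparison is a likelihood-ratio test
on the marginal log-likelihoods, $\chi^2$ with df equal to the
parameter-count difference (8 for the IDQ, 7 for the IAQ). The original
analysis software's robust weighted-least-squares estimator and its
adjusted difference test are deliberately out of scope: the package
reproduces the *decision* (are discriminations equal?) with a cleanly
defined test, not the proprietary statistic. For the same reason the
SRMR/RMSEA/CFI/TLI reported here are *approximate analogues* computed
from the unweighted least-squares discrepancy between the observed
tetrachoric matrix and the one-factor implied matrix, scaled by
$(n-1)$, with the zero-correlation independence model as baseline. They
are descriptive, ordered the right way and zero at perfect fit, but they
are not numerically comparable to weighted-least-squares fit indices;
parameter estimates are expected to agree with published
weighted-least-squares values approximately, not exactly.

**Reliability.** McDonald's ω uses the closed form
$\omega = (\sum\lambda)^2 / [(\sum\lambda)^2 + \sum(1-\lambda^2)]$ with
standardized loadings from the fitted 2PL (binary metric). Cronbach's α
is computed on the raw 0–4 items. These answer different questions — ω
describes the latent-response metric of the binary model, α the observed
ordinal sum score — and both are reported side by side rather than
reconciled; ω from high binary-metric loadings will typically exceed α
on the raw items. Item-total correlations are reported in both the
total-including-item and rest-score variants; the total variant is the
default display because that is the convention in instrument validation
tables (the two differ by a predictable attenuation).

**Group statistics.** The two-group comparison uses the pooled-variance
Student t (df $= n_1+n_2-2$) with Cohen's d from the pooled SD — the
flavor whose degrees of freedom match conventional reporting. One-way
ANOVA accepts raw data or per-group (n, M, SD) summaries; the summary
mode reconstructs the between/within sums of squares exactly, so
published group tables can be re-analyzed without raw data, and the two
modes agree to floating point. Scheffé post hoc tests (pairwise F
statistics against $F_{k-1,\,N-k}$ on the pooled MSE, α = 0.05) were
chosen to match standard practice for unplanned comparisons; Scheffé is
conservative, so any pair it flags is also significant unadjusted.
Skewness is the adjusted Fisher–Pearson $G_1$ (small-sample corrected)
with the exact normal-theory standard error
$\sqrt{6n(n-1)/((n-2)(n+1)(n+3))}$ — 0.054 at $n = 2058$, printing as
0.05 at two decimals.

## The synthetic-cohort generator

`simulate_cohort()` exists so that every stage of the pipeline — item
tables, reliability, IRT, model comparison, diagnosis, prevalence,
associations — can be exercised end to end against a *known* generating
model. Its defaults encode the structure of the instruments' UK
community validation sample (N = 2058):

* **Traits.** Depression and anxiety traits are marginally standard
  normal with correlation 0.75 (a free knob chosen to produce
  comorbidity of the order seen in community studies, not a published
  value). They are assembled from a standardized age component
  (trait–age correlation −0.33 / −0.32, younger respondents more
  symptomatic), a centered sex shift (d = 0.09 / 0.19, females higher)
  and a correlated Gaussian residual whose correlation is solved so the
  marginal trait correlation is exact.
* **Items.** Each 0–4 item is a graded probit: the standardized latent
  response $(a_j\theta + \varepsilon)/\sqrt{1+a_j^2}$ is cut at four
  ordered cutpoints. Cutpoints 1, 2 and 4 are back-solved from the
  published per-category response proportions; cutpoint 3 is set
  *exactly* to the binary threshold $a_jb_j/\sqrt{1+a_j^2}$, so
  dichotomizing simulated items at ≥ 3 is distributionally identical to
  the binary 2PL with the published parameters — the generator and the
  estimator meet in a closed form, which is what makes the end-to-end
  recovery tests sharp.
* **Impairment** is a probit in the trait,
  $P(\text{yes}\mid\theta) = \Phi(-2.1 + 1.6\,\theta)$, calibrated once
  so that IDQ diagnostic prevalence lands near 7% (the band 5–10% is
  asserted in the tests) with a plausible marginal impairment rate.
* **Treatment seeking** is assigned by severity-based selection: a noisy
  severity index (mean of the two traits plus N(0, 1.3²) noise) is cut
  at the quantiles of the group proportions (63.8 / 19.5 / 8.3 / 2.4%,
  with 6% missing at random). Selection on severity, rather than
  configured group offsets, keeps the trait marginally N(0,1) — so item
  endorsement rates stay at their closed-form values — while still
  producing the strong never < past < current ≈ waiting-list severity
  gradient. The flip side is that the generator controls the gradient
  only indirectly through the noise SD.
* **Comparators.** PHQ-9/GAD-7 items load on the same traits
  (discrimination 2.2) with three common cutpoints per instrument,
  calibrated once so that the ≥ 10 screening caseness falls near 25%
  and 21% and the severity–comparator correlations are high.

What the generator does **not** emulate: panel attrition and quota
sampling (respondents are i.i.d.), differential item functioning,
local dependence beyond the single factor per scale, response styles
(e.g. acquiescence, careless responding) and any non-probit link. A
passing pipeline on synthetic data therefore demonstrates correctness
of the algorithms under the stated model, not robustness of the
instruments to real-world response behaviour.

Determinism: a `sim_config()` carries its seed, identical
configurations yield byte-identical cohorts, and the bundled fixture
(`inst/extdata/cohort_fixture_n500.csv`) is exactly
`simulate_cohort(sim_config(n = 500))` — a test regenerates it and
compares.

## Problem sizes in the test suite

The validation experiments were sized to be decisive but desk-scale:
parameter recovery uses ten cohorts of n = 5000 (per-item recovery of
the across-seed mean within ±0.3 on a and ±0.15 on b — at these sample
sizes a single draw of the largest discriminations has a standard error
near 0.17, so the averaged criterion is the one the estimator's own
sampling theory supports); likelihood-ratio calibration uses 200
replicates of n = 1000 under an equal-discrimination truth (rejection
rate expected near 5%) and 100 replicates at n = 2058 under the
published heterogeneous discriminations (rejection expected nearly
always); the tetrachoric estimate is compared with a brute-force grid
MLE (orthant probabilities by one-dimensional quadrature, a code path
fully independent of the implementation) on 100 random tables at
1e-3 absolute agreement. Simulation-based checks in the unit tests use
n between 20,000 and 200,000 where a closed form is being verified.

## Known limitations

* Standard errors at a discrimination boundary (capped items) are not
  meaningful; the fit flags the items instead of suppressing them.
* The approximate fit indices share names but not distributions with
  their weighted-least-squares counterparts; use them comparatively.
* The graded-response *estimation* problem (fitting polytomous models to
  the 0–4 items) is out of scope — the generator simulates graded items,
  but the analysis dichotomizes, as the diagnostic algorithm does.
* `prevalence_ci()` treats respondents as an i.i.d. sample; survey
  weights are not supported anywhere in the pipeline.
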