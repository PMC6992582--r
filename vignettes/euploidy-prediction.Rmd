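---
title: "Predicting euploid blastocysts per MII oocyte: model, simulator, and validation machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting euploid blastocysts per MII oocyte}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(euploidcalc)
```

## The model and its assumptions

The package's core is a per-oocyte euploidy model for IVF/ICSI cycles with
PGT-A. Each woman contributes the pair (*m*, *N*): *m* euploid blastocysts
out of *N* mature (MII) oocytes. The model assumes every MII oocyte of a
given patient is an independent Bernoulli trial with the same probability
*p* of ending as a euploid blastocyst, so that *m* | *N* ~ Binomial(*N*, *p*),
and models *p* by logistic regression on three predictors — female age,
sperm source, and study center — with indicator-difference contrasts:

$$Y = a + b_1 d_1 (\mathrm{age} - c) + b_2 d_2 (\mathrm{age} - c)
      + s_1 d_1 + g_1 e_1 + g_2 e_2, \qquad p = \frac{1}{1 + e^{-Y}}$$

* $d_1 = I(\text{ejaculate}) - I(\text{testicular NOA})$ and
  $d_2 = I(\text{surgical non-NOA}) - I(\text{testicular NOA})$ encode the
  three sperm-source levels. We interpret the published second contrast as
  separating surgically retrieved sperm from men *without* non-obstructive
  azoospermia (epididymal or testicular, e.g. obstructive azoospermia) from
  testicular sperm of NOA men; the published label is ambiguous, and the
  coefficient-set abstraction accepts any alternative encoding expressed in
  these two contrasts.
* $e_1 = I(\text{Anatolia}) - I(\text{Androfert})$,
  $e_2 = I(\text{GENERA}) - I(\text{Anatolia})$ encode the three centers.
  An *unspecified* center sets $e_1 = e_2 = 0$: this "center-free" mode
  mimics the public online calculator, which has no center input.
* $c$ is the age-centering constant (39.414 years in the packaged default
  set). Note that the sperm main-effect coefficient $s_1$ and the intercept
  are **not** invariant to $c$: re-centering moves
  $s_1 \mapsto s_1 + b_1 (c - c')$. Coefficient sets are therefore only
  comparable at a common centering constant, and `fit_binomial_logit()`
  accepts an explicit `age_center` for that purpose (the default is the
  fitting cohort's mean age, matching how the published model was centered).

The published probability formula is typographically garbled in print; since
the model is declared logistic, the package implements the standard inverse
logit.

Key structural assumptions, inherited from the tool being reimplemented:
within-patient independence of oocytes (no embryo-cohort effects), no
patient-level random effect beyond the three predictors, and linearity of the
age effect on the logit scale within each sperm-source level.

## MIImin: the minimum-trials formula

With per-oocyte probability $p$, the chance of at least one euploid
blastocyst from $N$ oocytes is $1 - (1-p)^N$. For a target success
probability $\pi$ the minimum oocyte number is the geometric bound
$\mathrm{MII_{min}} \ge \log(1-\pi)/\log(1-p)$, integerized as the smallest
integer $N$ with $1-(1-p)^N \ge \pi$. Two numerical choices matter:

* **No raw ceiling.** `ceiling(log1p(-pi)/log1p(-p))` misfires when the
  ratio is floating-point-near an integer. The implementation seeds an
  integer search at the log-ratio and walks to the boundary.
* **Boundary tolerance.** The achieved-success comparison uses an absolute
  tolerance of $10^{-9}$ on the probability scale, so that e.g.
  $p = 0.9, \pi = 0.9$ returns 1 oocyte (the mathematically exact answer)
  rather than 2 (the answer binary rounding of $1 - 0.1$ would give). The
  test-suite brute-force oracle applies the same boundary rule.

$\pi$ is restricted to $[0.05, 0.99]$ in the command-line interface because
outside this range the formula returns degenerate (0) or astronomically large
oocyte numbers; the programmatic API accepts any $\pi \in (0,1)$. A $p \le 0$
is reported as an unreachable target, not as an overflow.

Confidence intervals on $p$ (and hence on MIImin) use a normal approximation
on the logit scale from the published per-coefficient standard errors. The
published report does not include coefficient covariances, so the interval
treats coefficients as independent and is approximate — typically
conservative, since the dominant age and intercept terms are negatively
correlated in such fits.

## The synthetic cohort: what it emulates, and what it does not

`cohort_spec()` / `generate_cohort()` produce case-report-form cohorts with
the statistical structure the analysis pipeline assumes, so that every
downstream stage is testable without patient data. Defaults state the world
of the original multicenter cohort:

| knob | default | rationale |
|---|---|---|
| ages | truncated normal, mean 39.4, sd 3.4 y, bounds [30, 46] | reproduces the printed mean 39.4 and 95% interval 33.0–44.0 |
| sperm mix | 92.7 / 3.7 / 3.6 % | printed sperm-source and azoospermia counts |
| center mix | 620 : 257 : 587 | printed per-center record counts |
| MII count | NB(mean 6.7, size 5) | printed mean 6.7; size 5 puts the 95% interval at roughly 1–16 oocytes, matching the printed interval (the exact dispersion is unpublished) |
| fertilization rate | 0.72 | printed means: 4.8 2PN per 6.7 MII |
| blastulation rate | 0.52 | see below |
| truth | `validation_model()` | the packaged published set |

The stage cascade draws `n_2pn ~ Bin(N, f)`, `n_blast ~ Bin(n_2pn, b)` and
`m ~ Bin(n_blast, p/(f·b))`, which composes to the exact marginal
`m | N ~ Binomial(N, p)` while keeping the counts ordered
(`m ≤ n_blast ≤ n_2pn ≤ N`). This identity requires `p ≤ f·b` for every
patient, which forced two design choices:

* **Age lower bound 30, not lower.** Under the published coefficients, an
  ejaculate/GENERA profile at age 25 has `p = 0.50`, which no realistic
  fertilization x blastulation product can dominate. Truncating at 30 (where
  the maximum `p` is 0.366) changes the age distribution negligibly — the
  mass below 30 in a N(39.4, 3.4²) is 0.3% — while keeping the cascade
  consistent.
* **Blastulation 0.52 rather than the printed 0.44.** With `f·b = 0.374`
  just above the maximum `p`, the generator's euploid-per-blastocyst rate is
  ≈ 31–36% rather than the printed 42%. The printed rate cannot be matched
  simultaneously with the thinning identity and the published model, because
  the model's young-age predictions exceed 42% of any realistic `f·b`. This
  is a genuine limitation of extrapolating the published model to young ages,
  and it is the one printed cohort-level statistic the stated world does not
  reproduce.

Other simplifications: MII counts are independent of age by default (an
optional trend is deliberately not enabled, since the joint law is
unpublished); covariates beyond the three predictors are absent unless the
user appends noise columns; mosaic embryos, morphology and stimulation
protocols are not modelled. Consequently a green test establishes that the
*pipeline* behaves correctly on data satisfying the model's own assumptions —
it says nothing about model fit on real patients, center heterogeneity beyond
the two contrasts, or PGT-A platform error.

Zero-MII patients are legal outputs (the original cohort kept 19 of them),
survive the CSV round-trip, and are excluded only at the fitting stages.

## Fitting pipeline choices

**Count distribution.** The marginal euploid count is fitted as negative
binomial by profile maximum likelihood (the MLE of the mean is the sample
mean for any dispersion, leaving a 1-D search over log *k*), and compared
with Poisson by AICc. A dispersion estimate above 10⁴ is flagged as the
Poisson boundary rather than reported as a fit.

**Adaptive lasso.** "Including MII oocytes to adjust the data" is implemented
as an `log(N)` offset in a negative-binomial log-link regression of *m* on
standardized candidates (a covariate mode is available as a sensitivity
switch). Adaptive weights are $1/|\tilde\beta|$ from an unpenalized initial
fit (ridge-stabilized fallback), exponent $\gamma = 1$; the path uses 100
log-spaced penalties with the dispersion fixed at the initial estimate; the
selected set is the support at minimum AICc with degrees of freedom equal to
the intercept plus the nonzero count. Two behaviors worth knowing:

* Exactly collinear duplicate candidates resolve deterministically to the
  first in input order; later copies are frozen at zero.
* Under a global null with *k* candidates, the AICc-minimum rule still admits
  each candidate with probability ≈ $P(\chi^2_1 > 2) \approx 0.16$, so the
  selected set is empty in only ≈ $0.84^k$ of runs (≈ 35–50% for six
  candidates, which simulation confirms). An analyst wanting near-certain
  empty null selections needs a stricter rule (BIC, one-SE); the AICc rule is
  retained because it is the published stopping criterion.

**Final logit.** Maximizes the aggregated binomial likelihood; estimates are
identical (to 10⁻⁸, enforced by an IRLS tolerance of 10⁻¹²) whether rows
enter aggregated or expanded per-oocyte, and the reported log-likelihood is
the Bernoulli form so the two representations agree exactly. Sperm source and
center are part of the model structure regardless of the lasso stage's
verdict, exactly as the published analysis force-included them; complete
separation (all-zero or all-one response) aborts with a diagnostic instead of
emitting a divergent coefficient set. Rows with missing predictors are not
imputed — they fail validation and must be resolved upstream, mirroring the
original analysis's no-imputation rule.

## Validation machinery

* **AUC** is the Mann-Whitney rank statistic with midrank tie correction,
  computed by default at the oocyte level (each patient contributes *N* rows,
  *m* of them positive) — the model's response unit. A patient-level variant
  (score $1-(1-p)^N$ against outcome $m \ge 1$) is available because the
  original report does not state which level its printed AUC used.
* **Generalized R²** is fixed to the Nagelkerke/Cragg–Uhler form. In the
  pipeline it is evaluated on the aggregated binomial log-likelihood
  (including the $\log\binom{N}{m}$ terms) with *n* equal to the number of
  patients, mirroring the row-count convention of the software used in the
  original analysis.
* **Model comparison** reports Pearson *and* Spearman correlation of
  predicted *p* over evaluation profiles, correlation of MIImin at each π,
  and median/mean |Δp|; zero-variance prediction vectors yield `NA`, not an
  error.
* **PPV tables** classify a patient as having *reached* MIImin when the
  observed retrieved MII count satisfies `N ≥ MIImin(profile, π)`, and
  cross-tabulate against `m ≥ 1`. An empty reached row gives an undefined
  PPV, never 0. For cohorts generated under the model being evaluated, PPV ≥
  π up to binomial noise — the tool's central claim, which the test suite
  verifies by simulation.
* **Holdout** is an unstratified simple random 75/25 split (the original
  report says only "randomly splitting").
* **Tukey-Kramer HSD** (for the per-center fertilization/blastulation
  sensitivity analysis) is implemented directly from the studentized-range
  distribution with the unequal-n Kramer standard error, and is cross-checked
  in the tests against `stats::TukeyHSD` as an independent oracle.

## Reproducibility

Every stochastic operation takes an explicit seed (`cohort_spec(seed=)`,
`holdout_split(seed=)`, `validation_config(seed=)`), reports embed the seed
and configuration echo, and the JSON/CSV writers emit full-precision numbers
(`%.17g` for doubles in the CRF), so any artifact can be regenerated exactly
from its recorded provenance. Rounding to the one-decimal percentages used in
clinical reporting happens only in display methods.

## Known limitations

* The original calculator's own coefficient set is unpublished; the package
  ships only the multicenter validation model. Comparisons against the
  original tool require a user-supplied coefficient JSON.
* The published headline statistics on real data (AUC 0.700, R² 0.258,
  r = 0.91/0.88) are not reproducible without the patient-level dataset;
  the package's tests verify the machinery on synthetic cohorts instead.
* Confidence intervals ignore coefficient covariances (unpublished).
* The endpoint is "at least one euploid blastocyst" — not implantation or
  live birth.
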