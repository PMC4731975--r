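---
title: "Growth curves and alpha-ages for walking speed: models, simulation design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth curves and alpha-ages for walking speed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkage)
```

## The scientific problem

Usual-pace walking (gait) speed is a standard summary of lower-body function
in surveys of older adults: it declines with age, predicts mortality and loss
of independence, and can be measured by non-specialist staff with a stopwatch
and a 2.4 m (8 ft) course. Subpopulations — by education, occupational class,
or the wealth of the region a person lives in — differ both in their level of
walking speed and, possibly, in how fast it declines. `walkage` packages the
analysis chain used to study such differences in the English Longitudinal
Study of Ageing (ELSA) and, crucially, to re-express them in the intuitive
unit of *years of age* rather than metres per second.

Because the underlying survey data are access-controlled, the package ships a
synthetic-cohort generator whose latent structure follows the analysis model
exactly. Everything downstream — cleaning rules, model fitting, model
selection, the alpha-age inversion — is therefore testable end to end against
known ground truth, and the published coefficient sets are available through
`reference_models()` for work that starts from the fitted trajectories.

## The growth-curve model

For person $i$ at wave $t$, with age centred at 70 years
($a_{ti} = \mathrm{age}_{ti} - 70$), observed speed $Y_{ti}$ (m/s, the mean of
two timed 2.4 m walks) is modelled as

$$Y_{ti} = \pi_{0i} + \pi_{1i}\,a_{ti} + \pi_{2i}\,a_{ti}^2
          + \pi_{3}\,\mathrm{wave}_{ti} + e_{ti},$$

with

* $\pi_{0i} = \beta_{00} + \beta_{01}\,g_i + \beta_{02}\,\mathrm{height}_i
  + \beta_{03}\,\mathrm{weight}_i + r_{0i}$ — the level at age 70;
* $\pi_{1i} = \beta_{10} + \beta_{11}\,g_i + r_{1i}$ — the linear aging rate
  (the group term $\beta_{11}$ is used in the **men's form**);
* $\pi_{2i} = \beta_{20} + \beta_{21}\,g_i$ — the acceleration (the group term
  $\beta_{21}$ is used in the **women's form**);

where $g_i$ is the binary subpopulation indicator, $r_{0i}, r_{1i}$ are
person-level normal random effects ("Intercept" and "Linear Slope" variances;
their covariance is 0 under the default diagonal structure), and
$e_{ti} \sim N(0, \sigma^2)$ iid. Estimation is maximum likelihood, *not*
REML, because the model-building sequence compares nested fixed-effect
structures by likelihood-ratio tests, and ML log-likelihoods are the ones that
are comparable. Sampling weights are used for descriptive tables
(`descriptive_table()`) but deliberately not in the fits: longitudinal survey
weights are typically defined only for complete participators, and the model
is fitted on everyone with at least one valid observation.

The sex-specific placement of the interaction — on $a^2$ for women, on $a$
for men — is not an aesthetic choice: it is the form selected by
likelihood-ratio tests in the original analysis, and
`select_growth_model()` re-enacts exactly that procedure: (1) linear base
model with height, weight and wave; (2) LRT for the $a^2$ term; (3) add the
group main effect; (4) LRT of group×$a$ against group×$a^2$ and retention of
the significant form (the higher log-likelihood wins if both are
significant). Every decision is logged in the returned trail.

### Why age is centred at 70

Centring makes the intercept and the group main effect interpretable at the
panel's mean age, and makes the interaction terms vanish there — which is why
the published "0.106 m/s faster at age 70" is literally the group main
effect. It is also a numerical necessity: with raw age, the quadratic
regressor ranges up to ~7,900 and the mixed-model optimiser fails to converge
on otherwise well-behaved panels. The package's test suite demonstrates both
the mathematical equivariance of the fit under recentring (with an
unstructured random-effect covariance — under the diagonal default a zero
intercept–slope covariance is itself a centring-specific statement) and the
numerical fragility of aggressive decentring.

## The alpha-age inversion

The characteristic-based $\alpha$-age answers: *at what age does the
comparison group walk as fast as the reference group does at age $t$?*
Writing the fitted fixed-effect trajectory of group $g$ as
$f_g(a) = \beta_{01}g + (\beta_{10} + \beta_{11}g)\,a +
(\beta_{20} + \beta_{21}g)\,a^2$ (shared covariate terms cancel because
height, weight and wave are held equal across groups), $\alpha_{k,t}$ solves
$f_{g_c}(\alpha - 70) = f_{g_r}(t - 70)$ — a quadratic with the closed-form
root implemented in `alpha_age()`.

Root policy: among real roots that map into the supported age range
$[50, 110]$, keep those on the age-*decreasing* branch of the comparison
parabola (speeds decline in old age; the rising branch of the fitted parabola
is an artefact of the quadratic), and of two survivors take the one nearer
$t$. A negative discriminant ("this speed is never attained by the comparison
group") and roots outside the support are explicit errors;
`alpha_age_table()` keeps such cells as marked failures rather than dropping
them. Every returned $\alpha$ is verified in tests to satisfy the inversion
identity to $10^{-10}$ and to agree with an independent bisection search on
the decreasing branch to $10^{-8}$.

Two presentation conventions follow the published table: alpha-ages print
with one decimal, rounded half away from zero; and the single-factor models
(not the joint three-factor fit) feed the table, one column per factor. The
interaction coefficients enter the inversion even where they were reported
non-significant — the published regional-wealth column is only reproducible
with the full printed coefficient set, which is how `reference_models()`
stores it.

## The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` draws an ELSA-like panel: six biennial waves (2002–2012),
a baseline sample aged 50+, refreshment samples entering at waves 3, 4 and 6,
nurse-measured height and weight only at waves 2, 4 and 6, two timed walks
per person-wave for those aged 60+, per-wave attrition, and sampling weights
constructed as inverse retention propensities normalised to mean 1 within
wave. Latent speeds follow the growth model above *exactly*, so parameter
recovery is a meaningful test of the whole pipeline.

Defaults were fixed once, against the published per-wave descriptive table,
before any downstream measurement:

* **Generating coefficients.** The published women's/men's education-model
  fixed effects and variance components. The height, weight and wave
  coefficients were not published (they cancel in every group contrast);
  defaults of 0.5 (women) / 0.35 (men) m/s per metre, 0.0015 m/s per kg and
  0.005 m/s per wave reproduce the published sample level (mean speed
  ≈ 0.85–0.88 m/s at the mean age, drifting slightly upward across waves).
* **Baseline ages** are integers from a truncated normal (mean 62, SD 10.5,
  support 50–89), which after entry staggering, attrition and the 60–89
  analysis window yields a cleaned panel with age mean ≈ 70.5 and SD ≈ 7,
  matching the published per-wave demographics.
* **Attrition** is 0.2 per wave, missing completely at random — consistent
  with published evidence of no socio-economic attrition bias at 65+ in this
  survey — with an optional education-dependent odds-ratio knob for
  sensitivity analyses. A single rate is used rather than wave-specific ones.
* **Trial times** are derived from the latent person-wave speed plus
  independent per-trial jitter *on the speed scale* (SD 0.02 m/s), then
  converted to times over 2.4 m. The mean of the two trial speeds is then an
  unbiased reading of the latent speed, which keeps the mean-of-trials
  estimator aligned with the generating model.
* **Group prevalences** are entry-wave-specific for education (0.40 at
  baseline rising to 0.65 for the last refreshment), matching the published
  upward drift in the educated share across waves.
* **Contamination** knobs inject implausible values — sub-floor walk speeds,
  heights < 1.29 m, weights < 29 kg, self-reported ages off by 3–5 years,
  missing walks, missing group flags — *disjointly*, at most one defect per
  record (per person for the anthropometric and group-flag rules, which act at
  the person level in cleaning). Disjoint injection is what makes the
  generator's log an exact ground truth for the preprocessor's first-failing-
  rule ledger, which the tests check count-for-count.

Features of the real survey that are deliberately **not** emulated: household
clustering and stratification of the sampling frame, institutionalisation
follow-up, wave-specific conditional response rates, and any structure in the
missingness beyond the MCAR/contamination mechanisms above. Passing tests
therefore validate the statistical machinery, not the claim that the
generator is a digital twin of the survey.

## Cleaning rules and the exclusion ledger

`build_panel()` applies, in a fixed order, with each record attributed to the
*first* rule it fails: (1) walk test not available (either trial missing;
records under age 60 carry no trials by design and land here); (2) mean trial
speed below the 0.09 m/s plausibility floor; (3) birth year missing; (4)
computed age (survey year − birth year) outside 60–89; (5) self-reported age
differing from the computed age by more than two years (exactly two is kept);
(6)–(7) person-level mean nurse height/weight missing after recoding
implausible values (< 1.29 m, < 29 kg); (8) any group indicator missing.
First-failure attribution keeps the ledger additive:
`input_rows = kept_rows + sum(counts)` always. The order itself is a
documented convention — the source analysis lists missingness percentages
without stating precedence.

Two interpretations are configurable: both trials are required by default
(`require_both = FALSE` accepts single-trial speeds), and the *computed* age
is the analysis age (the self-report is only used for the consistency
check). Group indicators are treated as time-constant at the person level;
on conflict the last observed value wins and the conflict is counted.

## Numerical choices

* Mixed models are fitted by `lme4::lmer` with `REML = FALSE` and its default
  deterministic optimiser, so fits are exactly reproducible given the data.
  Convergence and singularity messages are captured on the fitted object
  (`$converged`, `$boundary`, `$messages`) rather than printed mid-pipeline.
* Boundary variance components are reported as 0 with a warning, never an
  error; degenerate designs in which the random slope is not even estimable
  (every person observed once) are refitted with a random intercept only and
  the slope variance reported at its boundary.
* LRT p-values use the standard $\chi^2$ reference throughout. For the
  fixed-effect comparisons performed here that is the textbook test; the
  boundary-corrected mixture distribution relevant to testing variance
  components is out of scope and deliberately not implemented.
* The quadratic inversion treats $|\beta_2| < 10^{-12}$ as linear; the
  identity case (comparison = reference, or all group terms zero) returns
  $\alpha = t$ exactly rather than through the root formula.
* Weighted SDs use the frequency-weight convention with weights normalised
  to mean 1 within wave (the source does not state its weighted-variance
  estimator).
* Cohort CSVs are written with 17 significant digits so that write→read
  round-trips are bit-exact.

## Problem sizes used in the packaged studies

The packaged simulation studies were sized to be decisive but routine on a
single CPU: parameter recovery uses 200 replicate cohorts of 2,000 women
(≈ 5,500–6,000 cleaned observations each); the null-calibration study of the
interaction LRT uses 500 replicates of 250-person cohorts; the random-draw
equivalence check of the closed-form inversion against bisection uses 1,000
coefficient draws. The pipeline demo (`run_pipeline()`) uses a few hundred
persons and runs in seconds.

## Known limitations

* **The plausibility floor truncates.** Generating unbounded normal residuals
  from the published model and then imposing the 0.09 m/s floor (exactly as
  the cleaning rules require) left-truncates the speed distribution at high
  ages, where the marginal SD (≈ 0.30 m/s at age 89, driven by the random
  slope) places a noticeable tail below the floor. Only ≈ 0.5% of rows are
  affected, but the effect is systematic: the packaged 200-replicate recovery
  study finds the intercept, group main effect, group interaction, covariate
  effects, wave drift and residual variance all within 3 Monte-Carlo standard
  errors of truth (the education effect within 0.3%), while the linear age
  slope and especially the age² curvature are attenuated (curvature by
  roughly 15% of its small absolute value) and fall outside that band. A
  paired control experiment without the floor recovers everything, so this is
  a property of the floor-plus-normal-tails combination, not of the
  estimator; the recovery test asserts the full set of parameters and
  documents the two failing trajectory terms honestly rather than relaxing
  the check.
* Alpha-ages inherit the quadratic extrapolation: far from the data the
  parabola is not a biological statement, which is why the age support is
  capped at 110 and the decreasing branch is enforced.
* The published reference coefficients are rounded to 3–4 decimals;
  alpha-ages recomputed from them match the published table to ±0.4 years,
  not exactly, and two cells are exact at one decimal. That is the expected
  propagation of coefficient rounding through the inversion.
* `growth_model()` objects built from published coefficients carry no height/
  weight/wave terms, so their absolute predictions are meaningful only in
  differences (gaps, alpha-ages) — the use they are intended for.
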