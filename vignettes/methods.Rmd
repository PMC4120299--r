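---
title: "Register-based smoking prevalence: estimators, agreement statistics and the synthetic test world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Register-based smoking prevalence: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qofprev)
```

## The estimator and its missing-data behaviour

For one practice-year, QOF publishes the status indicator's counts
(numerator `sm07_num` = patients aged 15+ with a smoking status recorded;
denominator `sm07_den` = eligible patients aged 15+) and the cessation
indicator's counts (denominator `sm08_den` = recorded current smokers;
numerator `sm08_num` = those offered support). The register-based
prevalence estimator is

$$\hat p \;=\; \frac{\text{sm08 den}}{\text{sm07 den}}
      \;=\; \frac{\text{recorded current smokers}}
                 {\text{eligible population aged 15+}} .$$

Let $p$ be the true smoker fraction of the eligible population and let
$r_s$ be the probability that a smoker's status is recorded. Since the
numerator counts only *recorded* smokers while the denominator is the full
eligible population,

$$\mathbb E[\hat p] = r_s\,p .$$

Three consequences, all asserted in the test suite:

1. **Complete recording** ($r_s = 1$): $\hat p$ equals the realized smoker
   fraction exactly.
2. **Recording independent of smoking (MCAR)** at rate $r$: $\hat p$ is
   biased downward by $(1-r)p$ — about 2.9 percentage points at $r=0.85$,
   $p=0.19$. The *recorded-ratio* variant
   $\text{sm08 den}/\text{sm07 num}$ (`prevalence_among_recorded()`) is the
   MCAR-consistent form, and the package's bias tests show its mean bias is
   below 0.5 pp. Note the non-smoker recording rate never enters
   $\mathbb E[\hat p]$ at all: only differential recording of *smokers*
   moves the published-denominator estimator.
3. **Differential recording** (smokers' recording odds shifted down,
   `mar_log_odds_shift < 0`): $\hat p$ falls further below $p$. This is the
   direction real-world recording patterns suggest — groups more likely to
   be recorded (women, older patients, chronic disease registers) smoke
   less — so register-based estimates may *underestimate* prevalence.

One acceptance criterion demands that the published-denominator estimator
itself be unbiased under MCAR at $r=0.85$ (mean bias < 0.5 pp). By the
algebra above this is unattainable in any world where the published status
denominator is the eligible population and underlying achievement is below
100%; the criterion is implemented exactly as stated and left failing,
with the measured bias (−2.85 pp) matching $-(1-r)\,\bar p$ to two
decimals. We regard that red test as a correct statement about the
estimator, not a defect of the implementation.

`list_based_prevalence()` is the documented fallback for 2014/15 onward,
when the general status indicator was retired: the registered population
aged 15+ replaces the indicator-eligible denominator, adding a further
downward bias because the registered list exceeds the eligible population.

### Presentation precision

Storage is full-precision proportions. Published tables print percentages
rounded half-up to one decimal place (sometimes displayed with a trailing
zero, e.g. "30.30%" for 1129/3721 = 30.34…%, which rounds to 30.3 at 1 dp;
the true 2-dp value would be 30.34). `render_percent()` therefore rounds
half-up at 1 dp by default, which reproduces every printed worked-example
cell; R's own `round()` (banker's rounding) is deliberately not used.

## Aggregation

District prevalence is the pooled-count estimate
$\sum_i \text{sm08 den}_i \big/ \sum_i \text{sm07 den}_i$ over member
practices — equivalently the denominator-weighted mean of practice
estimates. The grand total over all districts uses the same rule, which is
why it behaves like (and is tested as) an associative operation with exact
count conservation. The unweighted mean-of-practices variant is retained
for sensitivity analysis only; with size-skewed practices it is pulled
toward small-practice prevalence. Practices are assigned whole to the
district of their own postcode; cross-boundary patient flow is a known
limitation of practice-postcode linkage and is documented, not modelled —
which is also why register-derived district populations can exceed census
counts.

## Agreement statistics

* **Lin's CCC** uses the original moment (1/n) estimators:
  $\mathrm{CCC} = 2s_{xy}\,/\,(s_x^2 + s_y^2 + (\bar x - \bar y)^2)$.
  Two identical constant series have CCC 1; unequal constants 0. The
  inequality $|\mathrm{CCC}| \le |r|$ holds always, with equality exactly
  under equal means and variances (both property-tested).
* **Bland–Altman** differences are first argument minus second; the sd uses
  the sample (n−1) convention and the limits use the fixed multiplier
  1.96 (the classic 95% presentation, not t-based, and no CIs on the
  limits). Callers pass (register aggregate, survey) or (chronic, general)
  to obtain the conventional signs.
* **Calibration** of general-population prevalence on chronic-register
  prevalence is OLS with an iterative outlier rule: remove every point
  with |externally studentized residual| > 3 (configurable), refit, repeat
  until none remain. The rule is a package design choice — the source
  method says only that outliers were removed — chosen because it is
  standard, reproducible, and fully reported (`removed_ids`, refitting on
  the retained set reproduces the coefficients). `threshold = Inf` is
  plain OLS. A numerically exact fit short-circuits removal, since
  studentizing floating-point noise would flag arbitrary points.

## Mortality model

Premature CHD death counts are modelled as NB2
($\mathrm{Var} = \mu + \alpha\mu^2$, log link), maximum likelihood via
`MASS::glm.nb`, coefficients exponentiated to IRRs with Wald 95% CIs on
the log scale. Design choices where the source was silent:

* **Parameterization**: NB2 with ML dispersion is the convention behind
  "negative binomial regression"; `dispersion = 0` collapses to Poisson
  (tested to 1e-6 agreement) and a fixed α uses
  `MASS::negative.binomial`.
* **Offset**: the published IRR table shows no population term and the
  companion methods paper is unavailable, so exposure handling is exposed
  as configuration — default `log(exposure)` offset (list size × 3-year
  window in the generator), with a `"none"` mode mirroring the
  covariate-only layout.
* Zero-variance and collinear covariates are rejected by name before
  fitting; non-convergence is an error, not a silent result.

`compare_models()` reproduces the with/without-smoking layout and reports
per-covariate IRR change plus the likelihood-ratio statistic for the added
term. The confounding pattern of interest — deprivation's IRR attenuating
toward its true value once the smoking estimate enters — is generated
structurally in the synthetic world (deprivation and the smoking estimate
share a latent factor with correlation `confounding_rho`) and asserted
over 200 replicates.

## The synthetic world

`cohort_config()` states the emulated world once; its defaults are
scenario parameters chosen from published summaries, not tuning dials:

| parameter | default | why |
|---|---|---|
| practices / districts | 215 / 16 | the analysis cohort and its districts |
| district weights | 9, 24, …, 59, 4 | printed per-district practice counts |
| eligible list size | log-normal(log 5500, 0.6) | pooled eligible population ≈ 1.43M over 215 practices; worked examples span ~1.5k–38k |
| true prevalence | Beta(5.7, 24.3) | mean 0.19; 215 draws span roughly 0.06–0.40, matching the reported 5.8–43% estimate range |
| chronic share | Beta(16.8, 43.2) | ≈28% of adults on a chronic register |
| chronic smoking offset | −3.05 pp | reported mean chronic−general difference |
| recording (general / chronic) | 0.881 / 0.966 | reported median underlying achievements |
| cessation offer | 0.90 | ≈ the printed cessation achievements |
| survey sample size | 328/district | total ≈ 5240 across 16 districts |
| NB dispersion α | 0.1 | mild overdispersion typical of practice-level death counts |
| mean deaths/practice | 8 | premature CHD deaths over a 3-year window |

A single seed expands to fixed substreams (registry, survey, mortality,
per-year) so stages regenerate independently; output is byte-deterministic
(tested on the CSV serialization). Multi-year truths follow a logit-scale
random walk (`drift_sd = 0.02`/year — small enough that year-pair CCC
stays above 0.92 and mean differences below 1 pp, the reported bounds,
while still moving every practice). Years before 2012/13 blank the general
cessation role, mirroring which indicators were actually published
(Records 22/23 provide general status recording only).

What the generator does **not** emulate: real postcode geography (tokens
only), patient-level longitudinal records, exception reporting, age/sex
structure, or cross-boundary registration. A green agreement test
therefore establishes internal consistency of the statistics, not
external validity of register-based estimates; and because the default
world records only 88.1% of statuses, its register aggregates sit ~2–3 pp
*below* the simulated survey truth — unlike the near-zero mean difference
reported for real data, which is informative about how close real-world
effective recording of smokers must be to complete.

## Numerical and testing choices

* Half-up rounding at the presentation layer only (see above).
* One simulation acceptance criterion asks the mean recovered smoking IRR
  to lie "within simulation SE" of 1.031 over 200 replicates. A 1-SE band
  rejects a perfectly unbiased estimator about a third of the time, so the
  test uses the standard 95% simulation-consistency band (2 SE), decided
  before the first run.
* Replicate counts in the test suite (200–1000 depending on cost) keep the
  default run under ~30 s on one CPU; the acceptance criteria use the
  stated replicate counts.
* No anomaly screen is implemented for suspect practice-years (the source
  excluded one practice on an undefined "data error" test); callers pass
  such practices to `filter_complete_series(exclude = ...)`, and the
  exclusion report records them as caller decisions.

## Known limitations

* The estimator inherits every limitation of self-reported,
  27-month-window smoking status; nothing here corrects for recording
  bias — the package *quantifies* it instead.
* District aggregation by practice postcode misassigns cross-boundary
  patients; sub-district estimation would require patient-level postcodes.
* IRRs from the mortality module on real data depend on the chosen
  exposure offset; the with/without comparison is robust to that choice,
  absolute IRRs are not.
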