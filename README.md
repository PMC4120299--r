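# qofprev

Smoking prevalence estimation from QOF pay-for-performance indicator data.

## The problem

England's Quality and Outcomes Framework (QOF) publishes, for every general
practice and year, the numerator and denominator of each pay-for-performance
indicator. Two of the smoking indicators identify, respectively, the
patients aged 15+ whose notes record a smoking status (status indicator,
e.g. SM07 in 2012/13) and the recorded current smokers offered cessation
support (cessation indicator, SM08). Although QOF was never designed to
measure smoking, the ratio of two published *denominators*,

```
prevalence = cessation denominator / status denominator
           = recorded current smokers / eligible patients aged 15+
```

is a free, practice-level smoking prevalence estimate. `qofprev` implements
this estimator and everything needed to use and appraise it:

- **qof_io** — readers/validators for long- and wide-format indicator
  extracts, an indicator code map across years (SM01–SM08, SMOK001–005,
  Records 22/23), a postcode → local-authority-district lookup, and the
  complete-series filter used to build an analysis cohort;
- **estimators** — the prevalence estimator, underlying achievements,
  chronic-condition share, the post-2014/15 list-based variant, and the
  recorded-ratio variant used in bias analysis;
- **aggregation** — pooled-count aggregation of practices to districts
  (Σ numerators / Σ denominators), plus mean-based sensitivity variants;
- **agreement_stats** — Pearson correlation, Lin's concordance correlation
  coefficient (CCC), Bland–Altman 95% limits of agreement, the
  chronic → general calibration regression with iterative studentized-
  residual outlier removal, and pairwise year-over-year concordance;
- **mortality_model** — NB2 negative binomial regression of premature CHD
  death counts (variance μ + αμ², log link) reported as incidence rate
  ratios, with a with/without-covariate comparison;
- **synthetic_data** — a generator of QOF-like registries with known
  ground truth (per-practice true prevalence, recording completeness —
  MCAR or differential — chronic registers, district survey draws,
  NB mortality counts) for bias and parameter-recovery studies;
- **pipeline_cli** — a file-based pipeline (`run_pipeline()`) and CLI
  (`qof_cli()`, wrapper in `inst/cli/qofprev`) chaining
  simulate → estimate → aggregate → agree → model.

## Worked example

The bundled extract `inst/extdata/qof_example_2012.csv` contains five
practices' 2012/13 status and cessation indicator counts:

```r
library(qofprev)
records <- read_indicator_table(
  system.file("extdata", "qof_example_2012.csv", package = "qofprev"))
est <- derive_practice_estimates(records)
data.frame(practice = est$practice_id,
           prevalence = paste0(render_percent(est$prevalence_general), "%"),
           status_recording = paste0(render_percent(est$ua_status_general), "%"))
#>   practice prevalence status_recording
#> 1        A      30.3%            92.7%
#> 2        B      26.8%            88.1%
#> 3        C      22.6%            89.2%
#> 4        D        29%            84.8%
#> 5        E      32.9%            90.2%
```

Practice A: 1129 recorded smokers among 3721 eligible patients → 30.3%.
`status_recording` is the underlying achievement of the status indicator —
the fraction of eligible patients with any status recorded (92.7% for A);
the gap to 100% is exactly the estimator's exposure to missing data.

Pooling the five practices into one district:

```r
agg <- aggregate_pooled(records, setNames(rep("E060X", 5), records$practice_id))
#> pooled district prevalence: 28.7% (16420 smokers / 57117 eligible)
```

An end-to-end synthetic run with known truth:

```r
res <- run_pipeline(list(outdir = tempdir(), seed = 42, simulate = TRUE))
res$agreement
#> Agreement summary (16 pairs)
#>   mean difference: -3.31 (95% limits of agreement -6.89, 0.28)
#>   Pearson r: 0.889   Lin's CCC: 0.555
res$model
#> Model comparison (added covariate LRT: stat = 12.62, p = 0.000381)
#>          term IRR without IRR with change
#>   deprivation       1.027    1.017 -0.010
#>     pct_white       1.003    1.003 +0.000
#>    pct_over65       0.997    0.995 -0.002
#>  smoking_prev          NA    1.024     NA
```

The −3.31 pp mean difference against the simulated survey is not a bug:
the default world records 88.1% of statuses, and the estimator's
expectation is (recording rate × truth) — see the methods vignette
(`vignettes/methods.Rmd`) for the bias algebra and what the tests do and
do not establish. The deprivation row shows the confounding pattern the
mortality module is designed to expose: its IRR attenuates (1.027 → 1.017)
once the smoking estimate enters the model.

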