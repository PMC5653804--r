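# rtrisk

Radiotherapy toxicity and secondary-cancer risk modelling for matched
breast-cancer cohorts described by dose-volume histograms (DVHs).

`rtrisk` is aimed at medical physicists and outcome modellers comparing
treatment techniques (IMRT vs VMAT) on observational cohorts. It
implements the full analysis chain:

- **DVH handling** — cumulative/differential curves, V\_x and mean-dose
  metrics, a TPS-neutral CSV dialect (`dvh()`, `v_at()`, `mean_dose()`,
  `dosimetric_vector()`, `read_dvh_file()`);
- **propensity-score caliper matching** — logistic propensity model,
  greedy 1:1 nearest-neighbour matching on the logit within a caliper of
  0.2 × SD(logit), without replacement, with balance diagnostics
  (`fit_propensity()`, `match_caliper()`, `balance_diagnostics()`);
- **dominant-factor selection** — L1-penalized logistic regression over
  MD + V5…V50 with 10-fold cross-validation and the one-standard-error
  rule (`fit_lasso_path()`, `cv_select()`);
- **LKB NTCP modelling** — the Lyman–Kutcher–Burman probit dose-response

  NTCP(x) = Φ((x − TV₅₀) / (m·TV₅₀)),   (volume parameter n = 1)

  fit by maximum likelihood with profile-likelihood 95% CIs, plus AUC,
  Hosmer–Lemeshow, scaled Brier score and calibration slope
  (`fit_lkb()`, `model_performance()`, `invert_lkb()`);
- **Schneider secondary-cancer risk** — risk-equivalent dose with
  fractionation correction α′ = α(1 + d/(α/β)), organ equivalent dose,
  and excess absolute risk with age modifiers
  EAR = β·OED·exp(γₑ(ageₓ−30) + γₐ ln(ageₐ/70)), per organ at risk
  (`red_full()`, `oed()`, `ear()`, `cohort_scr()`);
- **a synthetic cohort generator** with known ground truth standing in
  for restricted patient data (`synth_config()`, `generate_cohort()`),
  and an end-to-end pipeline (`run_pipeline()`, `make_figures()`).

The methods vignette
(`vignettes/radiotherapy-risk-modelling.Rmd`) documents the models,
their assumptions, the generator's design and the package's numerical
choices.

## Worked example

Synthesize a confounded two-arm cohort, match it, select the dominant
lung dosimetric factor, and fit the NTCP model (the generator's ground
truth is TV₅₀ = 15.07 % lung volume, m = 0.62, acting on V40):

```r
library(rtrisk)
cfg <- pipeline_config(synth = synth_config(n_per_arm = 100), seed = 1)
report <- run_pipeline(cfg, out_dir = "demo_run")
#> pipeline seed 1 (synth 102, folds 203, fit 304)
#> cohort: 200 patients (IMRT 81, VMAT 119)
#> matching: 58 pairs within caliper 0.1811, 23 unmatched
#> selection: dominant factor V40 at lambda 0.0885

summary(report$ntcp$fit)
#> LKB NTCP model fit (n = 1 volume parameter), factor: V40
#>   116 patients, 60 events
#>   TV50      13.6  (95% CI 11.44-15.94)
#>   m       0.5626  (95% CI 0.4132-0.8394)
#>   log-likelihood -49.9149
#> Model performance
#>   AUC              0.879
#>   Hosmer-Lemeshow  chi2 = 4.430 (df 8), p = 0.816
#>   scaled Brier     0.438
#>   calibration      slope 0.996, intercept -0.008
```

The matched cohort has 58 pairs inside the caliper; LASSO recovers the
generating factor (V40), and the fitted TV₅₀ = 13.6 (CI 11.4–15.9) and
m = 0.56 (CI 0.41–0.84) cover the generator's truth. Planning
thresholds follow by inverting the fitted curve:

```r
cf <- coef(report$ntcp$fit)
round(invert_lkb(c(0.25, 0.5), cf[["TV50"]], cf[["m"]]), 2)
#> [1]  8.44 13.60       # V40 (%) at 25% and 50% predicted RP risk
```

With the published fit (TV₅₀ = 15.07, m = 0.62) the same inversion gives
the 15.07 % and 8.8 % planning thresholds at 50 % and 25 % risk.

The secondary-cancer arm (here with the packaged *synthetic* organ
parameter template — substitute published values for real analyses)
summarizes OED per organ and arm:

```r
report$scr$summary[, c("organ", "oed_mean_IMRT", "oed_mean_VMAT", "p_oed")]
#>           organ oed_mean_IMRT oed_mean_VMAT    p_oed
#> 1     lung_ipsi         10.84         10.68 1.94e-01
#> 2   lung_contra          3.86          5.15 1.79e-12
#> 3 breast_contra          2.80          3.63 2.15e-11
#> 4   spinal_cord          5.53          5.67 4.28e-01
#> 5         liver          3.87          3.90 9.67e-01
#> 6       stomach          2.82          2.97 1.37e-01
```

mirroring the qualitative pattern the generator encodes: VMAT lowers
ipsilateral-lung exposure but spreads slightly more dose to the
contralateral lung and breast. `make_figures(report)` renders the mean
DVH, dose-response, scatter and OED/EAR figures into the run directory.

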