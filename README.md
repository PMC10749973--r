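# ntrasym

Trimodal radiodensitometric modelling and left–right soft-tissue asymmetry
analysis of mid-thigh CT, for researchers studying sarcopenia and mobility
in aging cohorts.

A mid-thigh CT cross-section, restricted to soft tissue (−200 to 200
Hounsfield units), shows three radiodensity modes: adipose tissue
[−200, −10] HU, loose connective tissue [−9, 40] HU and lean muscle
[41, 200] HU. `ntrasym` fits each leg's HU histogram with a sum of three
skewed-Gaussian modes,

φ(x; N, μ, σ, α) = N/(σ√(2π)) · exp(−(x−μ)²/(2σ²)) · erfc(α(x−μ)/(σ√2)),

with the connective mode constrained symmetric (α = 0), yielding 11
parameters per leg (N, μ, σ per tissue; α for fat and muscle). The mode
integrates to N for every α, so amplitudes are tissue masses in pixels.
Per subject, the 11 asymmetry indicators are the absolute left-minus-right
parameter differences Δᵢ = |Lᵢ − Rᵢ|. The cohort workflow runs paired
left–right t-tests, min-max normalization across the cohort, per-age
averaging, cubic age-trend fits with R²-based selection of the most
age-varying indicator per tissue, and stratified trend comparison across
BMI (18.5/25/30 kg/m²), gait-speed (1.0 and 1.3 m/s) and timed-up-and-go
(10/13/29 s) classes.

Because clinical cohorts of this kind are access-restricted, the package
ships a synthetic cohort generator with a ground-truth ledger
(age-dependent asymmetry, linked mobility outcomes, sampled histograms) so
the entire pipeline is testable end to end.

## Worked example

```r
library(ntrasym)

coh <- generate_cohort(cohort_config(n_subjects = 300, sampling_mass = 0,
                                     seed = 42))
res <- run_asymmetry_pipeline(coh, groupings = "gait_fast_class")
res$selected
#> # A tibble: 3 × 4
#>   tissue parameter r_squared tie
#>   <chr>  <chr>         <dbl> <lgl>
#> 1 fat    N_fat         0.878 FALSE
#> 2 con    sigma_con     0.814 FALSE
#> 3 mus    sigma_mus     0.877 FALSE
```

The fat amplitude and the muscle and connective widths are the indicators
whose cubic age trends explain the most variance (R² ≈ 0.81–0.88 here) —
exactly the three the generator made rise with age. The paired t-test
table (`res$ttests`) reports per-parameter side means, t and raw p:

```r
head(res$ttests[, c("tissue", "parameter", "mean_left", "mean_right",
                    "t_stat", "p_value")], 4)
#> # A tibble: 4 × 6
#>   tissue parameter mean_left mean_right t_stat p_value
#> 1 fat    N_fat     32954.     33020.    -1.14   0.255
#> 2 fat    mu_fat      -70.5      -70.6    2.27   0.0237
#> 3 fat    sigma_fat    25.0       25.1   -1.18   0.239
#> 4 fat    alpha_fat     0.492      0.492  0.166  0.868
```

With histograms (`sampling_mass = 1e5`), `fit_ntra_cohort()` recovers the
per-leg parameters from the binned HU counts first; `autoplot()` methods
draw the fitted trimodal decomposition, the selected age trends and the
stratified group curves. `inst/cli/ntrasym.R` wraps the same functions as
a small command line (`simulate`, `fit`, `all`).

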