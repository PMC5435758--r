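# calbold

Graded-hypercapnia calibrated BOLD: joint estimation of the calibration
parameter **M** and the dose-wise basal CMRO2 response to hypercapnia
(**κ**) from BOLD and CBF responses at two or more end-tidal CO2 levels.

## The problem

Calibrated BOLD turns fMRI signal changes into estimates of the cerebral
metabolic rate of oxygen (CMRO2). The classical calibration breathes CO2
and assumes the stimulus is purely vascular — CBF rises, CMRO2 does not
(the *iso-metabolic assumption*). If basal CMRO2 actually falls during
hypercapnia, the calibration parameter M is overestimated, and so is every
CMRO2 value computed from it.

`calbold` implements the graded alternative. With BOLD and CBF responses
measured at two or more CO2 levels, and CMRO2 assumed linear in the
end-tidal CO2 increase, the Davis model

&nbsp;&nbsp;&nbsp;&nbsp;ΔBOLD/BOLD₀ = M · (1 − f^(α−β) · (1 + κ·ΔP)^β)

(f = CBF ratio, ΔP = ΔP<sub>ET</sub>CO₂ in mmHg) yields one equation per
level in the two unknowns (M, κ). Solving them jointly measures the CMRO2
dose–response instead of assuming it away.

The package covers the full chain:

* **model** — Davis equation, linear dose model, their composition and
  inversions, echo-time contrast helpers (`davis_bold()`, `graded_bold()`,
  `invert_for_cmro2()`, `relative_bold_contrast()`);
* **fit** — bounded Levenberg–Marquardt fitting (`fit_graded()`), the
  classical κ = 0 fit (`fit_isometabolic()`), an independent exact
  two-level solver (`solve_two_level_exact()`), paired comparison and
  boundary-aware group statistics with exact Wilcoxon signed-rank tests
  (`compare_fits()`, `group_summary()`);
* **preprocess** — dual-echo tag/control ASL preprocessing: surround
  subtraction and averaging, two-echo R2\*, baseline detrending, block
  responses, end-tidal levels, ROI averaging (`hypercapnia_levels()` runs
  the chain);
* **simulate** — a synthetic dual-echo experiment generator with known
  ground truth and a parameter-recovery harness (`sim_config()`,
  `simulate_dualecho()`, `recovery_experiment()`);
* **CLI** — `calbold_cli()` with `simulate`, `preprocess`, `fit`,
  `pipeline`, `group`, `recover` subcommands (launcher in `inst/cli/`).

All functions take data frames and return tibbles; fitted objects have
`tidy()`/`glance()` methods and `autoplot()` views.

## Worked example

A cited global CMRO2 decrease of 13.4 % at a +8.7 mmHg end-tidal CO2
increase corresponds, through the linear dose model, to

```r
library(calbold)
100 * kappa_from_cmro2_ratio(1 - 0.134, 8.7)
#> [1] -1.54023
```

i.e. κ ≈ −1.5 %/mmHg — a 1.5 % drop in basal CMRO2 per mmHg of CO2.

Fitting two-level data (here generated from the forward model with
M = 8.6 %, κ = −1.3 %/mmHg, gray-matter-like responses):

```r
levels <- tibble::tibble(delta_petco2 = c(4.8, 8.4),
                         cbf_ratio    = c(1.13, 1.17))
levels$bold_frac <- graded_bold(0.086, -0.013,
                                levels$cbf_ratio, levels$delta_petco2)
fit_graded(levels)
#> <calbold_fit: graded model, 2 level(s), pairing empirical (alpha=0.14, beta=0.91)>
#>   M     = 8.6 %
#>   kappa = -1.3 %/mmHg
#>   residual norm = 0; boundary hit: none

fit_isometabolic(levels)
#> <calbold_fit: isometabolic model, 2 level(s), pairing empirical (alpha=0.14, beta=0.91)>
#>   M     = 14.62 %
#>   residual norm = 1.47e-06; boundary hit: none
```

The two-parameter fit recovers the generating values exactly, while the
iso-metabolic fit — forced to explain the same data with κ = 0 — inflates
M from 8.6 % to 14.6 %: the bias the graded design removes.

Recovery from full synthetic experiments (18-min dual-echo ASL scans with
realistic noise, gas settling, drift and TE1 contamination):

```r
rec <- recovery_experiment(sim_config(), n_sims = 20, seed = 1)
rec$summary
#> # A tibble: 2 × 7
#>   parameter  truth     bias      sd    rmse n_interior boundary_rate
#>   <chr>      <dbl>    <dbl>   <dbl>   <dbl>      <int>         <dbl>
#> 1 m          0.086 0.00781  0.0246  0.0251          19          0.05
#> 2 kappa     -0.013 0.000979 0.00877 0.00859         19          0.05
```

Bias is small relative to the spread; one run in twenty hit a parameter
bound and is excluded from the error statistics, mirroring how
boundary-hit subjects are excluded from group analyses.

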