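---
title: "Graded-hypercapnia calibrated BOLD: models, estimation, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graded-hypercapnia calibrated BOLD: models, estimation, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calbold)
```

## The problem

Calibrated BOLD converts blood-oxygenation-level-dependent (BOLD) fMRI
signal changes into estimates of the cerebral metabolic rate of oxygen
(CMRO2). It hinges on a calibration parameter $M$ — the theoretical
maximal BOLD signal increase if all deoxyhemoglobin were removed — that is
classically measured with a hypercapnic gas challenge under the
*iso-metabolic assumption*: breathing CO2 raises cerebral blood flow (CBF)
but leaves CMRO2 untouched. A body of evidence suggests basal CMRO2 in
fact falls during hypercapnia, which inflates $M$ and propagates into
every downstream CMRO2 estimate.

`calbold` implements the graded-hypercapnia alternative: acquire BOLD and
CBF responses at *two or more* CO2 levels, assume CMRO2 varies *linearly*
with the end-tidal CO2 increase, and solve jointly for $M$ and the
dose-wise CMRO2 slope $\kappa$ — removing the iso-metabolic assumption
while measuring the CMRO2 response it replaced.

## Models

The Davis/Hoge signal model relates the fractional BOLD change to the CBF
and CMRO2 ratios ($f = \mathrm{CBF}/\mathrm{CBF}_0$,
$r = \mathrm{CMRO_2}/\mathrm{CMRO}_{2,0}$):

$$\frac{\Delta \mathrm{BOLD}}{\mathrm{BOLD}_0}
  = M\left(1 - f^{\alpha-\beta}\, r^{\beta}\right)$$

with $\alpha$ the assumed CBF–CBV coupling exponent and $\beta$ the
power-law exponent linking venous deoxyhemoglobin to transverse
relaxation. The linear dose model for hypercapnia is

$$r = 1 + \kappa\,\Delta P_{ET}\mathrm{CO}_2,$$

and substituting it into the Davis model gives the two-unknown forward
model `graded_bold()`, one equation per CO2 level. With exactly two levels
the system is square; with more it is solved in the least-squares sense.

Three $(\alpha, \beta)$ conventions are built in: `"empirical"`
$(0.14, 0.91)$, `"3T"` $(0.2, 1.3)$, and `"simplified"` $(0.06, 1.0)$ —
the last expressing the single-exponent simplified model in
$\alpha/\beta$ form. All internal quantities are *fractions* (BOLD change,
$M$, $\kappa$ per mmHg); percent and %/mmHg appear only at file and CLI
interfaces. This avoids silent 100-fold errors inside the exponentiated
expressions.

## Estimation

`fit_graded()` minimises the sum of squared BOLD-fraction residuals by
bounded Levenberg–Marquardt least squares (`minpack.lm::nls.lm`), with box
constraints $0.01 < M < 0.20$ and $-0.05 < \kappa < +0.05$ /mmHg — broad
physiological bounds; estimates that *reach* a bound are flagged and, by
convention, excluded from group statistics as noise-dominated fits rather
than physiological outliers. For gas increases above 20 mmHg the lower
$\kappa$ bound is additionally tightened to keep $1 + \kappa \Delta P$
positive, so the objective stays finite without silent clamping.

Two numerical subtleties matter and shaped the defaults:

* **Multi-start.** On two-level data the objective can possess local
  minima and — rarely (about 1 in 150 random noiseless instances) — *two
  exact interior solutions*. A single start converges to a bound or the
  far root in a few percent of cases, so the default explores the initial
  guess $(0.05, 0)$ plus a $4 \times 7$ ($M \times \kappa$) grid of
  interior starts; the $\kappa$ axis is the dense one because the two
  roots' basins separate along $\kappa$. Among numerically tied minima
  the smallest-$|\kappa|$ solution is reported. `multi_start = FALSE`
  gives a faster single-start path that escalates to the grid only when
  the first solution touches a bound or leaves a clearly non-zero
  residual.
* **The exact two-level oracle.** `solve_two_level_exact()` eliminates
  $M$ by taking the ratio of the two model equations and finds $\kappa$
  by bracketed root finding over the positivity domain, Newton-polishing
  each root to machine precision (an error of $10^{-10}$ in $\kappa$ is
  amplified roughly 60-fold into $M$). Tangent (double) roots, which
  produce no sign change, are recovered by polishing local minima of the
  ratio function that reach numerical zero. Only roots whose $(M, \kappa)$
  lie inside the parameter box are admissible — the mathematically
  smaller-$|\kappa|$ root occasionally has $M$ outside the box or even
  negative. The oracle is an independent code path used to cross-check
  the least-squares route; the two agree to better than $10^{-10}$
  relative on well-posed noiseless instances. Near-tangent systems are
  excluded from that comparison: at a double root the data barely
  constrain $\kappa$ and no algorithm can pin it down.

`fit_isometabolic()` is the classical fit with $\kappa \equiv 0$. That
model is linear in $M$, so its bounded least-squares solution is the
closed-form projection clamped to the box. Comparing the two fits
per subject (`compare_fits()`) reproduces the method's central
observation: when the true $\kappa$ is negative, the iso-metabolic $M$ is
systematically inflated.

### Group statistics

`group_summary()` reports mean ± SEM (sample SD over $\sqrt{n}$, $n-1$
denominator) across subjects whose fits stayed interior, and a two-sided
Wilcoxon signed-rank test of $\kappa$ against zero or of paired $M$
differences. The signed-rank test drops zero differences, assigns
midranks to ties, and enumerates the exact null via a generating-function
convolution for $n \le 25$ (handling ties exactly), switching to the
tie-corrected normal approximation with continuity correction above. The
implementation is cross-checked against `stats::wilcox.test` where the
latter's exact path applies.

## Preprocessing

The raw input is an interleaved tag/control dual-echo ASL time series.

* `perfusion_series()` — surround subtraction: each label stream of echo 1
  is linearly interpolated onto the full TR grid (linear extrapolation at
  the ends, so the operator is exactly linear) and subtracted,
  control − tag. Under QUIPSS II acquisition the difference signal is
  proportional to CBF; no absolute quantification is attempted.
* `bold_series()` — surround averaging of echo 2, (control + tag)/2.
* `r2star_series()` — per-time-point two-echo estimate
  $R_2^* = \log(S_1/S_2)/(TE_2 - TE_1)$ within each label stream, streams
  combined by surround averaging.
* `detrend_baseline()` — an OLS line fitted to baseline steady-state
  samples only is subtracted from the whole series; the removed baseline
  level is retained so percent changes stay referenced to it.
* `block_response()` / `endtidal_level()` — steady-state window means
  expressed as fractional change (or mmHg difference) from baseline.
* `roi_average()` — unweighted mean over mask voxels of a 4D volume
  (plain arrays or NIfTI via RNifti); masks must already be on the
  functional grid.

**Steady-state windows.** Gas levels need time to settle after each
transition, so block statistics use only the final part of each 2-min
block: by default the last 60 s (`steady_state_offset_s = 60`),
configurable per paradigm. Windows are half-open $[start, end)$ — a sample
on a block boundary belongs to the next block — and, for series built by
surround interpolation, the final sampling step of each window is also
discarded, because the interpolated partner of the last sample would
straddle the block boundary. Without that guard, noiseless block
responses carry a systematic error of order $3\times10^{-4}$.

**Sessions.** Responses are computed per session and then averaged per
subject (`average_session_levels()`), matching the convention of
averaging session-level responses rather than raw time series.

`hypercapnia_levels()` chains all of this into the per-level
$(\Delta P_{ET}\mathrm{CO}_2, \Delta\mathrm{BOLD}/\mathrm{BOLD}_0, f)$
table that the fitting layer consumes.

## The synthetic-data generator

`simulate_dualecho()` is the generative inverse of the analysis chain,
providing ground truth for parameter-recovery validation. Its defaults
emulate the design the method was developed for: an 18-min scan of 490
volumes (TR 2.2 s, TE 3.3/29 ms), three randomized 2-min blocks each of
baseline, +4 and +8 mmHg CO2, gray-matter-like responses (CBF ratios
1.13/1.17 at 4.8/8.4 mmHg, baseline $R_2^* = 31.7\,$s$^{-1}$), ground
truth $M = 8.6\,\%$ and $\kappa = -1.3\,\%$/mmHg.

All signals are driven by one *instantaneous dose* $d(t)$: the programmed
block-wise CO2 targets passed through a first-order settling filter
(`petco2_tau_s`, default 10 s). CBF follows the piecewise-linear
dose–response through the programmed points, BOLD follows the graded
model at the same dose, and the measured end-tidal trace is the same
settled dose plus breath-wise jitter. Driving everything from one dose
keeps the simulation internally consistent: what the capnograph reports
is what the vasculature responded to. BOLD is injected through
$R_2^*(t) = R_{2,0}^* - \log(1 + b(t))/TE_2$ so the echo-2 fractional
signal change equals the model's prediction *exactly*, which makes
recovery tests sharp. Control and tag volumes are recorded as
$S \pm D/2$ (static+BOLD signal $S$, perfusion difference $D$), so
surround averaging returns $S$ and surround subtraction returns $D$
exactly.

Choices a real scanner forces and the simulator mirrors:

| parameter | default | why |
|---|---|---|
| `perfusion_fraction` | 0.01 | typical gray-matter pulsed-ASL $\Delta M/M$ at baseline |
| `noise_sd` (echo1, echo2) | 0.3, 0.4 a.u. on $S_0 = 1000$ | calibrated so per-experiment $\kappa$ scatter (~0.9 %/mmHg SD) and the boundary-hit rate (~5 %) match what small-group graded-hypercapnia studies report; ROI averaging justifies sub-percent channel noise |
| `petco2_tau_s` | 10 s | settles within ~30 s, consistent with manual gas feedback reaching target within the pre-window minute; keeps the settling systematic under $10^{-3}$ in both parameters across block orderings |
| `petco2_jitter_sd` | 0.3 mmHg | breath-to-breath end-tidal variability |
| `drift_slope` | 0.01 a.u./s | ~1 % signal drift per 17 min |
| `physio_noise_sd` | 0 (off) | optional slow signal-proportional fluctuations (0.005–0.05 Hz random-phase sinusoids) |
| `te1_bold` | TRUE | the echo-1 difference signal carries a small $(1+b)^{TE_1/TE_2}$ BOLD weighting — a realistic nuisance the estimator must tolerate; turning it off (and the settling, jitter, drift) gives the idealized configuration used for machine-precision recovery tests |

Measured systematics at zero channel noise, worst over ten block
orderings: settling $9\times10^{-5}$ on $M$, TE1 contamination
$7.5\times10^{-4}$, drift $2.2\times10^{-3}$ (the multiplicative
drift×response interaction that linear detrending cannot remove). The
idealized configuration (all nuisances off) recovers $(M, \kappa)$
through the full pipeline to better than $10^{-6}$; the package's
exactness tests are stated for that configuration, and drift is exercised
under realistic noise where its effect sits inside the noise.

What the simulator does **not** emulate: motion, slice-timing and
transit-delay effects, inversion-efficiency variation, task-evoked
responses (the original experiment interleaved a visual/motor task, here
out of scope), spatially structured physiological noise, and
inter-subject physiological variability. Recovery results therefore
demonstrate estimator correctness and noise behaviour, not robustness to
every artefact of real data.

`recovery_experiment()` repeats simulate → preprocess → fit with per-run
seeds and summarises bias, SD, RMSE (over runs whose two-parameter fit
stayed interior — a boundary-stuck fit is a flagged failure, not an
estimate) and the boundary-hit rate (over all runs).

## Validation summary

The test suite establishes, among others:

* algebraic identities and frozen closed-form values for every model
  operation, including the `invert_for_cmro2()` ∘ `davis_bold()`
  round-trip on a parameter grid;
* exact agreement of `fit_graded()` with the independent two-level solver
  on 1000 seeded noiseless experiments (relative differences below
  $10^{-10}$), across all three $(\alpha,\beta)$ pairings;
* hand-computed fixtures for every preprocessing operation (interpolated
  ramps, label-dependent $R_2^*$, drift removal, window means);
* end-to-end recovery of $(M, \kappa)$ to $10^{-6}$ in the idealized
  configuration, unbiasedness within two standard errors at realistic
  noise (100 simulations), a boundary-hit rate that grows with noise, and
  the signature iso-metabolic $M$ inflation (~6 percentage points at
  $\kappa_{true} = -1.5\,\%$/mmHg, paired Wilcoxon $p < 10^{-13}$).

Problem sizes (1000 oracle instances, 100-simulation recovery runs,
60-simulation noise-grid points) were chosen so the whole suite documents
the method's behaviour while running in a few minutes on one CPU.

## Known limitations

* Group means of per-subject nonlinear fits do not equal the fit of
  group-mean responses; published group response tables therefore cannot
  serve as numeric oracles for $M$ and $\kappa$, and the package makes no
  attempt to reproduce per-subject results that were never deposited.
* The reported Wilcoxon variant (exact enumeration for $n \le 25$, zeros
  dropped) is one defensible convention; published p-values computed with
  unknown variants are not exact reproduction targets.
* The two-level system can be genuinely ambiguous (two admissible exact
  solutions) or ill-conditioned (near-tangent); `solve_two_level_exact()`
  reports root multiplicity so such cases are visible rather than silent.
* Voxelwise mapping of $M$ and $\kappa$, Bayesian fitting, absolute CMRO2
  quantification, and the upstream neuroimaging toolchain (segmentation,
  registration, activation mapping) are out of scope; ROI time series and
  masks are inputs.
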