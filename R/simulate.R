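#' Configuration for a synthetic graded-hypercapnia dual-echo ASL experiment
#'
#' Defaults emulate the acquisition the method was developed for: an 18-min
#' dual-echo PICORE QUIPSS II scan (490 repetitions, TR 2.2 s, TE1 3.3 ms,
#' TE2 29 ms) with randomized 2-min blocks of baseline, +4 and +8 mmHg
#' end-tidal CO2 (three blocks each), gray-matter-like responses
#' (CBF ratios 1.13 / 1.17 at measured increases of 4.8 / 8.4 mmHg,
#' baseline R2* 31.7 1/s), ground truth M = 8.6 % and
#' kappa = -1.3 %/mmHg, a 1 % baseline perfusion difference signal, white
#' Gaussian channel noise, and a slow linear scanner drift.
#'
#' @param m_true True calibration parameter (fraction).
#' @param kappa_true True dose-wise CMRO2 slope (fraction/mmHg).
#' @param cbf_ratio CBF ratio per hypercapnia level (dimensionless).
#' @param delta_petco2 Programmed end-tidal CO2 increase per level (mmHg);
#'   same length as `cbf_ratio`.
#' @param baseline_petco2 Normocapnic end-tidal CO2 (mmHg).
#' @param baseline_r2star Baseline R2* (1/s).
#' @param baseline_signal Static signal S0 at TE = 0 (a.u.).
#' @param perfusion_fraction Baseline tag/control difference amplitude as a
#'   fraction of S0 (typical gray-matter pulsed-ASL value ~1 %).
#' @param noise_sd Additive white Gaussian noise SD per channel,
#'   `c(echo1, echo2)` in a.u.
#' @param drift_slope Linear drift of S0 (a.u./s).
#' @param te1,te2,tr Echo times and repetition time (s).
#' @param n_reps Number of volumes (must be even; tag/control interleaved).
#' @param blocks_per_condition Blocks per condition (baseline and each
#'   level).
#' @param block_duration_s Block duration (s).
#' @param steady_state_offset_s Steady-state offset used when building the
#'   paradigm (s).
#' @param petco2_tau_s Exponential settling time constant of the measured
#'   end-tidal trace at gas transitions (s); 0 for instantaneous steps.
#' @param petco2_jitter_sd Breath-to-breath end-tidal jitter SD (mmHg).
#' @param breath_interval_s Breath sampling interval (s).
#' @param physio_noise_sd Low-frequency physiological "noise" as a
#'   fractional SD of the static signal (signal-proportional slow
#'   fluctuations, modelled as random-phase sinusoids in the 0.005-0.05 Hz
#'   band); 0 (default) disables it.
#' @param te1_bold If `TRUE` (realistic), the perfusion difference signal
#'   is present at both echoes and carries the instantaneous R2*, so the
#'   echo-1 difference is slightly BOLD-weighted; if `FALSE` (idealized),
#'   the difference signal exists only at echo 1 with baseline R2*, making
#'   the preprocessing outputs exact.
#' @param pairing An [ab_pairing()] or preset name used by the generative
#'   model.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(m_true = 0.086,
                       kappa_true = -0.013,
                       cbf_ratio = c(1.13, 1.17),
                       delta_petco2 = c(4.8, 8.4),
                       baseline_petco2 = 40,
                       baseline_r2star = 31.7,
                       baseline_signal = 1000,
                       perfusion_fraction = 0.01,
                       noise_sd = c(0.3, 0.4),
                       drift_slope = 0.01,
                       te1 = 0.0033, te2 = 0.029, tr = 2.2,
                       n_reps = 490L,
                       blocks_per_condition = 3L,
                       block_duration_s = 120,
                       steady_state_offset_s = 60,
                       petco2_tau_s = 10,
                       petco2_jitter_sd = 0.3,
                       breath_interval_s = 4,
                       physio_noise_sd = 0,
                       te1_bold = TRUE,
                       pairing = "empirical",
                       seed = NULL) {
  cfg <- list(
    m_true = m_true, kappa_true = kappa_true,
    cbf_ratio = cbf_ratio, delta_petco2 = delta_petco2,
    baseline_petco2 = baseline_petco2,
    baseline_r2star = baseline_r2star,
    baseline_signal = baseline_signal,
    perfusion_fraction = perfusion_fraction,
    noise_sd = rep_len(noise_sd, 2L),
    drift_slope = drift_slope,
    te1 = te1, te2 = te2, tr = tr,
    n_reps = as.integer(n_reps),
    blocks_per_condition = as.integer(blocks_per_condition),
    block_duration_s = block_duration_s,
    steady_state_offset_s = steady_state_offset_s,
    petco2_tau_s = petco2_tau_s,
    petco2_jitter_sd = petco2_jitter_sd,
    breath_interval_s = breath_interval_s,
    physio_noise_sd = physio_noise_sd,
    te1_bold = isTRUE(te1_bold),
    pairing = ab_pairing(pairing),
    seed = if (is.null(seed)) NULL else as.integer(seed))
  for (nm in c("m_true", "baseline_petco2", "baseline_r2star",
               "baseline_signal", "perfusion_fraction", "te1", "te2", "tr",
               "block_duration_s")) {
    check_finite(cfg[[nm]], nm)
    if (any(cfg[[nm]] <= 0)) {
      cb_stop(sprintf("`%s` must be positive", nm), "calbold_config_error")
    }
  }
  if (length(cfg$cbf_ratio) != length(cfg$delta_petco2)) {
    cb_stop("cbf_ratio and delta_petco2 must have one entry per level",
            "calbold_config_error")
  }
  if (any(cfg$cbf_ratio <= 0) || any(cfg$delta_petco2 <= 0)) {
    cb_stop("cbf_ratio and delta_petco2 must be positive",
            "calbold_config_error")
  }
  if (anyDuplicated(cfg$delta_petco2)) {
    cb_stop("delta_petco2 levels must be distinct", "calbold_config_error")
  }
  if (cfg$n_reps %% 2L != 0L || cfg$n_reps < 4L) {
    cb_stop("n_reps must be an even count >= 4 (tag/control interleaving)",
            "calbold_config_error")
  }
  if (any(cfg$noise_sd < 0) || cfg$petco2_tau_s < 0 ||
      cfg$petco2_jitter_sd < 0 || cfg$physio_noise_sd < 0) {
    cb_stop("noise, settling and jitter parameters must be non-negative",
            "calbold_config_error")
  }
  if (1 + cfg$kappa_true * max(cfg$delta_petco2) <= 0) {
    cb_stop("kappa_true would drive the CMRO2 ratio non-positive at the top level",
            "calbold_config_error")
  }
  if (cfg$te2 <= cfg$te1) {
    cb_stop("te2 must exceed te1", "calbold_config_error")
  }
  structure(cfg, class = "sim_config")
}

# internal: condition labels, "baseline", "hc1", "hc2", ...
sim_conditions <- function(config) {
  c("baseline", paste0("hc", seq_along(config$delta_petco2)))
}

#' Randomized block paradigm for a simulated experiment
#'
#' Draws a seeded random ordering of `blocks_per_condition` blocks of each
#' condition (baseline plus one per hypercapnia level), back to back from
#' t = 0. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A [paradigm()] tibble.
#' @export
make_paradigm <- function(config) {
  if (!inherits(config, "sim_config")) {
    cb_stop("`config` must be a sim_config()", "calbold_config_error")
  }
  if (is.null(config$seed)) paradigm_draw(config) else
    withr::with_seed(config$seed, paradigm_draw(config))
}

# internal: validate the block plan and draw one randomized ordering
# (consumes RNG; callers handle seeding)
paradigm_draw <- function(config) {
  conds <- rep(sim_conditions(config), each = config$blocks_per_condition)
  total <- length(conds) * config$block_duration_s
  scan_dur <- config$n_reps * config$tr
  if (total > scan_dur + config$tr) {
    cb_stop(sprintf(
      "block plan (%g s) exceeds the scan duration (%g s)", total, scan_dur),
      "calbold_config_error")
  }
  order <- sample(conds)
  paradigm(
    tibble::tibble(
      condition = order,
      onset_s = (seq_along(order) - 1) * config$block_duration_s,
      duration_s = config$block_duration_s),
    steady_state_offset_s = config$steady_state_offset_s)
}

# internal: per-volume condition index (0 = baseline, k = level k); volumes
# after the last block (the scan can outrun the plan by < 1 TR) are baseline
condition_at <- function(time_s, paradigm, conds) {
  idx <- findInterval(time_s, paradigm$onset_s)
  cond <- rep("baseline", length(time_s))
  inside <- idx >= 1 &
    time_s < paradigm$onset_s[pmax(idx, 1)] + paradigm$duration_s[pmax(idx, 1)]
  cond[inside] <- paradigm$condition[idx[inside]]
  match(cond, conds) - 1L
}

# internal: settled end-tidal dose (mmHg above normocapnia) at arbitrary
# times: exact piecewise-exponential solution of dP/dt = (target - P)/tau
# with the block-wise target dose, starting settled at 0 before the scan.
# tau = 0 reproduces the programmed steps exactly. Times beyond the block
# plan relax toward 0.
settled_dose <- function(time_s, paradigm, conds, dose_by_cond, tau) {
  k <- nrow(paradigm)
  tgt <- dose_by_cond[match(paradigm$condition, conds)]
  onset <- c(paradigm$onset_s, paradigm$onset_s[k] + paradigm$duration_s[k])
  tgt <- c(tgt, 0)                       # post-plan: relax to baseline
  p0 <- numeric(k + 1)
  if (tau > 0) {
    for (i in seq_len(k)) {
      p0[i + 1] <- tgt[i] + (p0[i] - tgt[i]) *
        exp(-(onset[i + 1] - onset[i]) / tau)
    }
  } else {
    p0 <- c(0, tgt[-(k + 1)])
  }
  blk <- pmax(findInterval(time_s, onset), 1L)
  if (tau > 0) {
    tgt[blk] + (p0[blk] - tgt[blk]) * exp(-(time_s - onset[blk]) / tau)
  } else {
    tgt[blk]
  }
}

#' Simulate a dual-echo ASL graded-hypercapnia experiment
#'
#' Generative inverse of the analysis chain. All signals are driven by the
#' instantaneous end-tidal dose d(t): the programmed block-wise dose passed
#' through a first-order settling filter (time constant `petco2_tau_s`; with
#' it at 0, d(t) is the programmed step train exactly). Per volume: CBF
#' factor `f(t)` from the piecewise-linear dose-response curve through the
#' programmed (dose, cbf_ratio) points; BOLD fraction
#' `b(t) = graded_bold(m_true, kappa_true, f(t), d(t))`; R2* is
#' lowered so that the echo-2 fractional signal change equals `b(t)`
#' exactly, `R2*(t) = baseline_r2star - log(1 + b(t)) / te2`; the static
#' signal is `S0(t) = baseline_signal + drift_slope * t`. The BOLD-weighted
#' signal is `S(TE) = S0(t) exp(-TE R2*(t))` and the perfusion difference
#' is `D(TE) = perfusion_fraction * baseline_signal * f(t) * exp(-TE R2*)`
#' (baseline R2*, and echo 1 only, when `te1_bold = FALSE`). Control and
#' tag volumes alternate and are recorded as `S + D/2` and `S - D/2`, so
#' surround subtraction returns D and surround averaging returns S exactly;
#' white Gaussian noise is then added per channel. The end-tidal trace
#' follows the programmed levels through a first-order settling filter plus
#' breath-wise jitter.
#'
#' @param config A [sim_config()].
#' @return A list of class `calbold_sim`: `series` (dual-echo table),
#'   `endtidal` (breath table), `paradigm`, and `truth` (ground-truth
#'   record incl. per-level BOLD fractions).
#' @examples
#' s <- simulate_dualecho(sim_config(seed = 42))
#' head(s$series)
#' @export
simulate_dualecho <- function(config) {
  if (!inherits(config, "sim_config")) {
    cb_stop("`config` must be a sim_config()", "calbold_config_error")
  }
  run <- function() {
    prd <- paradigm_draw(config)
    conds <- sim_conditions(config)
    t <- (seq_len(config$n_reps) - 1) * config$tr
    dose <- settled_dose(t, prd, conds, c(0, config$delta_petco2),
                         config$petco2_tau_s)
    # instantaneous CBF from the dose-response curve through the programmed
    # (dose, ratio) points; BOLD from the graded model at the same dose, so
    # gas settling moves signal and measured end-tidal level together
    ord <- order(c(0, config$delta_petco2))
    f <- interp_linear(c(0, config$delta_petco2)[ord],
                       c(1, config$cbf_ratio)[ord], dose)
    b <- graded_bold(config$m_true, config$kappa_true, f, dose,
                     config$pairing)
    r2s <- config$baseline_r2star - log1p(b) / config$te2
    s0 <- config$baseline_signal + config$drift_slope * t
    if (config$physio_noise_sd > 0) {
      # slow signal-proportional fluctuations: three random-phase sinusoids
      freqs <- runif(3, 0.005, 0.05)
      phases <- runif(3, 0, 2 * pi)
      lf <- rowSums(sapply(seq_len(3), function(i) {
        sin(2 * pi * freqs[i] * t + phases[i])
      })) / sqrt(3 / 2)  # unit-SD combination
      s0 <- s0 * (1 + config$physio_noise_sd * lf)
    }
    p_amp <- config$perfusion_fraction * config$baseline_signal * f

    sig <- function(te, with_bold_r2s) {
      S <- s0 * exp(-te * r2s)
      D <- p_amp * exp(-te * if (with_bold_r2s) r2s else config$baseline_r2star)
      list(S = S, D = D)
    }
    e1 <- sig(config$te1, config$te1_bold)
    e2 <- sig(config$te2, TRUE)
    if (!config$te1_bold) e2$D <- 0 * e2$D  # idealized: difference in echo 1 only

    label <- rep(c("tag", "control"), length.out = config$n_reps)
    half <- ifelse(label == "control", 0.5, -0.5)
    series <- tibble::tibble(
      time_s = t, label = label,
      echo1 = e1$S + half * e1$D + rnorm(config$n_reps, 0, config$noise_sd[1]),
      echo2 = e2$S + half * e2$D + rnorm(config$n_reps, 0, config$noise_sd[2]))

    # breath-wise end-tidal trace: the same settled dose, plus jitter
    bt <- seq(0, config$n_reps * config$tr, by = config$breath_interval_s)
    endtidal <- tibble::tibble(
      time_s = bt,
      petco2_mmhg = config$baseline_petco2 +
        settled_dose(bt, prd, conds, c(0, config$delta_petco2),
                     config$petco2_tau_s) +
        rnorm(length(bt), 0, config$petco2_jitter_sd))

    truth <- list(
      m = config$m_true, kappa = config$kappa_true,
      cbf_ratio = config$cbf_ratio,
      delta_petco2 = config$delta_petco2,
      bold_frac = graded_bold(config$m_true, config$kappa_true,
                              config$cbf_ratio, config$delta_petco2,
                              config$pairing),
      conditions = setdiff(conds, "baseline"))
    structure(list(series = series, endtidal = endtidal, paradigm = prd,
                   truth = truth, config = config),
              class = "calbold_sim")
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

#' @export
print.calbold_sim <- function(x, ...) {
  cat(sprintf(
    "<calbold_sim: %d volumes, %d blocks, truth M = %.3g%%, kappa = %.3g%%/mmHg>\n",
    nrow(x$series), nrow(x$paradigm), 100 * x$truth$m, 100 * x$truth$kappa))
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Repeats simulate -> preprocess -> fit `n_sims` times with per-run seeds
#' derived from `seed`, fitting both the two-parameter graded model and the
#' one-parameter iso-metabolic model, and summarises recovery of (M, kappa).
#'
#' @param config A [sim_config()]; its `seed` field is ignored in favour of
#'   per-run seeds `seed + 1 ... seed + n_sims`.
#' @param n_sims Number of simulated experiments.
#' @param seed Base seed for the per-run seeds.
#' @param pairing Pairing used by the estimator (defaults to the generative
#'   pairing, i.e. a well-specified estimator).
#' @param bounds [fit_bounds()] passed to the fitters.
#' @param multi_start Passed to [fit_graded()].
#' @return A list of class `calbold_recovery`: `runs` (per-simulation
#'   tibble: estimates, errors, boundary flags) and `summary` (per
#'   parameter: bias, SD, RMSE computed over the runs whose two-parameter
#'   fit stayed interior -- boundary-stuck fits are flagged failures, not
#'   estimates -- plus the boundary-hit rate over all runs).
#' @examples
#' r <- recovery_experiment(sim_config(), n_sims = 3, seed = 7)
#' r$summary
#' @export
recovery_experiment <- function(config, n_sims, seed = 1L,
                                pairing = NULL, bounds = fit_bounds(),
                                multi_start = FALSE) {
  if (!inherits(config, "sim_config")) {
    cb_stop("`config` must be a sim_config()", "calbold_config_error")
  }
  if (n_sims < 1L) cb_stop("n_sims must be >= 1", "calbold_config_error")
  pairing <- ab_pairing(pairing %||% config$pairing)
  runs <- purrr::map_dfr(seq_len(n_sims), function(i) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    sim <- simulate_dualecho(cfg)
    lv <- hypercapnia_levels(sim$series, sim$endtidal, sim$paradigm)
    two <- fit_graded(lv, pairing, bounds, multi_start = multi_start)
    one <- fit_isometabolic(lv, pairing, bounds)
    m_err <- two$m - sim$truth$m
    kappa_err <- two$kappa - sim$truth$kappa
    tibble::tibble(
      sim = i, seed = cfg$seed,
      m_hat = two$m, kappa_hat = two$kappa, m_iso = one$m,
      m_err = m_err, kappa_err = kappa_err,
      hit_boundary_two = any(two$hit_boundary),
      hit_boundary_iso = any(one$hit_boundary),
      residual_norm = two$residual_norm)
  })
  # bias/SD/RMSE over interior runs only: a boundary-stuck fit is a flagged
  # failure (excluded from group statistics by convention), not an estimate
  ok <- !runs$hit_boundary_two
  if (!any(ok)) ok <- rep(TRUE, nrow(runs))
  summary <- tibble::tibble(
    parameter = c("m", "kappa"),
    truth = c(config$m_true, config$kappa_true),
    bias = c(mean(runs$m_err[ok]), mean(runs$kappa_err[ok])),
    sd = c(sd(runs$m_err[ok]), sd(runs$kappa_err[ok])),
    rmse = c(sqrt(mean(runs$m_err[ok]^2)), sqrt(mean(runs$kappa_err[ok]^2))),
    n_interior = sum(ok),
    boundary_rate = rep(mean(runs$hit_boundary_two), 2))
  structure(list(runs = runs, summary = summary,
                 config = config, n_sims = n_sims, seed = seed),
            class = "calbold_recovery")
}

#' @export
print.calbold_recovery <- function(x, ...) {
  cat(sprintf("<calbold_recovery: %d simulations>\n", x$n_sims))
  print(x$summary)
  invisible(x)
}
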