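# ---- dual-echo tag/control series ------------------------------------------

# internal: validate a dual-echo series table
validate_dualecho <- function(series) {
  if (!is.data.frame(series)) {
    cb_stop("`series` must be a data frame (columns time_s, label, echo1, echo2)",
            "calbold_input_error")
  }
  need <- c("time_s", "label", "echo1", "echo2")
  missing <- setdiff(need, names(series))
  if (length(missing)) {
    cb_stop(sprintf("series is missing column(s): %s",
                    paste(missing, collapse = ", ")), "calbold_input_error")
  }
  if (!all(series$label %in% c("tag", "control"))) {
    cb_stop("label must be \"tag\" or \"control\"", "calbold_input_error")
  }
  if (is.unsorted(series$time_s, strictly = TRUE)) {
    cb_stop("time_s must be strictly increasing", "calbold_input_error")
  }
  lab <- series$label
  if (length(lab) >= 2 && any(lab[-1] == lab[-length(lab)])) {
    cb_stop("tag/control labels must strictly alternate", "calbold_input_error")
  }
  for (lv in c("tag", "control")) {
    if (sum(lab == lv) < 2L) {
      cb_stop(sprintf("need at least 2 \"%s\" volumes, got %d",
                      lv, sum(lab == lv)), "calbold_input_error")
    }
  }
  tibble::as_tibble(series)
}

# internal: linear interpolation with linear extrapolation at both ends.
# keeps purely linear inputs exactly linear, so surround subtraction and
# averaging stay exactly linear operators.
interp_linear <- function(x, y, xout) {
  n <- length(x)
  out <- approx(x, y, xout = xout, method = "linear", rule = 1, ties = "ordered")$y
  lo <- xout < x[1]
  hi <- xout > x[n]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + s * (xout[lo] - x[1])
  }
  if (any(hi)) {
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  out
}

# internal: split tag/control streams of one echo and put both on the full
# TR grid, then combine with `op`
surround_combine <- function(series, echo_col, op) {
  tagv <- series$label == "tag"
  t_all <- series$time_s
  tag_i <- interp_linear(t_all[tagv], series[[echo_col]][tagv], t_all)
  con_i <- interp_linear(t_all[!tagv], series[[echo_col]][!tagv], t_all)
  op(con_i, tag_i)
}

#' Perfusion-weighted time series by surround subtraction
#'
#' Separates the interleaved tag and control volumes of the first echo,
#' linearly interpolates each stream onto the full TR grid, and subtracts
#' (control - tag) at every time point. Under QUIPSS II conditions the
#' resulting difference signal is proportional to CBF.
#'
#' @param series Data frame with columns `time_s`, `label` (`"tag"` /
#'   `"control"`, strictly alternating), `echo1`, `echo2`.
#' @return A tibble `time_s`, `value` with the same length as the input.
#' @examples
#' s <- sim_config(noise_sd = c(0, 0)) |> simulate_dualecho()
#' perfusion_series(s$series)
#' @export
perfusion_series <- function(series) {
  series <- validate_dualecho(series)
  tibble::tibble(time_s = series$time_s,
                 value = surround_combine(series, "echo1", `-`))
}

#' BOLD-weighted time series by surround averaging
#'
#' Same interpolation scheme as [perfusion_series()] but on the second echo
#' and combining by the mean, (control + tag) / 2, which suppresses the
#' perfusion component and retains the BOLD-weighted signal.
#'
#' @inheritParams perfusion_series
#' @return A tibble `time_s`, `value`.
#' @export
bold_series <- function(series) {
  series <- validate_dualecho(series)
  tibble::tibble(time_s = series$time_s,
                 value = surround_combine(series, "echo2",
                                          function(c, t) (c + t) / 2))
}

#' R2* time series from the two echoes
#'
#' Per time point, the mono-exponential two-point estimate
#' `R2* = log(S(TE1) / S(TE2)) / (TE2 - TE1)` is computed separately within
#' the tag and control streams; the two streams are then interpolated onto
#' the full TR grid and averaged (surround averaging).
#'
#' @inheritParams perfusion_series
#' @param te1,te2 Echo times in seconds, `te2 > te1 > 0`.
#' @return A tibble `time_s`, `value` (R2* in 1/s).
#' @export
r2star_series <- function(series, te1, te2) {
  series <- validate_dualecho(series)
  check_finite(te1, "te1")
  check_finite(te2, "te2")
  if (!(te2 > te1 && te1 > 0)) {
    cb_stop("echo times must satisfy te2 > te1 > 0", "calbold_input_error")
  }
  bad <- which(series$echo1 <= 0 | series$echo2 <= 0)
  if (length(bad)) {
    cb_stop(sprintf("non-positive signal at row(s) %s: cannot take log for R2*",
                    paste(utils::head(bad, 5), collapse = ", ")),
            "calbold_domain_error")
  }
  r2s <- log(series$echo1 / series$echo2) / (te2 - te1)
  tmp <- tibble::tibble(time_s = series$time_s, label = series$label,
                        echo1 = r2s, echo2 = r2s)
  tibble::tibble(time_s = series$time_s,
                 value = surround_combine(tmp, "echo1",
                                          function(c, t) (c + t) / 2))
}

# ---- paradigm and window helpers --------------------------------------------

#' Define a block paradigm
#'
#' @param blocks Data frame with columns `condition` (character; the
#'   baseline condition must be named `"baseline"`), `onset_s`, `duration_s`.
#'   Blocks must be ordered and non-overlapping.
#' @param steady_state_offset_s Seconds into each block at which the gas
#'   level is considered settled; block statistics use only
#'   `[onset + offset, onset + duration]`. Default 60 s of a 120-s block.
#' @return A `calbold_paradigm` tibble (the blocks, with the offset stored
#'   as an attribute).
#' @export
paradigm <- function(blocks, steady_state_offset_s = 60) {
  if (!is.data.frame(blocks)) {
    cb_stop("`blocks` must be a data frame", "calbold_input_error")
  }
  need <- c("condition", "onset_s", "duration_s")
  missing <- setdiff(need, names(blocks))
  if (length(missing)) {
    cb_stop(sprintf("paradigm is missing column(s): %s",
                    paste(missing, collapse = ", ")), "calbold_input_error")
  }
  check_finite(blocks$onset_s, "onset_s")
  check_finite(blocks$duration_s, "duration_s")
  if (any(blocks$duration_s <= 0)) {
    cb_stop("block durations must be positive", "calbold_input_error")
  }
  if (is.unsorted(blocks$onset_s, strictly = TRUE)) {
    cb_stop("blocks must be ordered by onset", "calbold_input_error")
  }
  ends <- blocks$onset_s + blocks$duration_s
  if (any(ends[-length(ends)] > blocks$onset_s[-1] + 1e-9)) {
    cb_stop("blocks must not overlap", "calbold_input_error")
  }
  check_finite(steady_state_offset_s, "steady_state_offset_s")
  if (steady_state_offset_s < 0 ||
      steady_state_offset_s >= min(blocks$duration_s)) {
    cb_stop("steady_state_offset_s must be >= 0 and shorter than every block",
            "calbold_input_error")
  }
  out <- tibble::as_tibble(blocks[, need])
  attr(out, "steady_state_offset_s") <- steady_state_offset_s
  class(out) <- c("calbold_paradigm", class(out))
  out
}

# internal: steady-state windows (start, end) for one condition
steady_windows <- function(paradigm, condition) {
  off <- attr(paradigm, "steady_state_offset_s") %||% 60
  b <- paradigm[paradigm$condition == condition, , drop = FALSE]
  if (nrow(b) == 0L) {
    cb_stop(sprintf("condition \"%s\" not present in paradigm", condition),
            "calbold_input_error")
  }
  tibble::tibble(start = b$onset_s + off, end = b$onset_s + b$duration_s)
}

# internal: logical index of times inside any window. Windows are half-open
# [start, end): a sample landing exactly on a block boundary belongs to the
# next block. `end_guard` additionally trims the window end; series built by
# surround interpolation use one sampling step there, because the
# interpolated partner of the final sample would straddle the boundary.
in_windows <- function(time_s, windows, end_guard = 0) {
  hit <- rep(FALSE, length(time_s))
  for (i in seq_len(nrow(windows))) {
    hit <- hit | (time_s >= windows$start[i] &
                    time_s < windows$end[i] - end_guard)
  }
  hit
}

# internal: end guard for an interpolated series = one median sampling step
series_end_guard <- function(time_s) {
  if (length(time_s) < 2L) return(0)
  stats::median(diff(time_s))
}

#' Remove a linear drift estimated from baseline periods
#'
#' Fits a straight line by ordinary least squares to the samples falling in
#' the baseline blocks' steady-state windows only, and subtracts it from the
#' entire series. The detrended baseline steady-state mean is therefore 0;
#' the removed baseline level (mean of the fitted line over the baseline
#' samples) is stored in the `"baseline_level"` attribute so that percent
#' changes can still be referenced to it.
#'
#' @param series A tibble `time_s`, `value` (e.g. from [bold_series()]).
#' @param paradigm A [paradigm()].
#' @return The series with `value` detrended and attribute
#'   `baseline_level`.
#' @export
detrend_baseline <- function(series, paradigm) {
  if (!is.data.frame(series) || !all(c("time_s", "value") %in% names(series))) {
    cb_stop("`series` must have columns time_s, value", "calbold_input_error")
  }
  wins <- steady_windows(paradigm, "baseline")
  if (nrow(wins) < 2L) {
    cb_stop("need at least 2 baseline blocks for detrending",
            "calbold_input_error")
  }
  base_i <- in_windows(series$time_s, wins,
                       end_guard = series_end_guard(series$time_s))
  if (length(unique(series$time_s[base_i])) < 2L) {
    cb_stop("need at least 2 distinct baseline time points",
            "calbold_input_error")
  }
  fit <- lm(value ~ time_s, data = series[base_i, ])
  trend <- predict(fit, newdata = series)
  out <- tibble::tibble(time_s = series$time_s,
                        value = series$value - trend)
  attr(out, "baseline_level") <- mean(trend[base_i])
  out
}

#' Fractional block response of a series relative to baseline
#'
#' Means the series over the steady-state windows of all blocks of the
#' requested condition and expresses it as a fractional change from the
#' baseline steady-state mean. If the series carries a `baseline_level`
#' attribute (i.e. it came from [detrend_baseline()]), that stored level is
#' the reference and the detrended values are treated as deviations from
#' it; otherwise the baseline-window mean of the raw values is used.
#'
#' For a BOLD-weighted series the result is the fractional BOLD change; for
#' the perfusion-weighted difference signal (proportional to CBF) the
#' result is the fractional CBF change, i.e. `cbf_ratio - 1`.
#'
#' @inheritParams detrend_baseline
#' @param condition Condition name to evaluate (e.g. `"hc1"`).
#' @return Fractional change (dimensionless scalar).
#' @export
block_response <- function(series, paradigm, condition) {
  if (!is.data.frame(series) || !all(c("time_s", "value") %in% names(series))) {
    cb_stop("`series` must have columns time_s, value", "calbold_input_error")
  }
  guard <- series_end_guard(series$time_s)
  cond_i <- in_windows(series$time_s, steady_windows(paradigm, condition),
                       end_guard = guard)
  base_i <- in_windows(series$time_s, steady_windows(paradigm, "baseline"),
                       end_guard = guard)
  if (!any(cond_i)) {
    cb_stop(sprintf("no samples fall in the steady-state windows of \"%s\"",
                    condition), "calbold_input_error")
  }
  if (!any(base_i)) {
    cb_stop("no samples fall in the baseline steady-state windows",
            "calbold_input_error")
  }
  level <- attr(series, "baseline_level")
  if (is.null(level)) {
    base_mean <- mean(series$value[base_i])
    cond_mean <- mean(series$value[cond_i])
  } else {
    base_mean <- level + mean(series$value[base_i])
    cond_mean <- level + mean(series$value[cond_i])
  }
  if (base_mean <= 0) {
    cb_stop(sprintf("baseline mean (%.4g) must be positive for a ratio",
                    base_mean), "calbold_domain_error")
  }
  cond_mean / base_mean - 1
}

#' End-tidal CO2 increase of a condition over baseline
#'
#' Means the breath-wise end-tidal CO2 values inside the condition's
#' steady-state windows and subtracts the same statistic over the baseline
#' windows.
#'
#' @param trace A tibble `time_s`, `petco2_mmhg` (one row per breath,
#'   strictly increasing times).
#' @param paradigm A [paradigm()].
#' @param condition Condition name.
#' @param min_breaths Windows with fewer breaths than this trigger a
#'   warning (an empty window is an error).
#' @return Delta PETCO2 in mmHg.
#' @export
endtidal_level <- function(trace, paradigm, condition, min_breaths = 3L) {
  if (!is.data.frame(trace) ||
      !all(c("time_s", "petco2_mmhg") %in% names(trace))) {
    cb_stop("`trace` must have columns time_s, petco2_mmhg",
            "calbold_input_error")
  }
  if (is.unsorted(trace$time_s, strictly = TRUE)) {
    cb_stop("breath times must be strictly increasing", "calbold_input_error")
  }
  window_mean <- function(wins, what) {
    counts <- vapply(seq_len(nrow(wins)), function(i) {
      sum(trace$time_s >= wins$start[i] & trace$time_s < wins$end[i])
    }, integer(1))
    if (any(counts == 0L)) {
      cb_stop(sprintf("empty steady-state window for %s (block %d)",
                      what, which(counts == 0L)[1]), "calbold_input_error")
    }
    if (any(counts < min_breaths)) {
      warning(sprintf("fewer than %d breaths in a %s steady-state window",
                      min_breaths, what), call. = FALSE)
    }
    mean(trace$petco2_mmhg[in_windows(trace$time_s, wins)])
  }
  window_mean(steady_windows(paradigm, condition), condition) -
    window_mean(steady_windows(paradigm, "baseline"), "baseline")
}

#' ROI-averaged time series from a 4D volume
#'
#' Unweighted mean over the mask voxels at each time point. Accepts plain
#' 4D/3D arrays or NIfTI file paths / images (read with the RNifti package
#' when available). The mask must already be on the functional grid; no
#' resampling is performed.
#'
#' @param volumes 4D numeric array (x, y, z, t), or a NIfTI path/image.
#' @param mask 3D array (nonzero = included), or a NIfTI path/image, with
#'   the same spatial dimensions as `volumes`.
#' @param tr Optional repetition time (s); when given, a `time_s` column
#'   `(0, tr, 2 tr, ...)` is added.
#' @return A tibble `volume` (1-based index), `value`, and optionally
#'   `time_s`.
#' @export
roi_average <- function(volumes, mask, tr = NULL) {
  as_img <- function(x, what) {
    if (is.character(x)) {
      if (!requireNamespace("RNifti", quietly = TRUE)) {
        cb_stop("reading NIfTI files requires the RNifti package",
                "calbold_input_error")
      }
      x <- RNifti::readNifti(x)
    }
    arr <- as.array(x)
    if (!is.numeric(arr)) {
      cb_stop(sprintf("%s must be numeric", what), "calbold_input_error")
    }
    arr
  }
  vol <- as_img(volumes, "volumes")
  msk <- as_img(mask, "mask")
  if (length(dim(vol)) == 3L) dim(vol) <- c(dim(vol), 1L)
  if (length(dim(vol)) != 4L || length(dim(msk)) != 3L) {
    cb_stop("volumes must be 4D and mask 3D", "calbold_input_error")
  }
  if (!identical(dim(vol)[1:3], dim(msk))) {
    cb_stop(sprintf("grid mismatch: volumes %s vs mask %s",
                    paste(dim(vol)[1:3], collapse = "x"),
                    paste(dim(msk), collapse = "x")), "calbold_input_error")
  }
  keep <- which(msk != 0)
  if (!length(keep)) cb_stop("mask is empty", "calbold_input_error")
  nt <- dim(vol)[4]
  flat <- matrix(vol, ncol = nt)
  out <- tibble::tibble(volume = seq_len(nt),
                        value = colMeans(flat[keep, , drop = FALSE]))
  if (!is.null(tr)) out$time_s <- (out$volume - 1) * tr
  out
}

#' Extract per-level fit inputs from a raw dual-echo experiment
#'
#' The full preprocessing chain: BOLD series by surround averaging of echo
#' 2 and perfusion series by surround subtraction of echo 1, both linearly
#' detrended against the baseline steady-state windows, then summarised per
#' hypercapnia condition as fractional BOLD change, CBF ratio, and measured
#' end-tidal CO2 increase. The output feeds [fit_graded()] /
#' [fit_isometabolic()] directly.
#'
#' @inheritParams perfusion_series
#' @param trace Breath-wise end-tidal CO2 table (see [endtidal_level()]);
#'   `NULL` to omit the `delta_petco2` column.
#' @param paradigm A [paradigm()].
#' @param conditions Conditions to summarise; default all non-baseline
#'   conditions in paradigm order.
#' @return A tibble with one row per condition: `condition`,
#'   `delta_petco2`, `bold_frac`, `cbf_ratio`.
#' @examples
#' s <- simulate_dualecho(sim_config(seed = 1))
#' hypercapnia_levels(s$series, s$endtidal, s$paradigm)
#' @export
hypercapnia_levels <- function(series, trace, paradigm, conditions = NULL) {
  conditions <- conditions %||%
    unique(paradigm$condition[paradigm$condition != "baseline"])
  if (!length(conditions)) {
    cb_stop("paradigm has no non-baseline conditions", "calbold_input_error")
  }
  bold <- detrend_baseline(bold_series(series), paradigm)
  perf <- detrend_baseline(perfusion_series(series), paradigm)
  purrr::map_dfr(conditions, function(cc) {
    tibble::tibble(
      condition = cc,
      delta_petco2 = if (is.null(trace)) NA_real_ else
        endtidal_level(trace, paradigm, cc),
      bold_frac = block_response(bold, paradigm, cc),
      cbf_ratio = 1 + block_response(perf, paradigm, cc))
  })
}

#' Average per-session level tables
#'
#' Responses are computed per session first and then averaged across
#' sessions, so a subject's fit input is the session-mean response per
#' condition. Bind the per-session outputs of [hypercapnia_levels()]
#' together (optionally with `subject` / `session` columns) and pass them
#' here.
#'
#' @param levels Row-bound per-session level tables: columns `condition`,
#'   `delta_petco2`, `bold_frac`, `cbf_ratio`, optionally `subject`.
#' @return One row per (subject,) condition with session-mean values.
#' @export
average_session_levels <- function(levels) {
  need <- c("condition", "delta_petco2", "bold_frac", "cbf_ratio")
  missing <- setdiff(need, names(levels))
  if (length(missing)) {
    cb_stop(sprintf("`levels` is missing column(s): %s",
                    paste(missing, collapse = ", ")), "calbold_input_error")
  }
  keys <- intersect(c("subject", "condition"), names(levels))
  levels |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      delta_petco2 = mean(.data$delta_petco2),
      bold_frac = mean(.data$bold_frac),
      cbf_ratio = mean(.data$cbf_ratio),
      n_sessions = dplyr::n(),
      .groups = "drop")
}
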