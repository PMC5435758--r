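# ggplot2 views of the main result types

#' Plot a calibration fit against its level data
#'
#' Measured fractional BOLD changes per hypercapnia level (points) with the
#' fitted graded model evaluated along the dose axis (line; CBF ratios are
#' linearly interpolated between the measured levels).
#'
#' @param object A `calbold_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calbold_fit <- function(object, ...) {
  lv <- object$levels
  dP_grid <- seq(min(lv$delta_petco2), max(lv$delta_petco2),
                 length.out = 50)
  f_grid <- interp_linear(lv$delta_petco2, lv$cbf_ratio, dP_grid)
  curve <- tibble::tibble(
    delta_petco2 = dP_grid,
    bold_percent = 100 * graded_bold(object$m, object$kappa, f_grid,
                                     dP_grid, object$pairing))
  pts <- tibble::tibble(delta_petco2 = lv$delta_petco2,
                        bold_percent = 100 * lv$bold_frac)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$delta_petco2,
                                    y = .data$bold_percent)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = expression(Delta * P[ET] * CO[2] ~ "(mmHg)"),
      y = "BOLD change (%)",
      title = sprintf("%s fit: M = %.2f%%%s", object$model, 100 * object$m,
                      if (object$model == "graded")
                        sprintf(", kappa = %.2f %%/mmHg", 100 * object$kappa)
                      else "")) +
    ggplot2::theme_minimal()
}

#' Plot a simulated experiment
#'
#' Echo-2 BOLD-weighted and echo-1 perfusion-weighted series with block
#' shading by condition.
#'
#' @param object A `calbold_sim` from [simulate_dualecho()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calbold_sim <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(bold_series(object$series), channel = "BOLD (echo 2 mean)"),
    dplyr::mutate(perfusion_series(object$series),
                  channel = "perfusion (echo 1 difference)"))
  blocks <- dplyr::mutate(tibble::as_tibble(object$paradigm),
                          end_s = .data$onset_s + .data$duration_s)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_rect(
      data = blocks[blocks$condition != "baseline", ],
      ggplot2::aes(xmin = .data$onset_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf, fill = .data$condition),
      alpha = 0.15, inherit.aes = FALSE) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "signal (a.u.)", fill = "condition") +
    ggplot2::theme_minimal()
}

#' Dot plot of per-subject kappa estimates
#'
#' Per-subject dose-wise CMRO2 slopes with the group mean, the view used to
#' judge whether basal CMRO2 falls with hypercapnia level.
#'
#' @param data Data frame with columns `kappa` (fraction/mmHg) and
#'   optionally `group` (e.g. ROI or pairing) and `hit_boundary`.
#' @return A ggplot object.
#' @export
plot_kappa_dots <- function(data) {
  if (!"group" %in% names(data)) data$group <- "all"
  if (!"hit_boundary" %in% names(data)) data$hit_boundary <- FALSE
  data$kappa_pct <- 100 * data$kappa
  means <- data |>
    dplyr::filter(!.data$hit_boundary) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(kappa_pct = mean(.data$kappa_pct), .groups = "drop")
  ggplot2::ggplot(data, ggplot2::aes(x = .data$group, y = .data$kappa_pct)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_jitter(ggplot2::aes(shape = .data$hit_boundary),
                         width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::geom_point(data = means, shape = 18, size = 4,
                        colour = "firebrick") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4),
                                name = "boundary hit") +
    ggplot2::labs(x = NULL, y = "kappa (%/mmHg)") +
    ggplot2::theme_minimal()
}

#' Compare two-parameter and iso-metabolic M estimates
#'
#' Mean +/- SEM of M under the graded (two-parameter) and iso-metabolic
#' (one-parameter) fits, over subjects interior in both.
#'
#' @param data Data frame with columns `m_two`, `m_one`, `included` (as
#'   from [compare_fits()]) and optionally `group`.
#' @return A ggplot object.
#' @export
plot_m_comparison <- function(data) {
  if (!"group" %in% names(data)) data$group <- "all"
  long <- data |>
    dplyr::filter(.data$included) |>
    tidyr::pivot_longer(c("m_two", "m_one"), names_to = "model",
                        values_to = "m") |>
    dplyr::mutate(model = dplyr::recode(.data$model,
                                        m_two = "two-parameter",
                                        m_one = "iso-metabolic")) |>
    dplyr::group_by(.data$group, .data$model) |>
    dplyr::summarise(mean_pct = 100 * mean(.data$m),
                     sem_pct = 100 * sd(.data$m) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$mean_pct,
                                     fill = .data$model)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_pct - .data$sem_pct,
                   ymax = .data$mean_pct + .data$sem_pct),
      position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::labs(x = NULL, y = "M (%)", fill = NULL) +
    ggplot2::theme_minimal()
}
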