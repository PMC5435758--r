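# ---- plain-text readers/writers --------------------------------------------
# All percent <-> fraction conversions live in this file: on-disk tables use
# the conventional reporting units (%BOLD, %CBF, M in %, kappa in %/mmHg);
# in-memory tables use fractions.

# internal: read a CSV and check its header, naming the first missing column
read_checked_csv <- function(path, need, what) {
  if (!file.exists(path)) {
    cb_stop(sprintf("%s file not found: %s", what, path), "calbold_io_error")
  }
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) {
                   cb_stop(sprintf("cannot parse %s file %s: %s",
                                   what, path, conditionMessage(e)),
                           "calbold_io_error")
                 })
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    cb_stop(sprintf("%s file %s is missing column \"%s\"",
                    what, path, missing[1]), "calbold_io_error")
  }
  tibble::as_tibble(df)
}

#' Read / write a dual-echo tag-control time-series CSV
#'
#' Columns: `time_s`, `label` (`tag`/`control`), `echo1`, `echo2`; header
#' row required.
#'
#' @param path File path.
#' @return A validated dual-echo tibble.
#' @export
read_dualecho_csv <- function(path) {
  validate_dualecho(read_checked_csv(
    path, c("time_s", "label", "echo1", "echo2"), "dual-echo series"))
}

#' @rdname read_dualecho_csv
#' @param series A dual-echo tibble.
#' @export
write_dualecho_csv <- function(series, path) {
  write.csv(validate_dualecho(series), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a breath-wise end-tidal CO2 CSV
#'
#' Columns: `time_s`, `petco2_mmhg`.
#'
#' @param path File path.
#' @return A tibble `time_s`, `petco2_mmhg`.
#' @export
read_endtidal_csv <- function(path) {
  df <- read_checked_csv(path, c("time_s", "petco2_mmhg"), "end-tidal")
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    cb_stop("end-tidal breath times must be strictly increasing",
            "calbold_io_error")
  }
  df
}

#' @rdname read_endtidal_csv
#' @param trace An end-tidal tibble.
#' @export
write_endtidal_csv <- function(trace, path) {
  write.csv(trace[, c("time_s", "petco2_mmhg")], path, row.names = FALSE)
  invisible(path)
}

#' Read / write a paradigm JSON
#'
#' Layout: `{"steady_state_offset_s": 60, "blocks": [{"condition": ...,
#' "onset_s": ..., "duration_s": ...}, ...]}`.
#'
#' @param path File path.
#' @return A [paradigm()].
#' @export
read_paradigm_json <- function(path) {
  if (!file.exists(path)) {
    cb_stop(sprintf("paradigm file not found: %s", path), "calbold_io_error")
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$blocks)) {
    cb_stop(sprintf("paradigm file %s has no \"blocks\" entry", path),
            "calbold_io_error")
  }
  paradigm(tibble::as_tibble(x$blocks),
           steady_state_offset_s = x$steady_state_offset_s %||% 60)
}

#' @rdname read_paradigm_json
#' @param paradigm A [paradigm()].
#' @export
write_paradigm_json <- function(paradigm, path) {
  jsonlite::write_json(
    list(steady_state_offset_s = attr(paradigm, "steady_state_offset_s") %||% 60,
         blocks = as.data.frame(paradigm)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read / write a per-subject hypercapnia level table CSV
#'
#' On disk the table uses reporting units: columns `subject`,
#' `delta_petco2_mmhg`, `bold_percent`, `cbf_percent` (percent change from
#' baseline, as conventionally tabulated). In memory the table is converted
#' to the internal units of [fit_graded()]: `bold_frac = bold_percent/100`,
#' `cbf_ratio = 1 + cbf_percent/100`.
#'
#' @param path File path.
#' @return A tibble `subject`, `delta_petco2`, `bold_frac`, `cbf_ratio`.
#' @export
read_levels_csv <- function(path) {
  df <- read_checked_csv(
    path, c("subject", "delta_petco2_mmhg", "bold_percent", "cbf_percent"),
    "levels")
  tibble::tibble(
    subject = as.character(df$subject),
    delta_petco2 = as.numeric(df$delta_petco2_mmhg),
    bold_frac = as.numeric(df$bold_percent) / 100,
    cbf_ratio = 1 + as.numeric(df$cbf_percent) / 100)
}

#' @rdname read_levels_csv
#' @param levels An in-memory level table (internal units), optionally with
#'   a `subject` column.
#' @export
write_levels_csv <- function(levels, path) {
  out <- data.frame(
    subject = if ("subject" %in% names(levels)) levels$subject else "s01",
    delta_petco2_mmhg = levels$delta_petco2,
    bold_percent = 100 * levels$bold_frac,
    cbf_percent = 100 * (levels$cbf_ratio - 1))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a calibration fit to JSON (reporting units)
#'
#' @param fit A `calbold_fit`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  if (!inherits(fit, "calbold_fit")) {
    cb_stop("`fit` must be a calbold_fit", "calbold_input_error")
  }
  jsonlite::write_json(list(
    model = fit$model,
    m_percent = 100 * fit$m,
    kappa_percent_per_mmhg = 100 * fit$kappa,
    hit_boundary = as.list(fit$hit_boundary),
    residual_norm = fit$residual_norm,
    n_levels = fit$n_levels,
    pairing = list(name = fit$pairing$name, alpha = fit$pairing$alpha,
                   beta = fit$pairing$beta),
    bounds = unclass(fit$bounds),
    converged = fit$converged
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a calibration-fit JSON back into a tibble row
#'
#' @param path Path written by [write_fit_json()].
#' @return A one-row tibble in internal units (fractions) plus metadata.
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tibble::tibble(
    model = x$model,
    m = x$m_percent / 100,
    kappa = x$kappa_percent_per_mmhg / 100,
    hit_boundary = any(unlist(x$hit_boundary)),
    residual_norm = x$residual_norm,
    n_levels = x$n_levels,
    pairing = x$pairing$name,
    alpha = x$pairing$alpha,
    beta = x$pairing$beta)
}

#' Write a group summary table CSV (reporting units)
#'
#' One row per model (two-parameter and iso-metabolic), with mean and SEM
#' of M in %, mean/SEM of kappa in %/mmHg, Wilcoxon p-values and the
#' included/total subject counts in the conventional "N = #/total" form.
#'
#' @param group A tibble as assembled by [cli_group_table()].
#' @param path Output path.
#' @export
write_group_csv <- function(group, path) {
  write.csv(as.data.frame(group), path, row.names = FALSE)
  invisible(path)
}

#' Assemble the group reporting table from per-subject fits
#'
#' Given per-subject graded and iso-metabolic fits, produces the standard
#' group table: per model the mean +/- SEM of M over subjects whose fit
#' stayed interior, the kappa summary with its Wilcoxon test against 0, and
#' the paired two- vs one-parameter M comparison on subjects interior in
#' both fits.
#'
#' @param two_fits,one_fits Lists of `calbold_fit` objects (same subjects,
#'   same order).
#' @param subjects Optional subject identifiers.
#' @return A tibble with rows `two_parameter`, `one_parameter`,
#'   `paired_difference`.
#' @export
cli_group_table <- function(two_fits, one_fits, subjects = NULL) {
  if (length(two_fits) != length(one_fits)) {
    cb_stop("two_fits and one_fits must have the same length",
            "calbold_input_error")
  }
  subjects <- subjects %||% sprintf("s%02d", seq_along(two_fits))
  per <- purrr::map_dfr(seq_along(two_fits), function(i) {
    cmp <- compare_fits(two_fits[[i]], one_fits[[i]])
    tibble::tibble(
      subject = subjects[i],
      m_two = cmp$m_two, m_one = cmp$m_one, kappa = cmp$kappa,
      hit_two = any(two_fits[[i]]$hit_boundary),
      hit_one = any(one_fits[[i]]$hit_boundary),
      included_pair = cmp$included)
  })
  n <- nrow(per)
  row_m <- function(label, m, hit) {
    keep <- m[!hit]
    tibble::tibble(
      result = label,
      m_percent_mean = 100 * mean(keep),
      m_percent_sem = if (length(keep) > 1) 100 * sd(keep) / sqrt(length(keep)) else NA_real_,
      kappa_mean = NA_real_, kappa_sem = NA_real_, wilcoxon_p = NA_real_,
      included = sprintf("N = %d/%d", length(keep), n))
  }
  gk <- group_summary(tibble::tibble(kappa = per$kappa,
                                     hit_boundary = per$hit_two),
                      mode = "kappa")
  gm <- group_summary(tibble::tibble(m_two = per$m_two, m_one = per$m_one,
                                     included = per$included_pair),
                      mode = "paired_m")
  two_row <- row_m("two_parameter", per$m_two, per$hit_two)
  two_row$kappa_mean <- 100 * gk$mean
  two_row$kappa_sem <- 100 * gk$sem
  two_row$wilcoxon_p <- gk$p_value
  two_row$included <- sprintf("N = %d/%d", gk$included_n, gk$total_n)
  one_row <- row_m("one_parameter", per$m_one, per$hit_one)
  pair_row <- tibble::tibble(
    result = "paired_difference",
    m_percent_mean = 100 * gm$mean,
    m_percent_sem = 100 * gm$sem,
    kappa_mean = NA_real_, kappa_sem = NA_real_,
    wilcoxon_p = gm$p_value,
    included = sprintf("N = %d/%d", gm$included_n, gm$total_n))
  dplyr::bind_rows(two_row, one_row, pair_row)
}

#' Write a run manifest
#'
#' Records package and R versions, the seed, and the echoed configuration,
#' sufficient to reproduce a deterministic run bit-identically.
#'
#' @param path Output path.
#' @param config Named list of configuration values to echo.
#' @param seed The seed used (or `NULL`).
#' @export
write_manifest <- function(path, config = list(), seed = NULL) {
  jsonlite::write_json(list(
    package = "calbold",
    version = as.character(utils::packageVersion("calbold")),
    r_version = R.version.string,
    seed = seed,
    config = config,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
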