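#' Alpha/beta exponent pairings for the Davis model
#'
#' The Davis model carries two power-law exponents: `alpha`, the assumed
#' CBF--CBV coupling exponent, and `beta`, relating venous deoxyhemoglobin
#' to the transverse relaxation rate. Three named conventions are supported:
#'
#' * `"empirical"`: alpha = 0.14, beta = 0.91 (empirically optimized values)
#' * `"3T"`: alpha = 0.2, beta = 1.3 (values commonly used at 3 Tesla)
#' * `"simplified"`: alpha = 0.06, beta = 1.0 (single-exponent simplified
#'   model, expressed in alpha/beta form)
#'
#' @param pairing A preset name (`"empirical"`, `"3T"`, `"simplified"`),
#'   an `ab_pairing` object (returned unchanged), or `NULL` together with
#'   explicit `alpha`/`beta`.
#' @param alpha,beta Explicit exponents for a custom pairing; both must be
#'   given when `pairing` is not a preset name. Require `0 < alpha < 1` and
#'   `0 < beta <= 2`.
#'
#' @return An object of class `ab_pairing`: a list with fields `name`,
#'   `alpha`, `beta`.
#' @examples
#' ab_pairing("empirical")
#' ab_pairing(alpha = 0.1, beta = 1.2)
#' @export
ab_pairing <- function(pairing = "empirical", alpha = NULL, beta = NULL) {
  if (inherits(pairing, "ab_pairing")) {
    return(pairing)
  }
  presets <- list(
    empirical  = c(alpha = 0.14, beta = 0.91),
    `3T`       = c(alpha = 0.20, beta = 1.30),
    simplified = c(alpha = 0.06, beta = 1.00)
  )
  if (!is.null(alpha) || !is.null(beta)) {
    if (is.null(alpha) || is.null(beta)) {
      cb_stop("give both `alpha` and `beta` for a custom pairing",
              "calbold_config_error")
    }
    out <- list(name = "custom", alpha = as.numeric(alpha),
                beta = as.numeric(beta))
  } else if (is.character(pairing) && length(pairing) == 1L) {
    if (!pairing %in% names(presets)) {
      cb_stop(sprintf(
        "unknown pairing \"%s\"; use one of %s or give alpha/beta explicitly",
        pairing, paste0('"', names(presets), '"', collapse = ", ")),
        "calbold_config_error")
    }
    p <- presets[[pairing]]
    out <- list(name = pairing, alpha = unname(p["alpha"]),
                beta = unname(p["beta"]))
  } else {
    cb_stop("`pairing` must be a preset name, an ab_pairing, or NULL with alpha/beta",
            "calbold_config_error")
  }
  check_finite(out$alpha, "alpha")
  check_finite(out$beta, "beta")
  if (out$alpha <= 0 || out$alpha >= 1) {
    cb_stop(sprintf("alpha must lie in (0, 1), got %g", out$alpha),
            "calbold_domain_error")
  }
  if (out$beta <= 0 || out$beta > 2) {
    cb_stop(sprintf("beta must lie in (0, 2], got %g", out$beta),
            "calbold_domain_error")
  }
  structure(out, class = "ab_pairing")
}

#' @export
print.ab_pairing <- function(x, ...) {
  cat(sprintf("<ab_pairing \"%s\": alpha = %g, beta = %g>\n",
              x$name, x$alpha, x$beta))
  invisible(x)
}

#' @export
format.ab_pairing <- function(x, ...) {
  sprintf("%s (alpha=%g, beta=%g)", x$name, x$alpha, x$beta)
}
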