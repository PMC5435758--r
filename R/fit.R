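#' Box bounds for the (M, kappa) fit
#'
#' Defaults reproduce the boundary conditions used for the graded-hypercapnia
#' fits: 1 % < M < 20 % and -5 < kappa < +5 %/mmHg, expressed internally as
#' fractions. Subjects whose fitted parameters reach a bound are flagged and
#' conventionally excluded from group statistics.
#'
#' @param m_low,m_high Bounds on M (fraction).
#' @param kappa_low,kappa_high Bounds on kappa (fraction/mmHg).
#' @return A `fit_bounds` object.
#' @export
fit_bounds <- function(m_low = 0.01, m_high = 0.20,
                       kappa_low = -0.05, kappa_high = 0.05) {
  check_finite(c(m_low, m_high, kappa_low, kappa_high), "bounds")
  if (m_low <= 0 || m_high <= m_low || kappa_high <= kappa_low) {
    cb_stop("bounds must satisfy 0 < m_low < m_high and kappa_low < kappa_high",
            "calbold_config_error")
  }
  structure(list(m_low = m_low, m_high = m_high,
                 kappa_low = kappa_low, kappa_high = kappa_high),
            class = "fit_bounds")
}

# internal: tolerance within which a fitted parameter counts as "at" a bound
BOUNDARY_TOL <- 1e-6

# internal: validate a levels table; returns it with canonical column order
validate_levels <- function(levels, min_levels = 2L) {
  if (!is.data.frame(levels)) {
    cb_stop("`levels` must be a data frame with columns delta_petco2, bold_frac, cbf_ratio",
            "calbold_input_error")
  }
  need <- c("delta_petco2", "bold_frac", "cbf_ratio")
  missing <- setdiff(need, names(levels))
  if (length(missing)) {
    cb_stop(sprintf("`levels` is missing column(s): %s",
                    paste(missing, collapse = ", ")),
            "calbold_input_error")
  }
  for (col in need) check_finite(levels[[col]], col)
  if (nrow(levels) < min_levels) {
    cb_stop(sprintf("need at least %d hypercapnia level(s), got %d",
                    min_levels, nrow(levels)), "calbold_input_error")
  }
  if (anyDuplicated(levels$delta_petco2)) {
    cb_stop("levels must have distinct delta_petco2 values",
            "calbold_input_error")
  }
  if (any(levels$delta_petco2 <= 0)) {
    cb_stop("delta_petco2 must be positive for hypercapnia levels",
            "calbold_input_error")
  }
  if (any(levels$cbf_ratio <= 0)) {
    cb_stop("cbf_ratio must be positive", "calbold_input_error")
  }
  tibble::as_tibble(levels[, c(need, setdiff(names(levels), need))])
}

# internal: kappa lower bound that keeps 1 + kappa * dP positive for all levels
effective_kappa_low <- function(kappa_low, delta_petco2, eps = 1e-6) {
  max(kappa_low, (eps - 1) / max(delta_petco2))
}

# internal: assemble a CalibrationResult
new_calbold_fit <- function(m, kappa, model, levels, pairing, bounds,
                            residual_norm, converged = TRUE, n_starts = 1L) {
  hit <- c(
    m = (m - bounds$m_low) <= BOUNDARY_TOL | (bounds$m_high - m) <= BOUNDARY_TOL,
    kappa = if (model == "graded") {
      (kappa - bounds$kappa_low) <= BOUNDARY_TOL |
        (bounds$kappa_high - kappa) <= BOUNDARY_TOL
    } else FALSE
  )
  structure(list(
    m = m, kappa = kappa, model = model,
    hit_boundary = hit,
    residual_norm = residual_norm,
    n_levels = nrow(levels),
    levels = levels,
    pairing = pairing,
    bounds = bounds,
    converged = converged,
    n_starts = n_starts
  ), class = "calbold_fit")
}

#' Jointly fit M and kappa to multi-level hypercapnia responses
#'
#' Solves the graded-hypercapnia calibration problem: given BOLD and CBF
#' responses at two or more end-tidal CO2 levels, finds the (M, kappa) pair
#' minimising the sum of squared BOLD-fraction residuals of [graded_bold()]
#' by bounded Levenberg--Marquardt least squares. With exactly two noiseless
#' consistent levels the solution is exact (residual at machine zero) and
#' matches [solve_two_level_exact()].
#'
#' @param levels Data frame with one row per hypercapnia level and columns
#'   `delta_petco2` (mmHg), `bold_frac` (fraction), `cbf_ratio`
#'   (dimensionless). At least two rows with distinct `delta_petco2`.
#' @param pairing An [ab_pairing()] or preset name.
#' @param bounds A [fit_bounds()] box; parameters are constrained inside it
#'   and flagged when they land on it.
#' @param init Optional starting values `c(m = ..., kappa = ...)`; default
#'   is the interior iso-metabolic start (0.05, 0).
#' @param multi_start If `TRUE` (default), fit from `init` plus a 4 x 7
#'   (M x kappa) grid of interior starts: the objective can have local
#'   minima and, on
#'   two-level data, more than one exact solution, so a single start can
#'   land on a bound or on a far root. If `FALSE`, fit once from `init`
#'   and escalate to the grid only when that solution touches a bound or
#'   leaves a residual clearly above exact-fit level (a faster path for
#'   bulk noiseless work). When several starts reach numerically tied
#'   minima, the solution of smallest absolute kappa is reported, matching
#'   [solve_two_level_exact()]'s tie-break.
#' @return A `calbold_fit` object; see [tidy.calbold_fit()] and
#'   [glance.calbold_fit()] for tabular views. Fields include `m`, `kappa`
#'   (fractions), `hit_boundary`, `residual_norm`, `n_levels`, `pairing`.
#' @examples
#' lv <- tibble::tibble(delta_petco2 = c(4.8, 8.4),
#'                      cbf_ratio = c(1.13, 1.17))
#' lv$bold_frac <- graded_bold(0.086, -0.013, lv$cbf_ratio, lv$delta_petco2)
#' fit_graded(lv)
#' @seealso [fit_isometabolic()] for the classical kappa = 0 fit,
#'   [solve_two_level_exact()] for the independent two-level oracle.
#' @export
fit_graded <- function(levels, pairing = "empirical", bounds = fit_bounds(),
                       init = NULL, multi_start = TRUE) {
  levels <- validate_levels(levels, min_levels = 2L)
  p <- ab_pairing(pairing)
  if (!inherits(bounds, "fit_bounds")) {
    cb_stop("`bounds` must be a fit_bounds() object", "calbold_config_error")
  }
  klo <- effective_kappa_low(bounds$kappa_low, levels$delta_petco2)
  lower <- c(bounds$m_low, klo)
  upper <- c(bounds$m_high, bounds$kappa_high)

  resid_fun <- function(par) {
    levels$bold_frac -
      graded_bold(par[1], par[2], levels$cbf_ratio, levels$delta_petco2, p)
  }
  solve_from <- function(st) {
    minpack.lm::nls.lm(
      par = pmin(pmax(as.numeric(st), lower), upper),
      lower = lower, upper = upper, fn = resid_fun,
      control = minpack.lm::nls.lm.control(
        ftol = .Machine$double.eps, ptol = .Machine$double.eps,
        gtol = 0, maxiter = 500))
  }
  # the kappa axis needs dense coverage: on two-level data the objective
  # can have two interior exact roots with narrow basins along kappa
  grid_starts <- function() {
    ms <- seq(lower[1], upper[1], length.out = 6)[2:5]
    ks <- seq(lower[2], upper[2], length.out = 9)[2:8]
    unname(as.list(as.data.frame(t(expand.grid(ms, ks)))))
  }

  first <- solve_from(init %||% c(max(lower[1], min(upper[1], 0.05)),
                                  max(lower[2], min(upper[2], 0))))
  cands <- list(first)
  escalate <- isTRUE(multi_start) ||
    any(pmin(first$par - lower, upper - first$par) <= BOUNDARY_TOL) ||
    first$deviance > 1e-12 * max(sum(levels$bold_frac^2), 1e-8)
  if (escalate) cands <- c(cands, lapply(grid_starts(), solve_from))

  dev <- vapply(cands, function(a) a$deviance, numeric(1))
  best_dev <- min(dev)
  # among numerically tied minima report the smallest |kappa| solution
  tied <- which(dev <= best_dev * (1 + 1e-9) + 1e-30)
  best <- cands[[tied[which.min(vapply(
    cands[tied], function(a) abs(a$par[2]), numeric(1)))]]]
  new_calbold_fit(
    m = best$par[1], kappa = best$par[2], model = "graded",
    levels = levels, pairing = p, bounds = bounds,
    residual_norm = best$deviance,
    converged = best$info %in% 1:4,
    n_starts = length(cands))
}

#' Iso-metabolic (kappa = 0) calibration fit
#'
#' The classical hypercapnia calibration: least-squares M over all levels
#' with the CMRO2 ratio fixed at 1. Because the model is linear in M, the
#' bounded least-squares solution is the closed-form projection
#' `M = sum(b * g) / sum(g^2)` with `g = 1 - f^(alpha - beta)`, clamped to
#' the box. With a single level this reduces to
#' `M = bold_frac / (1 - cbf_ratio^(alpha - beta))` exactly.
#'
#' @inheritParams fit_graded
#' @param levels As in [fit_graded()] but a single level is allowed.
#' @return A `calbold_fit` with `model = "isometabolic"` and `kappa = 0`.
#' @export
fit_isometabolic <- function(levels, pairing = "empirical",
                             bounds = fit_bounds()) {
  levels <- validate_levels(levels, min_levels = 1L)
  p <- ab_pairing(pairing)
  if (!inherits(bounds, "fit_bounds")) {
    cb_stop("`bounds` must be a fit_bounds() object", "calbold_config_error")
  }
  g <- 1 - levels$cbf_ratio^(p$alpha - p$beta)
  if (all(g == 0)) {
    cb_stop("all cbf_ratio equal 1: M is unidentifiable with kappa = 0",
            "calbold_input_error")
  }
  m <- sum(levels$bold_frac * g) / sum(g^2)
  m <- min(max(m, bounds$m_low), bounds$m_high)
  new_calbold_fit(
    m = m, kappa = 0, model = "isometabolic",
    levels = levels, pairing = p, bounds = bounds,
    residual_norm = sum((levels$bold_frac - m * g)^2))
}

#' Exact two-level solver for (M, kappa)
#'
#' Independent closed-route solution of the two-equation system: eliminates
#' M by taking the ratio of the two Davis-model equations, solves the
#' resulting one-dimensional equation in kappa by bracketed root finding
#' over the positivity domain `1 + kappa * dP > 0`, then recovers
#' `M = b1 / (1 - f1^(alpha - beta) * (1 + kappa * dP1)^beta)`. Serves as an
#' oracle for [fit_graded()] on noiseless data; on noisy data the two
#' approaches coincide only when a kappa exists that fits both levels
#' exactly.
#'
#' @param levels Data frame with exactly two rows (columns as in
#'   [fit_graded()]); both `bold_frac` values must be nonzero.
#' @param pairing An [ab_pairing()] or preset name.
#' @param bounds A [fit_bounds()] box; the system can admit several exact
#'   roots, and only those whose (M, kappa) lie inside the box are
#'   physically admissible candidates.
#' @param kappa_max Upper end of the kappa search range (fraction/mmHg).
#' @param n_grid Grid resolution used to bracket sign changes.
#' @return A tibble with columns `m`, `kappa`, `n_roots` (number of
#'   distinct roots of the ratio equation found in the positivity domain;
#'   among the admissible ones, the root of smallest absolute kappa is
#'   returned).
#' @examples
#' lv <- tibble::tibble(delta_petco2 = c(4.8, 8.4),
#'                      cbf_ratio = c(1.13, 1.17))
#' lv$bold_frac <- graded_bold(0.10, -0.02, lv$cbf_ratio, lv$delta_petco2)
#' solve_two_level_exact(lv)
#' @export
solve_two_level_exact <- function(levels, pairing = "empirical",
                                  bounds = fit_bounds(),
                                  kappa_max = 0.5, n_grid = 4001L) {
  levels <- validate_levels(levels, min_levels = 2L)
  if (nrow(levels) != 2L) {
    cb_stop("solve_two_level_exact needs exactly 2 levels",
            "calbold_input_error")
  }
  if (any(levels$bold_frac == 0)) {
    cb_stop("both bold_frac values must be nonzero for the ratio equation",
            "calbold_input_error")
  }
  p <- ab_pairing(pairing)
  b <- levels$bold_frac
  f <- levels$cbf_ratio
  dP <- levels$delta_petco2
  e <- p$alpha - p$beta

  # b2 * (1 - f1^e (1+k dP1)^beta) - b1 * (1 - f2^e (1+k dP2)^beta) = 0
  h <- function(k) {
    b[2] * (1 - f[1]^e * (1 + k * dP[1])^p$beta) -
      b[1] * (1 - f[2]^e * (1 + k * dP[2])^p$beta)
  }
  hprime <- function(k) {
    -b[2] * f[1]^e * p$beta * dP[1] * (1 + k * dP[1])^(p$beta - 1) +
      b[1] * f[2]^e * p$beta * dP[2] * (1 + k * dP[2])^(p$beta - 1)
  }
  k_lo <- (1e-9 - 1) / max(dP)
  # Newton polish to machine precision (M amplifies kappa error ~100-fold)
  polish <- function(k0) {
    for (it in 1:6) {
      d <- hprime(k0)
      if (!is.finite(d) || d == 0) break
      step <- h(k0) / d
      k1 <- k0 - step
      if (!is.finite(k1) || k1 <= k_lo) break
      k0 <- k1
      if (abs(step) < 1e-17) break
    }
    k0
  }
  grid <- seq(k_lo, kappa_max, length.out = n_grid)
  hv <- vapply(grid, h, numeric(1))
  sgn <- sign(hv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  exact0 <- which(hv == 0)
  roots <- grid[exact0]
  for (i in flips) {
    r <- uniroot(h, lower = grid[i], upper = grid[i + 1],
                 tol = .Machine$double.eps^0.9)
    roots <- c(roots, polish(r$root))
  }
  # tangent (double) roots give no sign change: polish interior local
  # minima of |h| and keep those that are numerically zero
  scale <- sum(abs(b))
  absv <- abs(hv)
  lmin <- which(diff(sign(diff(absv))) > 0) + 1L
  for (i in lmin[absv[lmin] <= 1e-6 * scale]) {
    o <- stats::optimize(function(kk) h(kk)^2,
                         lower = grid[max(i - 1L, 1L)],
                         upper = grid[min(i + 1L, n_grid)],
                         tol = .Machine$double.eps)
    if (sqrt(o$objective) <= 1e-9 * scale) {
      roots <- c(roots, polish(o$minimum))  # no-op at a true tangency
    }
  }
  roots <- sort(unique(roots))
  if (length(roots) > 1L) {
    # distinct interior roots are far apart; anything closer is one root
    roots <- roots[c(TRUE, diff(roots) > 1e-8)]
  }
  if (!length(roots)) {
    cb_stop(sprintf(
      "no kappa in (%.4g, %.4g) satisfies the two-level ratio equation: the BOLD ratio b2/b1 = %.4g is unreachable",
      k_lo, kappa_max, b[2] / b[1]), "calbold_no_solution_error")
  }
  m_of <- function(k) {
    denom <- 1 - f[1]^e * (1 + k * dP[1])^p$beta
    if (denom == 0) NA_real_ else b[1] / denom
  }
  ms <- vapply(roots, m_of, numeric(1))
  tol <- 1e-9
  ok <- is.finite(ms) &
    ms >= bounds$m_low - tol & ms <= bounds$m_high + tol &
    roots >= bounds$kappa_low - tol & roots <= bounds$kappa_high + tol
  if (!any(ok)) {
    cb_stop(sprintf(
      "the two-level system has %d exact root(s), but none inside the parameter box (closest: M = %.4g, kappa = %.4g)",
      length(roots), ms[which.min(abs(roots))], roots[which.min(abs(roots))]),
      "calbold_no_solution_error")
  }
  pick <- which(ok)[which.min(abs(roots[ok]))]
  tibble::tibble(m = ms[pick], kappa = roots[pick], n_roots = length(roots))
}

#' Pair a two-parameter fit with its iso-metabolic counterpart
#'
#' Returns the paired M values and their difference for one subject, with a
#' joint inclusion flag that is `TRUE` only when neither fit reached a
#' parameter bound (the conventional exclusion rule). Both fits must share
#' the pairing and the level data.
#'
#' @param two_param A `calbold_fit` from [fit_graded()].
#' @param one_param A `calbold_fit` from [fit_isometabolic()].
#' @return A one-row tibble: `m_two`, `m_one`, `delta_m`, `kappa`,
#'   `included`.
#' @export
compare_fits <- function(two_param, one_param) {
  if (!inherits(two_param, "calbold_fit") || !inherits(one_param, "calbold_fit")) {
    cb_stop("both arguments must be calbold_fit objects", "calbold_input_error")
  }
  if (two_param$model != "graded" || one_param$model != "isometabolic") {
    cb_stop("expected a graded fit and an isometabolic fit, in that order",
            "calbold_input_error")
  }
  same_pairing <- isTRUE(all.equal(
    c(two_param$pairing$alpha, two_param$pairing$beta),
    c(one_param$pairing$alpha, one_param$pairing$beta)))
  same_levels <- isTRUE(all.equal(
    two_param$levels[, c("delta_petco2", "bold_frac", "cbf_ratio")],
    one_param$levels[, c("delta_petco2", "bold_frac", "cbf_ratio")]))
  if (!same_pairing || !same_levels) {
    cb_stop("fits do not share pairing and level data; refusing to pair them",
            "calbold_input_error")
  }
  tibble::tibble(
    m_two = two_param$m,
    m_one = one_param$m,
    delta_m = two_param$m - one_param$m,
    kappa = two_param$kappa,
    included = !any(two_param$hit_boundary) && !any(one_param$hit_boundary))
}

#' Group-level summary with boundary exclusion
#'
#' Summarises per-subject calibration results the way graded-hypercapnia
#' group analyses report them: subjects whose fit reached a parameter bound
#' are excluded, the retained values are reported as mean +/- SEM, and a
#' two-sided Wilcoxon signed-rank test is applied (exact enumeration for
#' n <= 25 after dropping zeros, normal approximation above).
#'
#' @param data A data frame of per-subject results. For `mode = "kappa"` it
#'   needs columns `kappa` (fraction/mmHg) and a logical exclusion column
#'   (default `hit_boundary`); the test is kappa vs 0. For
#'   `mode = "paired_m"` it needs `m_two`, `m_one` and `included` (as from
#'   [compare_fits()]); the test is on paired differences `m_two - m_one`.
#' @param mode `"kappa"` or `"paired_m"`.
#' @return A one-row tibble: `mode`, `included_n`, `total_n`, `mean`, `sem`
#'   (of kappa or of delta_m, in internal fraction units), `p_value`.
#' @examples
#' group_summary(tibble::tibble(kappa = -(1:6) / 100,
#'                              hit_boundary = FALSE), mode = "kappa")
#' @export
group_summary <- function(data, mode = c("kappa", "paired_m")) {
  mode <- match.arg(mode)
  if (!is.data.frame(data)) {
    cb_stop("`data` must be a data frame of per-subject results",
            "calbold_input_error")
  }
  if (mode == "kappa") {
    if (!"kappa" %in% names(data)) {
      cb_stop("`data` needs a `kappa` column", "calbold_input_error")
    }
    excl <- if ("hit_boundary" %in% names(data)) data$hit_boundary else FALSE
    keep <- data$kappa[!excl]
    values <- keep
  } else {
    need <- c("m_two", "m_one", "included")
    missing <- setdiff(need, names(data))
    if (length(missing)) {
      cb_stop(sprintf("`data` is missing column(s): %s",
                      paste(missing, collapse = ", ")),
              "calbold_input_error")
    }
    values <- (data$m_two - data$m_one)[data$included]
  }
  total_n <- nrow(data)
  included_n <- length(values)
  if (included_n == 0L) {
    cb_stop("no subjects remain after boundary exclusion",
            "calbold_empty_group_error")
  }
  tibble::tibble(
    mode = mode,
    included_n = included_n,
    total_n = total_n,
    mean = mean(values),
    sem = if (included_n > 1) sd(values) / sqrt(included_n) else NA_real_,
    p_value = wilcoxon_signed_rank(values)$p_value)
}

#' @export
print.calbold_fit <- function(x, ...) {
  cat(sprintf("<calbold_fit: %s model, %d level(s), pairing %s>\n",
              x$model, x$n_levels, format(x$pairing)))
  cat(sprintf("  M     = %.4g %%\n", 100 * x$m))
  if (x$model == "graded") {
    cat(sprintf("  kappa = %.4g %%/mmHg\n", 100 * x$kappa))
  }
  cat(sprintf("  residual norm = %.3g; boundary hit: %s\n",
              x$residual_norm,
              if (any(x$hit_boundary)) {
                paste(names(x$hit_boundary)[x$hit_boundary], collapse = ", ")
              } else "none"))
  invisible(x)
}

#' Tidy a calibration fit
#'
#' @param x A `calbold_fit`.
#' @param percent If `TRUE`, report M in % and kappa in %/mmHg (the
#'   conventional reporting units); otherwise internal fractions.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `hit_boundary`.
#' @export
tidy.calbold_fit <- function(x, percent = FALSE, ...) {
  scale <- if (percent) 100 else 1
  terms <- if (x$model == "graded") c("m", "kappa") else "m"
  tibble::tibble(
    term = terms,
    estimate = c(x$m, x$kappa)[seq_along(terms)] * scale,
    hit_boundary = unname(x$hit_boundary[terms]))
}

#' Glance at a calibration fit
#'
#' @param x A `calbold_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model, n_levels, residual_norm, pairing name
#'   and exponents, convergence flag, any boundary hit.
#' @export
glance.calbold_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_levels = x$n_levels,
    residual_norm = x$residual_norm,
    pairing = x$pairing$name,
    alpha = x$pairing$alpha,
    beta = x$pairing$beta,
    converged = x$converged,
    any_boundary = any(x$hit_boundary))
}
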