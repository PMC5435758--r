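#' CMRO2 ratio under a linear dose--response to hypercapnia
#'
#' The basal cerebral metabolic rate of oxygen during hypercapnia, relative
#' to normocapnia, is modelled as a linear function of the end-tidal CO2
#' increase: `CMRO2_HC / CMRO2_0 = 1 + kappa * delta_petco2`.
#'
#' @param kappa Dose-wise fractional CMRO2 change per mmHg increase in
#'   end-tidal CO2 (fraction/mmHg; e.g. -0.015 means a 1.5 %/mmHg decrease).
#' @param delta_petco2 End-tidal CO2 increase above normocapnic baseline
#'   (mmHg).
#' @return The dimensionless CMRO2 ratio `1 + kappa * delta_petco2`.
#'   Errors if the ratio would be non-positive.
#' @examples
#' cmro2_ratio_from_dose(0, 8.4)        # iso-metabolic: 1
#' cmro2_ratio_from_dose(-0.0154, 8.7)  # a 13.4 % decrease
#' @seealso [kappa_from_cmro2_ratio()] for the inverse, [graded_bold()].
#' @export
cmro2_ratio_from_dose <- function(kappa, delta_petco2) {
  check_finite(kappa, "kappa")
  check_finite(delta_petco2, "delta_petco2")
  ratio <- 1 + kappa * delta_petco2
  bad <- ratio <= 0
  if (any(bad)) {
    i <- which(bad)[1L]
    cb_stop(sprintf(
      "CMRO2 ratio must be positive; kappa = %g /mmHg with delta_petco2 = %g mmHg gives %g",
      kappa[pmin(i, length(kappa))], delta_petco2[pmin(i, length(delta_petco2))],
      ratio[i]), "calbold_domain_error")
  }
  ratio
}

#' Dose-wise CMRO2 slope implied by a fractional CMRO2 change
#'
#' Inverts the linear dose model: given a CMRO2 ratio observed at a known
#' end-tidal CO2 increase, returns the dose-wise slope
#' `kappa = (ratio - 1) / delta_petco2` (fraction/mmHg).
#'
#' @param cmro2_ratio CMRO2 during hypercapnia relative to baseline
#'   (dimensionless, > 0).
#' @param delta_petco2 End-tidal CO2 increase (mmHg, nonzero).
#' @return kappa in fraction/mmHg. Multiply by 100 for %/mmHg.
#' @examples
#' # a 13.4 % global CMRO2 decrease at +8.7 mmHg corresponds to -1.5 %/mmHg
#' 100 * kappa_from_cmro2_ratio(1 - 0.134, 8.7)
#' @export
kappa_from_cmro2_ratio <- function(cmro2_ratio, delta_petco2) {
  check_finite(cmro2_ratio, "cmro2_ratio")
  check_finite(delta_petco2, "delta_petco2")
  if (any(cmro2_ratio <= 0)) {
    cb_stop("cmro2_ratio must be positive", "calbold_domain_error")
  }
  if (any(delta_petco2 == 0)) {
    cb_stop("delta_petco2 must be nonzero to define a dose-wise slope",
            "calbold_domain_error")
  }
  (cmro2_ratio - 1) / delta_petco2
}

#' Davis-model BOLD signal change
#'
#' Forward calibrated-BOLD model: the fractional BOLD signal change produced
#' by joint CBF and CMRO2 changes,
#' `dBOLD/BOLD0 = M * (1 - f^(alpha - beta) * r^beta)` with `f` the CBF
#' ratio and `r` the CMRO2 ratio relative to baseline.
#'
#' @param m Calibration parameter M, the maximal fractional BOLD change if
#'   all deoxyhemoglobin were removed (fraction, > 0; e.g. 0.086 for 8.6 %).
#' @param cbf_ratio CBF during the condition relative to baseline (> 0).
#' @param cmro2_ratio CMRO2 relative to baseline (> 0).
#' @param pairing An [ab_pairing()] or preset name.
#' @return Fractional BOLD signal change (dimensionless). Zero when both
#'   ratios are 1.
#' @examples
#' davis_bold(0.10, cbf_ratio = 1.17, cmro2_ratio = 1, pairing = "empirical")
#' @seealso [invert_for_cmro2()], [graded_bold()]
#' @export
davis_bold <- function(m, cbf_ratio, cmro2_ratio, pairing = "empirical") {
  p <- ab_pairing(pairing)
  check_finite(m, "m")
  check_finite(cbf_ratio, "cbf_ratio")
  check_finite(cmro2_ratio, "cmro2_ratio")
  if (any(m <= 0)) cb_stop("M must be positive", "calbold_domain_error")
  if (any(cbf_ratio <= 0)) {
    cb_stop("cbf_ratio must be positive", "calbold_domain_error")
  }
  if (any(cmro2_ratio <= 0)) {
    cb_stop("cmro2_ratio must be positive", "calbold_domain_error")
  }
  m * (1 - cbf_ratio^(p$alpha - p$beta) * cmro2_ratio^p$beta)
}

#' BOLD change under graded hypercapnia with a linear CMRO2 dose--response
#'
#' Composes the linear CMRO2 dose model into the Davis model:
#' `dBOLD/BOLD0 = M * (1 - f^(alpha - beta) * (1 + kappa * dP)^beta)`.
#' This is the two-unknown (M, kappa) forward model that one BOLD/CBF
#' measurement per hypercapnia level constrains.
#'
#' @inheritParams davis_bold
#' @inheritParams cmro2_ratio_from_dose
#' @return Fractional BOLD signal change.
#' @examples
#' graded_bold(0.10, kappa = -0.015, cbf_ratio = 1.17, delta_petco2 = 8.4)
#' @export
graded_bold <- function(m, kappa, cbf_ratio, delta_petco2,
                        pairing = "empirical") {
  davis_bold(m, cbf_ratio, cmro2_ratio_from_dose(kappa, delta_petco2),
             pairing)
}

#' Invert the Davis model for the CMRO2 ratio
#'
#' Given a measured fractional BOLD change, CBF ratio, and a calibration
#' parameter M, solves the Davis model for the CMRO2 ratio:
#' `r = ((1 - b/M) * f^(beta - alpha))^(1/beta)`. This is the standard
#' endpoint of a calibrated-BOLD experiment (task CMRO2 response).
#'
#' @inheritParams davis_bold
#' @param bold_frac Measured fractional BOLD change (must be < `m`).
#' @return CMRO2 ratio (dimensionless, > 0). Round-trips with
#'   [davis_bold()].
#' @examples
#' b <- davis_bold(0.10, 1.17, 0.874)
#' invert_for_cmro2(0.10, b, 1.17)  # 0.874
#' @export
invert_for_cmro2 <- function(m, bold_frac, cbf_ratio, pairing = "empirical") {
  p <- ab_pairing(pairing)
  check_finite(m, "m")
  check_finite(bold_frac, "bold_frac")
  check_finite(cbf_ratio, "cbf_ratio")
  if (any(m <= 0)) cb_stop("M must be positive", "calbold_domain_error")
  if (any(cbf_ratio <= 0)) {
    cb_stop("cbf_ratio must be positive", "calbold_domain_error")
  }
  if (any(bold_frac >= m)) {
    cb_stop(sprintf(
      "bold_frac (%g) must be smaller than M (%g): the model cannot reach its own ceiling",
      max(bold_frac), min(m)), "calbold_domain_error")
  }
  ((1 - bold_frac / m) * cbf_ratio^(p$beta - p$alpha))^(1 / p$beta)
}

#' Relative BOLD contrast of a gradient-echo acquisition at a given echo time
#'
#' Under the spoiled gradient-echo contrast model, BOLD sensitivity is
#' proportional to `TE * exp(-TE * R2*)`, maximal at `TE = 1/R2*`. This
#' helper returns contrast relative to that optimum, useful for judging how
#' well a fixed echo time suits a region's R2*.
#'
#' @param te Echo time (seconds, > 0).
#' @param r2star Effective transverse relaxation rate (1/s, > 0).
#' @return Contrast relative to the optimum (dimensionless, in (0, 1]).
#' @examples
#' relative_bold_contrast(0.029, 31.7)  # 29 ms is near-optimal for R2* ~ 31.7
#' relative_bold_contrast(0.029, 22.3)  # less so for a lower R2*
#' @export
relative_bold_contrast <- function(te, r2star) {
  check_finite(te, "te")
  check_finite(r2star, "r2star")
  if (any(te <= 0)) cb_stop("te must be positive", "calbold_domain_error")
  if (any(r2star <= 0)) {
    cb_stop("r2star must be positive", "calbold_domain_error")
  }
  (te * r2star) * exp(1 - te * r2star)
}
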