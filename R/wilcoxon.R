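#' Two-sided Wilcoxon signed-rank test
#'
#' Signed-rank test of symmetry about `mu`, in the variant conventional for
#' small calibrated-fMRI group analyses: zero differences are dropped
#' (Wilcoxon's original treatment), ties among absolute values receive
#' midranks, and the null distribution is obtained by exact enumeration of
#' all sign assignments when n <= `exact_max_n` (via the generating-function
#' convolution, so ties are handled exactly) and by the normal approximation
#' with tie correction and continuity correction otherwise.
#'
#' @param x Numeric vector of differences (e.g. per-subject kappa values, or
#'   paired M differences).
#' @param mu Hypothesised centre of symmetry (default 0).
#' @param exact_max_n Largest n (after dropping zeros) for which the exact
#'   null is enumerated.
#' @return A tibble: `statistic` (W+, sum of positive signed ranks), `n`
#'   (nonzero differences used), `p_value`, `method` ("exact" or "normal").
#' @examples
#' wilcoxon_signed_rank(-(1:6))  # p = 2/2^6 = 0.03125, the n = 6 floor
#' @export
wilcoxon_signed_rank <- function(x, mu = 0, exact_max_n = 25L) {
  check_finite(x, "x")
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    cb_stop("all differences are zero: signed-rank test undefined",
            "calbold_empty_group_error")
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])

  if (n <= exact_max_n) {
    # exact null: distribution of W+ over all 2^n sign assignments.
    # midranks may be half-integers; double them so polynomial indices are
    # integers. counts[s + 1] = number of assignments with doubled sum s.
    dr <- as.integer(round(2 * r))
    total <- sum(dr)
    counts <- c(1, rep(0, total))
    for (di in dr) {
      shifted <- c(rep(0, di), counts[seq_len(total + 1 - di)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    w2 <- round(2 * w_plus)
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu_w <- n * (n + 1) / 4
    # variance with tie correction (midranks)
    sigma2 <- sum(r^2) / 4
    z <- (w_plus - mu_w - sign(w_plus - mu_w) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  tibble::tibble(statistic = w_plus, n = n, p_value = p, method = method)
}
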