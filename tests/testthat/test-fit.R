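# Bounded (M, kappa) fitting, the exact two-level oracle, and group layer.

test_that("noiseless two-level data is recovered exactly by both routes", {
  lv <- make_levels(0.086, -0.013)
  fit <- fit_graded(lv)
  expect_equal(fit$m, 0.086, tolerance = 1e-8)
  expect_equal(fit$kappa, -0.013, tolerance = 1e-8)
  expect_lt(fit$residual_norm, 1e-16)
  expect_false(any(fit$hit_boundary))
  ex <- solve_two_level_exact(lv)
  expect_equal(fit$m, ex$m, tolerance = 1e-8)
  expect_equal(fit$kappa, ex$kappa, tolerance = 1e-8)
})

test_that("two-level oracle round-trips generating parameters incl. positive kappa", {
  for (truth in list(c(0.10, -0.02), c(0.08, 0.01))) {
    lv <- make_levels(truth[1], truth[2])
    ex <- solve_two_level_exact(lv)
    expect_equal(ex$m, truth[1], tolerance = 1e-10)
    expect_equal(ex$kappa, truth[2], tolerance = 1e-10)
    expect_equal(ex$n_roots, 1L)
  }
})

test_that("an unreachable BOLD ratio raises a no-solution error, never a clamp", {
  # brute-force the reachable range of b2/b1 over the kappa domain, then ask
  # for a ratio beyond it
  f <- c(1.3, 1.3); dP <- c(4.8, 8.4)
  e <- 0.14 - 0.91
  ratio_fun <- function(k) {
    (1 - f[2]^e * (1 + k * dP[2])^0.91) / (1 - f[1]^e * (1 + k * dP[1])^0.91)
  }
  ks <- seq((1e-9 - 1) / max(dP), 0.5, length.out = 20001)
  reachable <- range(ratio_fun(ks))
  bad_ratio <- reachable[2] * 3
  lv <- tibble::tibble(delta_petco2 = dP, cbf_ratio = f,
                       bold_frac = c(0.01, 0.01 * bad_ratio))
  expect_error(solve_two_level_exact(lv), class = "calbold_no_solution_error")
})

test_that("fit and oracle agree on random noiseless instances across pairings", {
  withr::local_seed(42)
  for (p in c("empirical", "3T", "simplified")) {
    n_ok <- 0
    while (n_ok < 50) {
      m <- runif(1, 0.02, 0.18)
      k <- runif(1, -0.04, 0.04)
      f1 <- runif(1, 1.05, 1.3)
      lv <- make_levels(m, k, p, f = c(f1, f1 + runif(1, 0.02, 0.2)),
                        dP = c(runif(1, 3, 6), runif(1, 7, 10)))
      if (any(abs(lv$bold_frac) < 1e-4) ||
          two_level_conditioning(lv, k, p) < 1e-3) next
      fit <- fit_graded(lv, p)
      ex <- solve_two_level_exact(lv, p)
      expect_equal(fit$m, ex$m, tolerance = 1e-8)
      expect_equal(fit$kappa, ex$kappa, tolerance = 1e-8)
      n_ok <- n_ok + 1
    }
  }
})

test_that("kappa = 0 data collapses the graded fit onto the iso-metabolic fit", {
  lv <- make_levels(0.06, 0)
  fit <- fit_graded(lv)
  iso <- fit_isometabolic(lv)
  expect_equal(fit$kappa, 0, tolerance = 1e-8)
  expect_equal(fit$m, iso$m, tolerance = 1e-8)
  expect_lt(iso$residual_norm, 1e-16)
})

test_that("a generating kappa near the bound is still solved or flagged, matching the oracle", {
  lv <- make_levels(0.05, -0.049)
  fit <- fit_graded(lv)
  ex <- solve_two_level_exact(lv)
  if (any(fit$hit_boundary)) {
    expect_true(fit$hit_boundary["kappa"])
  } else {
    expect_equal(fit$kappa, ex$kappa, tolerance = 1e-8)
    expect_equal(fit$m, ex$m, tolerance = 1e-8)
  }
  expect_equal(ex$kappa, -0.049, tolerance = 1e-8)
})

test_that("single-level iso-metabolic fit equals the closed-form inverse", {
  lv <- tibble::tibble(delta_petco2 = 8.4, cbf_ratio = 1.17,
                       bold_frac = 0.0113871129199485)
  iso <- fit_isometabolic(lv)
  expect_equal(iso$m, 0.10, tolerance = 1e-10)
  expect_equal(iso$m, lv$bold_frac / (1 - 1.17^(0.14 - 0.91)),
               tolerance = 1e-12)
})

test_that("ignoring a CMRO2 decrease inflates M; a brute-force grid agrees", {
  lv <- make_levels(0.06, -0.015)
  iso <- fit_isometabolic(lv)
  expect_gt(iso$m, 0.06)
  # independent route: scan the kappa = 0 sum of squares over an M grid
  g <- 1 - lv$cbf_ratio^(0.14 - 0.91)
  ms <- seq(0.01, 0.2, by = 1e-4)
  sse <- vapply(ms, function(m) sum((lv$bold_frac - m * g)^2), numeric(1))
  expect_equal(iso$m, ms[which.min(sse)], tolerance = 1e-3)  # grid step 1e-4
  expect_gt(ms[which.min(sse)], 0.06)
})

test_that("direction of bias follows the sign of the true kappa", {
  for (p in c("empirical", "3T", "simplified")) {
    for (m in c(0.04, 0.086, 0.15)) {
      down <- make_levels(m, -0.012, p)
      up <- make_levels(m, 0.012, p)
      flat <- make_levels(m, 0, p)
      expect_gt(fit_isometabolic(down, p)$m, fit_graded(down, p)$m)
      expect_lt(fit_isometabolic(up, p)$m, fit_graded(up, p)$m)
      expect_equal(fit_isometabolic(flat, p)$m, fit_graded(flat, p)$m,
                   tolerance = 1e-8)
    }
  }
})

test_that("fitted parameters always respect the box and flags mark bound hits", {
  withr::local_seed(7)
  b <- fit_bounds()
  for (i in 1:40) {
    lv <- make_levels(runif(1, 0.02, 0.18), runif(1, -0.045, 0.045))
    lv$bold_frac <- lv$bold_frac + rnorm(2, 0, 0.004)  # heavy noise
    lv <- lv[lv$bold_frac != 0, ]
    if (nrow(lv) < 2) next
    fit <- fit_graded(lv)
    expect_gte(fit$m, b$m_low); expect_lte(fit$m, b$m_high)
    expect_gte(fit$kappa, b$kappa_low); expect_lte(fit$kappa, b$kappa_high)
    at_edge <- c(m = min(fit$m - b$m_low, b$m_high - fit$m) <= 1e-6,
                 kappa = min(fit$kappa - b$kappa_low,
                             b$kappa_high - fit$kappa) <= 1e-6)
    expect_identical(fit$hit_boundary, at_edge)
  }
})

test_that("more than two levels are pooled by least squares", {
  lv <- make_levels(0.09, -0.01, f = c(1.08, 1.13, 1.17), dP = c(2.5, 4.8, 8.4))
  fit <- fit_graded(lv)
  expect_equal(fit$m, 0.09, tolerance = 1e-7)
  expect_equal(fit$kappa, -0.01, tolerance = 1e-7)
  expect_equal(fit$n_levels, 3L)
})

test_that("level-table validation rejects malformed input", {
  lv <- make_levels(0.08, -0.01)
  expect_error(fit_graded(lv[1, ]), class = "calbold_input_error")
  expect_error(fit_graded(dplyr::mutate(lv, delta_petco2 = c(4.8, 4.8))),
               class = "calbold_input_error")
  expect_error(fit_graded(dplyr::select(lv, -bold_frac)),
               class = "calbold_input_error")
  expect_error(fit_graded(dplyr::mutate(lv, cbf_ratio = c(-1, 1.17))),
               class = "calbold_input_error")
  expect_error(fit_isometabolic(lv[0, ]), class = "calbold_input_error")
})

test_that("compare_fits pairs matching fits and refuses mismatched metadata", {
  lv <- make_levels(0.086, -0.013)
  two <- fit_graded(lv)
  one <- fit_isometabolic(lv)
  cmp <- compare_fits(two, one)
  expect_true(cmp$included)
  expect_lt(cmp$delta_m, 0)  # true kappa < 0 implies lower two-parameter M
  other <- fit_isometabolic(lv, "3T")
  expect_error(compare_fits(two, other), class = "calbold_input_error")
  expect_error(compare_fits(one, two), class = "calbold_input_error")
  # a boundary-hit partner excludes the pair
  lv2 <- make_levels(0.21, -0.001)  # generating M above the box
  two2 <- fit_graded(lv2)
  one2 <- fit_isometabolic(lv2)
  expect_false(compare_fits(two2, one2)$included)
})

test_that("group summary reports mean, SEM and exact Wilcoxon p with exclusion", {
  g <- group_summary(tibble::tibble(kappa = -(1:6) / 100,
                                    hit_boundary = FALSE), mode = "kappa")
  expect_equal(g$p_value, 0.03125)
  expect_equal(g$included_n, 6L)
  g2 <- group_summary(tibble::tibble(kappa = c(1, 2, 3) / 100,
                                     hit_boundary = FALSE), mode = "kappa")
  expect_equal(100 * g2$mean, 2)
  expect_equal(100 * g2$sem, 0.577350269189626, tolerance = 1e-12)
  # exclusion bookkeeping: included + excluded = total
  g3 <- group_summary(tibble::tibble(kappa = c(-0.01, -0.02, -0.05, 0.03),
                                     hit_boundary = c(FALSE, FALSE, TRUE, FALSE)),
                      mode = "kappa")
  expect_equal(g3$included_n, 3L)
  expect_equal(g3$total_n, 4L)
  expect_error(group_summary(tibble::tibble(kappa = 1, hit_boundary = TRUE),
                             mode = "kappa"),
               class = "calbold_empty_group_error")
})

test_that("tidy and glance views expose estimates and fit metadata", {
  fit <- fit_graded(make_levels(0.086, -0.013))
  td <- tidy(fit, percent = TRUE)
  expect_equal(td$term, c("m", "kappa"))
  expect_equal(td$estimate, c(8.6, -1.3), tolerance = 1e-6)
  gl <- glance(fit)
  expect_equal(gl$pairing, "empirical")
  expect_false(gl$any_boundary)
  expect_equal(tidy(fit_isometabolic(make_levels(0.086, 0)))$term, "m")
})
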