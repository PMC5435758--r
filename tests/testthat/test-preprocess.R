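# Surround subtraction/averaging, R2* estimation, detrending, block
# responses, end-tidal levels, ROI averaging.

test_that("surround subtraction: constant labels give the constant difference", {
  s <- make_dualecho(tag_e1 = rep(990, 3), con_e1 = rep(1000, 3))
  p <- perfusion_series(s)
  expect_equal(p$value, rep(10, 6))
  expect_equal(nrow(p), nrow(s))
  # identical values in both labels -> all-zero difference
  s0 <- make_dualecho(tag_e1 = rep(7, 3), con_e1 = rep(7, 3))
  expect_equal(perfusion_series(s0)$value, rep(0, 6))
})

test_that("surround subtraction interpolates a ramp exactly (hand-computed)", {
  # tag at t = 0, 2, 4 ramps 990 -> 980; control constant 1000 at t = 1, 3, 5
  s <- make_dualecho(tag_e1 = c(990, 985, 980), con_e1 = rep(1000, 3))
  p <- perfusion_series(s)
  expect_equal(p$value, c(10, 12.5, 15, 17.5, 20, 22.5))
})

test_that("surround averaging isolates BOLD modulation from perfusion", {
  s <- make_dualecho(tag_e1 = rep(990, 4), con_e1 = rep(1000, 4),
                     tag_e2 = c(400, 400, 404, 404),
                     con_e2 = c(420, 420, 424.2, 424.2))
  b <- bold_series(s)
  expect_equal(b$value[1], 410)
  # a pure echo-2 modulation leaves the echo-1 difference untouched
  expect_equal(perfusion_series(s)$value, rep(10, 8))
  # constant labels: average is the midpoint
  s2 <- make_dualecho(tag_e1 = rep(990, 3), con_e1 = rep(1000, 3),
                      tag_e2 = rep(990, 3), con_e2 = rep(1000, 3))
  expect_equal(bold_series(s2)$value, rep(995, 6))
})

test_that("degenerate single-label input errors", {
  s <- tibble::tibble(time_s = 0:3, label = rep("tag", 4),
                      echo1 = 1, echo2 = 1)
  expect_error(perfusion_series(s), class = "calbold_input_error")
  s2 <- make_dualecho(tag_e1 = rep(1, 3), con_e1 = rep(1, 3))
  s2$label[2] <- "tag"  # breaks alternation
  expect_error(bold_series(s2), class = "calbold_input_error")
})

test_that("perfusion and BOLD extraction are linear operators", {
  withr::local_seed(21)
  s <- make_dualecho(tag_e1 = runif(5, 900, 1100), con_e1 = runif(5, 900, 1100),
                     tag_e2 = runif(5, 300, 500), con_e2 = runif(5, 300, 500))
  s3 <- dplyr::mutate(s, echo1 = 3 * echo1, echo2 = 3 * echo2)
  expect_equal(perfusion_series(s3)$value, 3 * perfusion_series(s)$value)
  expect_equal(bold_series(s3)$value, 3 * bold_series(s)$value)
})

test_that("two-point R2* inverts a mono-exponential decay exactly", {
  te1 <- 0.0033; te2 <- 0.029
  s1 <- 1000
  r_true <- 30
  s2 <- s1 * exp(-r_true * (te2 - te1))
  s <- make_dualecho(tag_e1 = rep(s1, 3), con_e1 = rep(s1, 3),
                     tag_e2 = rep(s2, 3), con_e2 = rep(s2, 3))
  expect_equal(r2star_series(s, te1, te2)$value, rep(r_true, 6),
               tolerance = 1e-12)
  # equal signals at both echoes -> R2* = 0
  sflat <- make_dualecho(tag_e1 = rep(500, 3), con_e1 = rep(500, 3))
  expect_equal(r2star_series(sflat, te1, te2)$value, rep(0, 6))
})

test_that("label-dependent R2* combines to the midpoint by surround averaging", {
  te1 <- 0.0033; te2 <- 0.029; d <- te2 - te1
  s <- make_dualecho(tag_e1 = rep(1000, 3), con_e1 = rep(1000, 3),
                     tag_e2 = rep(1000 * exp(-30 * d), 3),
                     con_e2 = rep(1000 * exp(-32 * d), 3))
  expect_equal(r2star_series(s, te1, te2)$value, rep(31, 6), tolerance = 1e-12)
  # non-positive signal reports the offending index
  s$echo2[3] <- -1
  expect_error(r2star_series(s, te1, te2), class = "calbold_domain_error")
})

test_that("baseline detrending removes a pure drift and preserves amplitudes", {
  prd <- toy_paradigm()
  t <- 0:79
  drift <- 100 + 0.05 * t
  s <- tibble::tibble(time_s = t, value = drift)
  d <- detrend_baseline(s, prd)
  expect_lt(max(abs(d$value)), 1e-10)
  expect_equal(attr(d, "baseline_level"),
               mean(drift[in_win <- t %in% c(0:18, 40:58)]), tolerance = 1e-6)
  # drift + block response: amplitude survives detrending
  resp <- ifelse((t >= 20 & t < 40) | (t >= 60 & t < 80), 13, 0)
  s2 <- tibble::tibble(time_s = t, value = drift + resp)
  d2 <- detrend_baseline(s2, prd)
  expect_equal(block_response(d2, prd, "hc1"),
               13 / mean(drift[t %in% c(0:18, 40:58)]), tolerance = 1e-9)
  # a drift-free series changes by at most a constant
  s3 <- tibble::tibble(time_s = t, value = rep(42, 80))
  d3 <- detrend_baseline(s3, prd)
  expect_lt(diff(range(d3$value)), 1e-12)
})

test_that("detrending requires two baseline blocks", {
  one_base <- paradigm(tibble::tibble(
    condition = c("baseline", "hc1"), onset_s = c(0, 20), duration_s = 20),
    steady_state_offset_s = 0)
  s <- tibble::tibble(time_s = 0:39, value = rnorm(40))
  expect_error(detrend_baseline(s, one_base), class = "calbold_input_error")
})

test_that("block responses are fractional changes against the baseline mean", {
  prd <- toy_paradigm()
  t <- 0:79
  val <- ifelse((t >= 20 & t < 40) | (t >= 60 & t < 80), 113, 100)
  s <- tibble::tibble(time_s = t, value = val)
  expect_equal(block_response(s, prd, "hc1"), 0.13, tolerance = 1e-12)
  # identical baseline and condition -> 0
  s0 <- tibble::tibble(time_s = t, value = rep(100, 80))
  expect_equal(block_response(s0, prd, "hc1"), 0)
  # two condition blocks with different means average across blocks
  val2 <- rep(100, 80)
  val2[t >= 20 & t < 40] <- 110
  val2[t >= 60 & t < 80] <- 116
  s2 <- tibble::tibble(time_s = t, value = val2)
  expect_equal(block_response(s2, prd, "hc1"), 0.13, tolerance = 1e-12)
  expect_error(block_response(s, prd, "absent"), class = "calbold_input_error")
  sneg <- tibble::tibble(time_s = t, value = val - 200)
  expect_error(block_response(sneg, prd, "hc1"), class = "calbold_domain_error")
})

test_that("end-tidal levels difference condition and baseline window means", {
  prd <- toy_paradigm()
  bt <- seq(0, 79, by = 2)
  pet <- ifelse((bt >= 20 & bt < 40) | (bt >= 60 & bt < 80), 44.8, 40)
  tr <- tibble::tibble(time_s = bt, petco2_mmhg = pet)
  expect_equal(endtidal_level(tr, prd, "hc1"), 4.8, tolerance = 1e-12)
  expect_equal(endtidal_level(dplyr::mutate(tr, petco2_mmhg = 41), prd, "hc1"), 0)
  # a ramp settling late: a steady-state offset restricts to settled breaths
  prd2 <- toy_paradigm(offset = 10)
  ramp <- ifelse(bt >= 20 & bt < 40, pmin(44.8, 40 + (bt - 20) * 0.48), 40)
  ramp[bt >= 60 & bt < 80] <- pmin(44.8, 40 + (bt[bt >= 60 & bt < 80] - 60) * 0.48)
  tr2 <- tibble::tibble(time_s = bt, petco2_mmhg = ramp)
  expect_equal(endtidal_level(tr2, prd2, "hc1"), 4.8, tolerance = 1e-12)
  expect_lt(endtidal_level(tr2, toy_paradigm(), "hc1"), 4.8)
  # empty window errors
  sparse <- tibble::tibble(time_s = c(1, 50), petco2_mmhg = c(40, 40))
  expect_error(suppressWarnings(endtidal_level(sparse, prd, "hc1")),
               class = "calbold_input_error")
})

test_that("ROI averaging means over mask voxels and validates grids", {
  vol <- array(7, dim = c(3, 3, 2, 4))
  mask <- array(1, dim = c(3, 3, 2))
  out <- roi_average(vol, mask, tr = 2.2)
  expect_equal(out$value, rep(7, 4))
  expect_equal(out$time_s, (0:3) * 2.2)
  # two-voxel mask with values 1 and 3 -> 2
  vol2 <- array(0, dim = c(2, 2, 1, 1))
  vol2[1, 1, 1, 1] <- 1; vol2[2, 1, 1, 1] <- 3
  mask2 <- array(0, dim = c(2, 2, 1)); mask2[1:2, 1, 1] <- 1
  expect_equal(roi_average(vol2, mask2)$value, 2)
  expect_error(roi_average(vol, array(1, dim = c(2, 2, 2))),
               class = "calbold_input_error")
  expect_error(roi_average(vol, array(0, dim = c(3, 3, 2))),
               class = "calbold_input_error")
})

test_that("ROI averaging reads NIfTI volumes when RNifti is available", {
  skip_if_not_installed("RNifti")
  dir <- withr::local_tempdir()
  vol <- array(rnorm(3 * 3 * 2 * 5, mean = 100), dim = c(3, 3, 2, 5))
  mask <- array(0L, dim = c(3, 3, 2)); mask[2, 2, 1] <- 1L
  vp <- file.path(dir, "vol.nii.gz"); mp <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), vp)
  RNifti::writeNifti(RNifti::asNifti(mask), mp)
  out <- roi_average(vp, mp)
  expect_equal(out$value, vol[2, 2, 1, ], tolerance = 1e-6)
})

test_that("full level extraction recovers a constructed noiseless experiment", {
  s <- simulate_dualecho(exact_sim_config(seed = 2))
  lv <- hypercapnia_levels(s$series, s$endtidal, s$paradigm)
  lv <- lv[order(lv$delta_petco2), ]
  expect_equal(lv$delta_petco2, c(4.8, 8.4), tolerance = 0.05)
  expect_equal(lv$cbf_ratio, c(1.13, 1.17), tolerance = 1e-3)
  expect_equal(lv$bold_frac, s$truth$bold_frac, tolerance = 1e-3)
})

test_that("session averaging means responses per condition across sessions", {
  s1 <- hypercapnia_levels_of_seed <- function(sd) {
    s <- simulate_dualecho(sim_config(seed = sd))
    hypercapnia_levels(s$series, s$endtidal, s$paradigm)
  }
  lv <- dplyr::bind_rows(s1(1), s1(2))
  avg <- average_session_levels(lv)
  expect_equal(nrow(avg), 2L)
  expect_equal(unname(avg$n_sessions), c(2L, 2L))
  one <- lv[lv$condition == "hc1", ]
  expect_equal(avg$bold_frac[avg$condition == "hc1"], mean(one$bold_frac))
  expect_error(average_session_levels(lv[, -2]), class = "calbold_input_error")
})
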