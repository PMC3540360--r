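test_that("trapezoid AUC matches hand-computed areas", {
  expect_equal(auc_trapezoid(make_profile(c(0, 1), c(0, 100))), 50)
  expect_equal(auc_trapezoid(make_profile(0:3, rep(100, 4))), 300)
  expect_equal(
    auc_trapezoid(make_profile(c(0, 0.5, 1, 2, 4),
                               c(0, 1000, 600, 300, 100))),
    250 + 400 + 450 + 400)
  # a leading censored point counts as zero, so this is a valid triangle
  expect_equal(auc_trapezoid(make_profile(c(0, 1), c(NA, 100))), 50)
  expect_error(auc_trapezoid(make_profile(1, 100)), "insufficient")
})

test_that("trapezoid AUC equals the analytic integral of piecewise-linear
           profiles and is additive over sub-intervals", {
  set.seed(42)
  for (i in 1:200) {
    case <- random_piecewise_linear()
    expect_equal(auc_trapezoid(case$profile), case$exact,
                 tolerance = 1e-12)
  }
  # additivity: splitting a profile at an interior sample point
  p <- random_piecewise_linear(9)$profile
  t <- p$points$time_h
  left <- make_profile(t[1:5], p$points$conc_ng_ml[1:5])
  right <- make_profile(t[5:9], p$points$conc_ng_ml[5:9])
  expect_equal(auc_trapezoid(left) + auc_trapezoid(right),
               auc_trapezoid(p), tolerance = 1e-12)
})

test_that("BLOQ handling: leading censored points count as zero, embedded and
           trailing ones are excluded", {
  p <- make_profile(c(0, 1, 2, 3, 4, 5),
                    c(NA, 100, NA, 50, 25, NA))
  # leading NA -> 0 at t=0; embedded NA at t=2 dropped (segment 1->3);
  # trailing NA at t=5 ends the span at t=4
  expect_equal(auc_trapezoid(p), 50 + 150 + 37.5)
})

test_that("terminal slope recovers noise-free mono-exponential rates exactly
           and the printed-constant pair is self-inverse", {
  for (k in c(0.05, 0.112, 0.219, 0.5)) {
    fit <- fit_terminal_slope(mono_exp_profile(k))
    expect_equal(fit$k_per_h, k, tolerance = 1e-9)
    expect_identical(fit$beta_per_h, fit$k_per_h)
    expect_equal(fit$slope_log10_per_h * (-2.303), fit$beta_per_h,
                 tolerance = 1e-12)
    expect_identical(half_life(fit$k_per_h), 0.693 / fit$k_per_h)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  }
  # a log10 slope of -0.1/h corresponds to beta = 0.2303/h
  p <- make_profile(0:5, 1000 * 10^(-0.1 * (0:5)))
  expect_identical(round(fit_terminal_slope(p)$beta_per_h, 4), 0.2303)
})

test_that("terminal fit rejects flat or rising data and thin profiles", {
  flat <- make_profile(0:4, c(200, rep(100, 4)))
  fit <- fit_terminal_slope(flat)
  expect_false(fit$accepted)
  expect_match(fit$flags, "not_negative")
  expect_error(fit_terminal_slope(make_profile(c(0, 1, 2), c(10, 5, 2))),
               "insufficient")  # only 2 points after Cmax
  # exactly 3 points after the maximum uses all of them
  p <- mono_exp_profile(0.2, times = c(0, 1, 2, 3))
  fit <- fit_terminal_slope(p)
  expect_equal(fit$n_points, 3)
})

test_that("explicit window override restricts the regression range", {
  p <- mono_exp_profile(0.3, times = c(0, 1, 2, 4, 8, 12, 16, 20))
  fit <- fit_terminal_slope(p, lambda_z_policy(window = c(8, 20)))
  expect_equal(fit$t_first_h, 8)
  expect_equal(fit$n_points, 4)
  expect_equal(fit$k_per_h, 0.3, tolerance = 1e-9)
})

test_that("half life uses the printed constant", {
  expect_equal(half_life(0.219), 3.164, tolerance = 1e-3)
  expect_equal(round(half_life(0.219), 1), 3.2)
  expect_identical(half_life(0.693), 1)
  expect_equal(half_life(0.112), 6.19, tolerance = 1e-3)
  expect_error(half_life(0), "positive")
})

test_that("Cmax/Tmax report the observed maximum, earliest on ties", {
  peak <- cmax_tmax(make_profile(c(2, 6.2, 30, 120) / 60,
                                 c(900, 1571, 1200, 400)))
  expect_equal(peak$c_max_ng_ml, 1571)
  expect_equal(peak$t_max_min, 6.2)
  single <- cmax_tmax(make_profile(5 / 60, 10))
  expect_equal(single$c_max_ng_ml, 10)
  expect_equal(single$t_max_min, 5)
  tie <- cmax_tmax(make_profile(c(5, 10, 20) / 60, c(100, 100, 50)))
  expect_equal(tie$t_max_min, 5)
  expect_error(cmax_tmax(make_profile(c(0, 1), c(NA, NA),
                                      analyte = "metabolite")),
               "insufficient")
})

test_that("AUC extrapolation adds the terminal tail", {
  expect_equal(extrapolate_auc(7307.1, 13.5, 0.219), 7368.7,
               tolerance = 1e-4)
  expect_equal(extrapolate_auc(100, 10, 0.5), 120)
  expect_equal(extrapolate_auc(100, 1e-12, 0.5), 100, tolerance = 1e-10)
  expect_error(extrapolate_auc(100, 0, 0.5), "positive")
  expect_error(extrapolate_auc(100, 10, 0), "positive")
})

test_that("dose normalization is linear scaling to the reference dose", {
  expect_equal(normalize_auc(7368.8, 100), 12821.7, tolerance = 1e-5)
  expect_identical(normalize_auc(5000, 174), 5000)
  expect_equal(normalize_auc(1000, 348), 500)
  expect_error(normalize_auc(1000, 0), "positive")
})

test_that("clearance converts dose over AUC to ml/min", {
  expect_equal(clearance(6, 1e6), 0.1)
  expect_equal(clearance(174, 6440.6), 450.2, tolerance = 1e-3)
  expect_equal(clearance(348, 6440.6), 2 * clearance(174, 6440.6))
  expect_error(clearance(0, 100), "positive")
})

test_that("bioavailability is the percent ratio of normalized exposures", {
  expect_identical(bioavailability(5000, 5000), 100)
  expect_equal(bioavailability(12821.72, 6330.76), 202.5, tolerance = 1e-3)
  expect_equal(bioavailability(2, 1), 200)
  expect_error(bioavailability(-1, 1), "positive")
})

test_that("summary statistics use the sample SD and CV% conventions", {
  s <- summary_stat(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$cv_percent, 50)
  one <- summary_stat(5)
  expect_equal(one$sd, 0)
  expect_equal(one$cv_percent, 0)
  expect_equal(100 * 2129.28 / 7307.10, 29.14, tolerance = 1e-3)
  expect_error(summary_stat(numeric(0)), "at least one")
})

test_that("full NCA composes all parameters on clean simulated data", {
  dp <- disposition_params()
  times <- default_schedule("iv_infusion")
  conc <- simulate_iv(dp, 174, 1, times)
  p <- make_profile(times, conc, phase = "primary_iv", dose_mg = 174,
                    infusion_duration_h = 1)
  res <- run_nca(p)
  expect_length(res$flags, 0)
  expect_true(all(is.finite(c(res$auc_0_t_ng_h_ml, res$auc_0_inf_ng_h_ml,
                              res$n_auc_0_inf_ng_h_ml, res$t_half_h,
                              res$c_max_ng_ml, res$t_max_min,
                              res$clearance_ml_min))))
  # exposure and clearance are close to the generating model, up to the
  # during-infusion exposure that the post-infusion clock cannot observe
  expect_equal(res$clearance_ml_min, 460, tolerance = 0.10)
  expect_lt(res$extrapolated_fraction, 0.2)
  expect_equal(res$t_max_min, 0)  # end of infusion is the observed peak
})

test_that("full NCA degrades gracefully: all-BLOQ profiles flag everything", {
  p <- make_profile(c(0, 1, 2), c(NA, NA, NA), analyte = "metabolite")
  res <- run_nca(p)
  expect_true(all(is.na(c(res$auc_0_t_ng_h_ml, res$auc_0_inf_ng_h_ml,
                          res$t_half_h, res$c_max_ng_ml))))
  expect_true(length(res$flags) > 0)
})

test_that("half-life identity holds through the full fit chain", {
  for (k in c(0.1, 0.219, 0.4)) {
    fit <- fit_terminal_slope(mono_exp_profile(k))
    expect_equal(half_life(fit$k_per_h), 0.693 / k, tolerance = 1e-8)
  }
})
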