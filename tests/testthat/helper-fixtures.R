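# Shared builders and frozen printed values used across the suite.

# quick profile: bloq wherever conc is NA
make_profile <- function(time_h, conc, phase = "primary_embolization",
                         analyte = "parent", dose_mg = 100,
                         infusion_duration_h = NULL) {
  if (is.null(infusion_duration_h) && grepl("_iv$", phase))
    infusion_duration_h <- 1
  pk_profile("s1", phase, analyte, dose_mg,
             data.frame(time_h = time_h, conc_ng_ml = conc,
                        bloq = is.na(conc)),
             infusion_duration_h = infusion_duration_h)
}

# noise-free mono-exponential decline
mono_exp_profile <- function(k, c0 = 1000, times = c(0, 1, 2, 4, 8, 12, 16),
                             ...) {
  make_profile(times, c0 * exp(-k * times), ...)
}

# IV dosing table: weight (kg), intensity (mg/m2), printed dose (mg)
table3_doses <- data.frame(
  weight_kg = c(31.0, 37.5, 31.0, 40.0, 30.0, 36.5, 32.0, 45.5, 33.5, 43.5,
                32.5, 39.5, 30.5, 38.5),
  dose_per_m2 = c(rep(250, 12), 350, 350),
  printed_mg = c(174.6, 197.8, 174.6, 206.3, 170.9, 194.3, 178.2, 224.5,
                 183.7, 218.0, 180.1, 204.6, 241.8, 281.7))

# grouped parameter table: printed mean, SD and CV% per phase and parameter
table4_rows <- data.frame(
  phase = c(rep("1E", 6), rep("2E", 6), rep("1IV", 5), rep("2IV", 5)),
  parameter = c("Dose", "k", "AUC0t", "nAUC", "CLF", "F",
                "Dose", "k", "AUC0t", "nAUC", "CLF", "F",
                "Dose", "k", "AUC0t", "nAUC", "CL",
                "Dose", "k", "AUC0t", "nAUC", "CL"),
  mean = c(100, 0.219, 7307.10, 12821.72, 240.22, 205.54,
           100, 0.204, 6724.38, 11838.92, 266.41, 219.06,
           177.02, 0.112, 6345.13, 6330.76, 494.76,
           207.58, 0.143, 6309.65, 5427.57, 580.44),
  sd = c(0, 0.026, 2129.28, 3714.94, 60.38, 18.72,
         0, 0.038, 2351.96, 4130.29, 75.94, 22.85,
         4.58, 0.016, 2374.00, 2264.09, 127.70,
         11.64, 0.044, 2047.31, 1909.68, 162.27),
  cv = c(0, 12.09, 29.14, 28.97, 25.13, 9.11,
         0, 18.62, 34.98, 34.89, 28.51, 10.43,
         2.58, 14.04, 37.41, 35.76, 25.81,
         5.61, 30.54, 32.45, 35.18, 27.96))

# decimals carried by the printed mean and SD (for rounding-propagation
# bounds on the CV% recomputation)
table4_rows$mean_dp <- c(0, 3, 2, 2, 2, 2, 0, 3, 2, 2, 2, 2,
                         2, 3, 2, 2, 2, 2, 3, 2, 2, 2)
table4_rows$sd_dp <- table4_rows$mean_dp

# random piecewise-linear profile plus its exact integral computed from the
# antiderivative of each linear segment (an algebraically different route
# from the trapezoid sum)
random_piecewise_linear <- function(n_points = sample(3:12, 1)) {
  t <- sort(runif(n_points, 0, 24))
  while (any(diff(t) == 0)) t <- sort(runif(n_points, 0, 24))
  conc <- runif(n_points, 0, 5000)
  # midpoint rule, exact for a linear segment and free of the cancellation
  # the shifted-antiderivative form suffers at large times
  segment_integral <- function(t1, t2, c1, c2) {
    (t2 - t1) * (c1 + (c2 - c1) / 2)
  }
  exact <- sum(mapply(segment_integral, head(t, -1), tail(t, -1),
                      head(conc, -1), tail(conc, -1)))
  list(profile = make_profile(t, conc), exact = exact)
}

# during-infusion exposure of the IV simulator, by quadrature through the
# public API: the concentration u hours into an infusion of duration td at
# rate dose/td equals the end-of-infusion concentration of a u-long infusion
# at the same rate.
auc_during_infusion <- function(params, dose_mg, td) {
  f <- Vectorize(function(u) simulate_iv(params, dose_mg * u / td, u, 0))
  stats::integrate(f, 0, td, rel.tol = 1e-9)$value
}
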