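# Non-compartmental analysis of a single concentration-time profile, and the
# cross-route bioavailability / clearance quantities built on it.
#
# Conventions, mirroring the source study's analysis:
#   * AUC by the linear trapezoid rule over the quantifiable span.
#   * Terminal rate constant from least squares of log10 concentration vs
#     time; beta = slope * (-2.303); k = beta; T1/2 = 0.693 / k. The printed
#     constants 2.303 and 0.693 are used as written; the log10 slope is
#     defined as slope_ln / 2.303 so that the constant pair is self-inverse
#     and noise-free mono-exponential data are recovered exactly.
#   * AUC(0-inf) = AUC(0-t) + Clast/k; nAUC scales linearly to a reference
#     dose (174 mg); F = 100 * nAUC(bead)/nAUC(IV); CL = dose/AUC(0-inf)
#     (apparent CL/F for the bead route).
#
# BLOQ handling (the study reports no rule; this one is conservative and
# documented): censored points before the first quantifiable sample enter the
# AUC as zero concentration; censored points after it are excluded from both
# the AUC span and the terminal fit. No imputation.

log10_constant <- 2.303
half_life_constant <- 0.693

# Quantifiable series with leading-BLOQ points as zeros. Returns a data.frame
# (time_h, conc_ng_ml, lead) where lead marks substituted leading zeros.
quantifiable_series <- function(p) {
  pts <- p$points
  qi <- which(!pts$bloq)
  if (length(qi) == 0)
    return(data.frame(time_h = numeric(0), conc_ng_ml = numeric(0),
                      lead = logical(0)))
  lead <- which(pts$bloq & pts$time_h < pts$time_h[qi[1]])
  out <- rbind(
    data.frame(time_h = pts$time_h[lead],
               conc_ng_ml = rep(0, length(lead)),
               lead = rep(TRUE, length(lead))),
    data.frame(time_h = pts$time_h[qi], conc_ng_ml = pts$conc_ng_ml[qi],
               lead = FALSE))
  out[order(out$time_h), ]
}

#' Area under the curve by the linear trapezoid rule
#'
#' Sum of `(t[i+1] - t[i]) * (C[i] + C[i+1]) / 2` over the quantifiable span
#' of the profile, ending at the last quantifiable time. Censored points ahead
#' of the first quantifiable sample contribute zero concentration; censored
#' points inside or after the span are excluded.
#'
#' @param profile A [pk_profile()].
#' @return AUC(0-t) in ng h/ml.
#' @export
auc_trapezoid <- function(profile) {
  validate_pk_profile(profile)
  s <- quantifiable_series(profile)
  if (sum(!s$lead) < 1 || nrow(s) < 2)
    stop("insufficient data: need at least 2 usable points for AUC",
         call. = FALSE)
  sum(diff(s$time_h) * (utils::head(s$conc_ng_ml, -1) +
                        utils::tail(s$conc_ng_ml, -1)) / 2)
}

#' Terminal-window selection policy
#'
#' The study does not state how terminal windows were chosen. The default
#' policy follows standard lambda-z practice: among candidate windows formed
#' by the last m quantifiable points (m = `min_points` ... all points strictly
#' after Tmax), take the fit with the highest adjusted R-squared, preferring
#' the longer window on ties (within 1e-4). An explicit time `window`
#' (`c(t_first, t_last)`, hours) overrides the search.
#'
#' @param min_points Smallest window size (default 3).
#' @param window Optional explicit `c(t_first, t_last)` in hours.
#' @return A `lambda_z_policy` list.
#' @export
lambda_z_policy <- function(min_points = 3, window = NULL) {
  stopifnot(min_points >= 3)
  structure(list(min_points = min_points, window = window),
            class = "lambda_z_policy")
}

terminal_fit <- function(slope_ln, r_squared, n_points, t_first, t_last,
                         accepted, flags = character(0)) {
  structure(list(
    slope_log10_per_h = slope_ln / log10_constant,
    beta_per_h = -slope_ln,
    k_per_h = -slope_ln,
    r_squared = r_squared, n_points = n_points,
    t_first_h = t_first, t_last_h = t_last,
    accepted = accepted, flags = flags), class = "terminal_fit")
}

# Least squares of ln(conc) on time; returns slope, intercept, r2, adj r2.
ln_ols <- function(time_h, conc) {
  y <- log(conc)
  n <- length(y)
  sxx <- sum((time_h - mean(time_h))^2)
  slope <- sum((time_h - mean(time_h)) * (y - mean(y))) / sxx
  resid <- y - mean(y) - slope * (time_h - mean(time_h))
  syy <- sum((y - mean(y))^2)
  r2 <- if (syy == 0) 0 else 1 - sum(resid^2) / syy
  list(slope = slope, r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2))
}

#' Fit the terminal log-linear slope
#'
#' Ordinary least squares of log10 concentration against time over the
#' selected terminal window (see [lambda_z_policy()]); the terminal rate
#' constant is `k = beta = slope * (-2.303)`. Windows start strictly after
#' Tmax. A non-negative slope is rejected and flagged rather than returned as
#' a rate constant.
#'
#' @param profile A [pk_profile()].
#' @param policy A [lambda_z_policy()].
#' @return A `terminal_fit` with fields `slope_log10_per_h`, `beta_per_h`,
#'   `k_per_h`, `r_squared`, `n_points`, `t_first_h`, `t_last_h`, `accepted`,
#'   `flags`.
#' @export
fit_terminal_slope <- function(profile, policy = lambda_z_policy()) {
  validate_pk_profile(profile)
  pts <- profile$points[!profile$points$bloq, ]
  if (!is.null(policy$window)) {
    w <- pts[pts$time_h >= policy$window[1] & pts$time_h <= policy$window[2], ]
    if (nrow(w) < policy$min_points)
      stop("insufficient data: fewer than ", policy$min_points,
           " quantifiable points in the requested window", call. = FALSE)
    f <- ln_ols(w$time_h, w$conc_ng_ml)
    ok <- f$slope < 0
    return(terminal_fit(f$slope, f$r2, nrow(w), min(w$time_h), max(w$time_h),
                        accepted = ok,
                        flags = if (ok) character(0)
                                else "terminal_slope_not_negative"))
  }
  i_max <- which.max(pts$conc_ng_ml)  # ties resolved to the earliest maximum
  tail_pts <- pts[pts$time_h > pts$time_h[i_max], ]
  n <- nrow(tail_pts)
  if (n < policy$min_points)
    stop("insufficient data: need at least ", policy$min_points,
         " quantifiable points after Cmax for the terminal fit",
         call. = FALSE)
  best <- NULL
  best_adj <- -Inf
  rejected_only <- TRUE
  for (m in policy$min_points:n) {
    w <- tail_pts[(n - m + 1):n, ]
    f <- ln_ols(w$time_h, w$conc_ng_ml)
    if (f$slope >= 0) next
    rejected_only <- FALSE
    if (f$adj_r2 > best_adj + 1e-4 ||
        (f$adj_r2 > best_adj - 1e-4 && m > best$n)) {
      best_adj <- f$adj_r2
      best <- list(f = f, n = m, t1 = min(w$time_h), t2 = max(w$time_h))
    }
  }
  if (rejected_only) {
    w <- tail_pts
    f <- ln_ols(w$time_h, w$conc_ng_ml)
    return(terminal_fit(f$slope, f$r2, n, min(w$time_h), max(w$time_h),
                        accepted = FALSE,
                        flags = "terminal_slope_not_negative"))
  }
  terminal_fit(best$f$slope, best$f$r2, best$n, best$t1, best$t2,
               accepted = TRUE)
}

#' Terminal half-life from a rate constant
#'
#' `0.693 / k`, with the printed constant.
#'
#' @param k_per_h Terminal rate constant in 1/h (> 0).
#' @return Half-life in hours.
#' @examples
#' half_life(0.219)  # 3.16 h, reported as 3.2
#' @export
half_life <- function(k_per_h) {
  if (any(!is.finite(k_per_h) | k_per_h <= 0))
    stop("k_per_h must be positive", call. = FALSE)
  half_life_constant / k_per_h
}

#' Observed maximum concentration and its time
#'
#' The maximum quantifiable concentration and its time converted to minutes,
#' ties resolved to the earliest time (the study obtained these by visual
#' inspection of the data).
#'
#' @param profile A [pk_profile()].
#' @return List with `c_max_ng_ml` and `t_max_min`.
#' @export
cmax_tmax <- function(profile) {
  validate_pk_profile(profile)
  pts <- profile$points[!profile$points$bloq, ]
  if (nrow(pts) == 0)
    stop("insufficient data: no quantifiable points", call. = FALSE)
  i <- which.max(pts$conc_ng_ml)
  list(c_max_ng_ml = pts$conc_ng_ml[i], t_max_min = pts$time_h[i] * 60)
}

#' Extrapolate AUC to infinite time
#'
#' `AUC(0-inf) = AUC(0-t) + Clast / k`, the standard completion of the
#' observed exposure with the terminal mono-exponential tail.
#'
#' @param auc_0_t AUC to the last quantifiable time (ng h/ml).
#' @param c_last Last quantifiable concentration (ng/ml, > 0).
#' @param k_per_h Terminal rate constant (1/h, > 0).
#' @return AUC(0-inf) in ng h/ml.
#' @export
extrapolate_auc <- function(auc_0_t, c_last, k_per_h) {
  if (!is.finite(c_last) || c_last <= 0)
    stop("c_last must be positive", call. = FALSE)
  if (!is.finite(k_per_h) || k_per_h <= 0)
    stop("k_per_h must be positive", call. = FALSE)
  auc_0_t + c_last / k_per_h
}

#' Dose-normalized AUC
#'
#' Rescales AUC(0-inf) linearly to a reference dose (174 mg by default, the
#' 250 mg/m2 dose of a nominal typical animal), so that routes given at
#' different absolute doses are comparable.
#'
#' @param auc_0_inf AUC(0-inf) in ng h/ml.
#' @param dose_mg Administered dose in mg (> 0).
#' @param reference_dose_mg Reference dose in mg (default 174).
#' @return nAUC(0-inf) in ng h/ml.
#' @export
normalize_auc <- function(auc_0_inf, dose_mg, reference_dose_mg = 174) {
  if (any(!is.finite(dose_mg) | dose_mg <= 0))
    stop("dose_mg must be positive", call. = FALSE)
  auc_0_inf * reference_dose_mg / dose_mg
}

#' Clearance from dose and total exposure
#'
#' `CL = dose / AUC(0-inf)`, converted to ml/min. For the bead route, where
#' the absorbed fraction is folded into the exposure, this is the apparent
#' clearance CL/F.
#'
#' @param dose_mg Absolute dose in mg (> 0).
#' @param auc_0_inf_ng_h_ml AUC(0-inf) in ng h/ml (> 0).
#' @return Clearance in ml/min.
#' @examples
#' clearance(174, 6440.6)  # 450.2 ml/min
#' @export
clearance <- function(dose_mg, auc_0_inf_ng_h_ml) {
  if (any(!is.finite(dose_mg) | dose_mg <= 0) ||
      any(!is.finite(auc_0_inf_ng_h_ml) | auc_0_inf_ng_h_ml <= 0))
    stop("dose and AUC must be positive", call. = FALSE)
  dose_mg * 1e6 / auc_0_inf_ng_h_ml / 60
}

#' Bioavailability as a ratio of dose-normalized exposures
#'
#' `F = 100 * nAUC(bead) / nAUC(IV)`, in percent. Computed per subject and
#' then summarized across subjects (mean of ratios), with the ratio of group
#' means reported alongside; the two differ whenever exposures vary between
#' subjects.
#'
#' @param n_auc_bead,n_auc_iv Dose-normalized AUC(0-inf) values (> 0).
#' @return F in percent.
#' @export
bioavailability <- function(n_auc_bead, n_auc_iv) {
  if (any(!is.finite(n_auc_bead) | n_auc_bead <= 0) ||
      any(!is.finite(n_auc_iv) | n_auc_iv <= 0))
    stop("normalized AUCs must be positive", call. = FALSE)
  100 * n_auc_bead / n_auc_iv
}

#' Mean, SD, CV% and n of a parameter across subjects
#'
#' Arithmetic mean, sample standard deviation (n-1 denominator, zero for a
#' single value) and CV% = 100 * SD / mean.
#'
#' @param values Numeric vector (length >= 1, NAs dropped).
#' @return A `summary_stat` list with `mean`, `sd`, `cv_percent`, `n`.
#' @export
summary_stat <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1) stop("summary_stat needs at least one value", call. = FALSE)
  m <- mean(values)
  s <- if (n == 1) 0 else stats::sd(values)
  structure(list(mean = m, sd = s,
                 cv_percent = if (m != 0) 100 * s / m else NA_real_,
                 n = n), class = "summary_stat")
}

#' Full non-compartmental analysis of one profile
#'
#' Composes the individual estimators with "where possible" semantics: any
#' parameter whose preconditions fail is returned as `NA` with an explanatory
#' flag, without aborting the remaining parameters. Only a profile with no
#' quantifiable points yields an all-`NA` result.
#'
#' @param profile A [pk_profile()].
#' @param config A [run_config()]; supplies the reference dose and the
#'   lambda-z policy.
#' @return An `nca_result` list: `auc_0_t_ng_h_ml`, `auc_0_inf_ng_h_ml`,
#'   `n_auc_0_inf_ng_h_ml`, `extrapolated_fraction`, `t_half_h`,
#'   `c_max_ng_ml`, `t_max_min`, `clearance_ml_min` (CL for the IV route,
#'   CL/F for beads), `terminal` (the [fit_terminal_slope()] result or
#'   `NULL`), and `flags`.
#' @export
run_nca <- function(profile, config = run_config()) {
  validate_pk_profile(profile)
  flags <- character(0)
  res <- list(subject_id = profile$subject_id, phase = profile$phase,
              route = profile$route, analyte = profile$analyte,
              dose_mg = profile$dose_mg,
              auc_0_t_ng_h_ml = NA_real_, auc_0_inf_ng_h_ml = NA_real_,
              n_auc_0_inf_ng_h_ml = NA_real_,
              extrapolated_fraction = NA_real_,
              t_half_h = NA_real_, c_max_ng_ml = NA_real_,
              t_max_min = NA_real_, clearance_ml_min = NA_real_,
              terminal = NULL, flags = character(0))

  grab <- function(expr, flag) {
    tryCatch(expr, error = function(e) {
      flags <<- c(flags, flag)
      NULL
    })
  }

  peak <- grab(cmax_tmax(profile), "no_quantifiable_data")
  if (!is.null(peak)) {
    res$c_max_ng_ml <- peak$c_max_ng_ml
    res$t_max_min <- peak$t_max_min
  }
  auc <- grab(auc_trapezoid(profile), "insufficient_points_for_auc")
  if (!is.null(auc)) res$auc_0_t_ng_h_ml <- auc

  fit <- grab(fit_terminal_slope(profile, config$lambda_z),
              "insufficient_points_for_terminal_fit")
  if (!is.null(fit)) {
    res$terminal <- fit
    flags <- c(flags, fit$flags)
    if (fit$accepted) res$t_half_h <- half_life(fit$k_per_h)
  }

  if (!is.null(auc) && !is.null(fit) && isTRUE(fit$accepted)) {
    q <- profile$points[!profile$points$bloq, ]
    c_last <- q$conc_ng_ml[nrow(q)]
    if (c_last > 0) {
      res$auc_0_inf_ng_h_ml <- extrapolate_auc(auc, c_last, fit$k_per_h)
      res$extrapolated_fraction <-
        (res$auc_0_inf_ng_h_ml - auc) / res$auc_0_inf_ng_h_ml
      if (res$extrapolated_fraction > 0.2)
        flags <- c(flags, "high_extrapolation")
      res$n_auc_0_inf_ng_h_ml <- normalize_auc(
        res$auc_0_inf_ng_h_ml, profile$dose_mg, config$reference_dose_mg)
      res$clearance_ml_min <- clearance(profile$dose_mg,
                                        res$auc_0_inf_ng_h_ml)
    } else {
      flags <- c(flags, "last_quantifiable_concentration_zero")
    }
  }
  res$flags <- unique(flags)
  class(res) <- "nca_result"
  res
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> %s / %s / %s\n", x$subject_id, x$phase, x$analyte))
  cat(sprintf("  AUC0-t %.2f  AUC0-inf %.2f  nAUC0-inf %.2f ng h/ml\n",
              x$auc_0_t_ng_h_ml, x$auc_0_inf_ng_h_ml, x$n_auc_0_inf_ng_h_ml))
  cat(sprintf("  k %.3f /h  T1/2 %.1f h  Cmax %.1f ng/ml  Tmax %.1f min  %s %.1f ml/min\n",
              if (is.null(x$terminal)) NA_real_ else x$terminal$k_per_h,
              x$t_half_h, x$c_max_ng_ml, x$t_max_min,
              if (x$route == "iv_infusion") "CL" else "CL/F",
              x$clearance_ml_min))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
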