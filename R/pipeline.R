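# End-to-end study analysis: per-profile NCA, subject-level bioavailability,
# and grouped summary tables shaped like the study's reporting (a parameter
# table per phase with Dose, k, AUC0-t, nAUC0-inf, CL or CL/F and F, and a
# key-PK table per phase and analyte with AUC, T1/2, Cmax, Tmax).
#
# Bioavailability is reported under both conventions: the mean of per-subject
# ratios (the convention the study's printed F values follow, labelled
# "as published") and the ratio of group-mean normalized exposures. The two
# differ whenever exposures vary across subjects.

#' Run configuration for the analysis pipeline
#'
#' @param reference_dose_mg Reference dose for AUC normalization
#'   (default 174 mg).
#' @param lambda_z A [lambda_z_policy()].
#' @param lloq_parent_ng_ml,lloq_metabolite_ng_ml Assay limits recorded with
#'   the run (informational; censoring is a property of the data).
#' @param seed Seed recorded for any resampling step.
#' @return A `run_config` list.
#' @export
run_config <- function(reference_dose_mg = 174,
                       lambda_z = lambda_z_policy(),
                       lloq_parent_ng_ml = NA_real_,
                       lloq_metabolite_ng_ml = NA_real_,
                       seed = NULL) {
  if (!is.finite(reference_dose_mg) || reference_dose_mg <= 0)
    stop("reference_dose_mg must be positive", call. = FALSE)
  structure(list(reference_dose_mg = reference_dose_mg,
                 lambda_z = lambda_z,
                 lloq_parent_ng_ml = lloq_parent_ng_ml,
                 lloq_metabolite_ng_ml = lloq_metabolite_ng_ml,
                 seed = seed),
            class = "run_config")
}

nca_results_frame <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(subject = r$subject_id, phase = r$phase, route = r$route,
               analyte = r$analyte, dose_mg = r$dose_mg,
               auc_0_t_ng_h_ml = r$auc_0_t_ng_h_ml,
               auc_0_inf_ng_h_ml = r$auc_0_inf_ng_h_ml,
               n_auc_0_inf_ng_h_ml = r$n_auc_0_inf_ng_h_ml,
               extrapolated_fraction = r$extrapolated_fraction,
               k_per_h = if (!is.null(r$terminal) && r$terminal$accepted)
                 r$terminal$k_per_h else NA_real_,
               t_half_h = r$t_half_h, c_max_ng_ml = r$c_max_ng_ml,
               t_max_min = r$t_max_min,
               clearance_ml_min = r$clearance_ml_min,
               flags = paste(r$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

stat_row <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0)
    return(data.frame(mean = NA_real_, sd = NA_real_, cv_percent = NA_real_,
                      n = 0L))
  s <- summary_stat(v)
  data.frame(mean = s$mean, sd = s$sd, cv_percent = s$cv_percent, n = s$n)
}

#' Analyse a complete study
#'
#' Runs [run_nca()] on every profile, pairs the bead and IV phases of each
#' subject and cycle to compute per-subject bioavailability, and assembles
#' grouped summary tables. Profiles or pairings that fail the "where
#' possible" preconditions are excluded from the affected summaries and
#' listed with reasons; they never abort the run.
#'
#' @param profiles List of [pk_profile()] objects.
#' @param dose_records Optional [dose_records()] frame; used to cross-check
#'   profile doses when supplied.
#' @param config A [run_config()].
#' @return A `study_report` list: `per_profile` (NCA results frame),
#'   `bioavailability` (per subject x cycle F), `f_summary` (both
#'   conventions), `parameter_summary` (phase-level table for the parent
#'   drug), `key_pk_summary` (phase x analyte table), `exclusions`.
#' @export
analyze_study <- function(profiles, dose_records = NULL,
                          config = run_config()) {
  stopifnot(is.list(profiles))
  if (length(profiles) == 0) {
    warning("empty study: nothing to analyse")
    return(structure(list(per_profile = NULL, bioavailability = NULL,
                          f_summary = NULL, parameter_summary = NULL,
                          key_pk_summary = NULL,
                          exclusions = data.frame()),
                     class = "study_report"))
  }
  results <- lapply(profiles, run_nca, config = config)
  per_profile <- nca_results_frame(results)

  exclusions <- per_profile[per_profile$flags != "",
                            c("subject", "phase", "analyte", "flags")]
  names(exclusions)[4] <- "reason"

  # per-subject bioavailability, parent analyte, per cycle
  parent <- per_profile[per_profile$analyte == "parent", ]
  bio <- list()
  for (cycle in c("primary", "secondary")) {
    bead <- parent[parent$phase == paste0(cycle, "_embolization"), ]
    iv <- parent[parent$phase == paste0(cycle, "_iv"), ]
    subjects <- union(bead$subject, iv$subject)
    for (s in subjects) {
      nb <- bead$n_auc_0_inf_ng_h_ml[bead$subject == s]
      ni <- iv$n_auc_0_inf_ng_h_ml[iv$subject == s]
      if (length(nb) != 1 || length(ni) != 1) {
        warning("subject ", s, " lacks a matching ", cycle,
                " bead/IV phase pair; excluded from bioavailability")
        bio[[length(bio) + 1]] <- data.frame(
          subject = s, cycle = cycle, f_percent = NA_real_,
          note = "unpaired_phase", stringsAsFactors = FALSE)
      } else if (is.na(nb) || is.na(ni)) {
        bio[[length(bio) + 1]] <- data.frame(
          subject = s, cycle = cycle, f_percent = NA_real_,
          note = "normalized_auc_unavailable", stringsAsFactors = FALSE)
      } else {
        bio[[length(bio) + 1]] <- data.frame(
          subject = s, cycle = cycle,
          f_percent = bioavailability(nb, ni), note = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  bio <- if (length(bio)) do.call(rbind, bio) else
    data.frame(subject = character(0), cycle = character(0),
               f_percent = numeric(0), note = character(0))

  f_summary <- do.call(rbind, lapply(
    c("primary", "secondary", "pooled"), function(cycle) {
      fv <- if (cycle == "pooled") bio$f_percent
            else bio$f_percent[bio$cycle == cycle]
      mr <- stat_row(fv)
      nb <- if (cycle == "pooled") parent$n_auc_0_inf_ng_h_ml[
        parent$route == "bead_intraarterial"]
        else parent$n_auc_0_inf_ng_h_ml[
          parent$phase == paste0(cycle, "_embolization")]
      ni <- if (cycle == "pooled") parent$n_auc_0_inf_ng_h_ml[
        parent$route == "iv_infusion"]
        else parent$n_auc_0_inf_ng_h_ml[parent$phase == paste0(cycle, "_iv")]
      rom <- if (any(is.finite(nb)) && any(is.finite(ni)))
        100 * mean(nb, na.rm = TRUE) / mean(ni, na.rm = TRUE) else NA_real_
      data.frame(cycle = cycle,
                 f_mean_of_ratios_percent = mr$mean,
                 f_sd_percent = mr$sd, n = mr$n,
                 f_ratio_of_means_percent = rom,
                 convention_note =
                   "mean_of_ratios is the as-published convention",
                 stringsAsFactors = FALSE)
    }))

  # phase-level parameter summary (parent analyte), one row per parameter
  parameter_summary <- do.call(rbind, lapply(pk_phases, function(ph) {
    g <- parent[parent$phase == ph, ]
    if (nrow(g) == 0) return(NULL)
    is_iv <- phase_route(ph) == "iv_infusion"
    cyc <- phase_cycle(ph)
    rows <- list(
      Dose = g$dose_mg, k = g$k_per_h, `AUC_0-t` = g$auc_0_t_ng_h_ml,
      `nAUC_0-inf` = g$n_auc_0_inf_ng_h_ml)
    rows[[if (is_iv) "CL" else "CL/F"]] <- g$clearance_ml_min
    if (!is_iv) rows$F <- bio$f_percent[bio$cycle == cyc]
    units <- c(Dose = "mg", k = "/h", `AUC_0-t` = "ng h/ml",
               `nAUC_0-inf` = "ng h/ml", CL = "ml/min", `CL/F` = "ml/min",
               F = "%")
    do.call(rbind, lapply(names(rows), function(nm) {
      cbind(data.frame(phase = ph, parameter = nm,
                       stringsAsFactors = FALSE),
            stat_row(rows[[nm]]),
            data.frame(units = unname(units[nm]),
                       stringsAsFactors = FALSE))
    }))
  }))

  # key PK table per phase and analyte: AUC, T1/2, Cmax, Tmax
  combos <- expand.grid(analyte = pk_analytes, phase = pk_phases,
                        stringsAsFactors = FALSE)
  key_pk_summary <- do.call(rbind, lapply(seq_len(nrow(combos)), function(j) {
    g <- per_profile[per_profile$phase == combos$phase[j] &
                     per_profile$analyte == combos$analyte[j], ]
    if (nrow(g) == 0) return(NULL)
    vals <- list(`AUC_ng_h_ml` = g$auc_0_t_ng_h_ml, `T_half_h` = g$t_half_h,
                 `Cmax_ng_ml` = g$c_max_ng_ml, `Tmax_min` = g$t_max_min)
    do.call(rbind, lapply(names(vals), function(nm) {
      cbind(data.frame(analyte = combos$analyte[j], phase = combos$phase[j],
                       parameter = nm, stringsAsFactors = FALSE),
            stat_row(vals[[nm]]))
    }))
  }))

  structure(list(per_profile = per_profile, bioavailability = bio,
                 f_summary = f_summary, parameter_summary = parameter_summary,
                 key_pk_summary = key_pk_summary, exclusions = exclusions,
                 config = config),
            class = "study_report")
}

# reporting rounds, matching the study's printed precision
round_parameter <- function(parameter, x) {
  digits <- c(Dose = 1, k = 3, `AUC_0-t` = 2, `nAUC_0-inf` = 2, CL = 2,
              `CL/F` = 2, F = 2, AUC_ng_h_ml = 2, T_half_h = 1,
              Cmax_ng_ml = 1, Tmax_min = 1)
  d <- digits[parameter]
  d[is.na(d)] <- 2
  round(x, unname(d))
}

#' Write a study report to CSV files
#'
#' Emits `per_profile.csv` (full precision), `parameter_summary.csv` and
#' `key_pk_summary.csv` (rounded to the reported precision: doses 1 decimal,
#' k 3, AUCs and clearances 2, half-lives, Cmax and Tmax 1),
#' `bioavailability.csv` and `exclusions.csv`. Regenerating from the same
#' inputs gives identical files.
#'
#' @param report A `study_report` from [analyze_study()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                         row.names = FALSE)
  if (!is.null(report$per_profile)) out(report$per_profile,
                                        "per_profile.csv")
  if (!is.null(report$parameter_summary)) {
    ps <- report$parameter_summary
    for (col in c("mean", "sd")) ps[[col]] <- round_parameter(ps$parameter,
                                                              ps[[col]])
    ps$cv_percent <- round(ps$cv_percent, 2)
    out(ps, "parameter_summary.csv")
  }
  if (!is.null(report$key_pk_summary)) {
    ks <- report$key_pk_summary
    for (col in c("mean", "sd")) ks[[col]] <- round_parameter(ks$parameter,
                                                              ks[[col]])
    ks$cv_percent <- round(ks$cv_percent, 2)
    out(ks, "key_pk_summary.csv")
  }
  if (!is.null(report$bioavailability)) out(report$bioavailability,
                                            "bioavailability.csv")
  out(report$exclusions, "exclusions.csv")
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  if (is.null(x$per_profile)) {
    cat("  (empty study)\n")
    return(invisible(x))
  }
  cat(sprintf("  %d profiles analysed, %d exclusions\n",
              nrow(x$per_profile), nrow(x$exclusions)))
  if (!is.null(x$f_summary)) {
    fp <- x$f_summary[x$f_summary$cycle == "pooled", ]
    cat(sprintf("  F (mean of ratios): %.1f %% (n=%d); ratio of means: %.1f %%\n",
                fp$f_mean_of_ratios_percent, fp$n,
                fp$f_ratio_of_means_percent))
  }
  invisible(x)
}

#' Plot a concentration-time profile
#'
#' Linear time, log concentration (the style of the study's figures). BLOQ
#' points are omitted.
#'
#' @param x A [pk_profile()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pk_profile <- function(x, ...) {
  pts <- x$points[!x$points$bloq, ]
  if (nrow(pts) == 0) stop("no quantifiable points to plot", call. = FALSE)
  graphics::plot(pts$time_h, pts$conc_ng_ml, log = "y", type = "b", pch = 16,
                 xlab = "time since completion of administration (h)",
                 ylab = "concentration (ng/ml)",
                 main = sprintf("%s / %s / %s", x$subject_id, x$phase,
                                x$analyte), ...)
  invisible(x)
}
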