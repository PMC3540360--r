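# Data model and I/O for concentration-time profiles and dosing records.
#
# The sampling clock: time 0 is the completion of administration (end of
# embolization for the bead route, end of infusion for the IV route). All
# scheduled offsets in the source study are relative to that instant, which is
# why IV Tmax values of under a minute are coherent. Times are stored in hours;
# minute-denominated input is converted on read (division by 60, no rounding).

#' Phase, route and analyte vocabularies
#'
#' The study design crosses two delivery routes (intra-arterial drug-eluting
#' beads, intravenous infusion) with two treatment cycles (primary, secondary)
#' and two analytes (the parent drug and its circulating metabolite, present at
#' roughly thousand-fold lower exposure).
#'
#' @name vocabularies
#' @keywords internal
NULL

pk_phases <- c("primary_embolization", "secondary_embolization",
               "primary_iv", "secondary_iv")
pk_routes <- c("bead_intraarterial", "iv_infusion")
pk_analytes <- c("parent", "metabolite")

#' Route implied by a phase label
#'
#' @param phase One of `"primary_embolization"`, `"secondary_embolization"`,
#'   `"primary_iv"`, `"secondary_iv"`.
#' @return `"bead_intraarterial"` for embolization phases, `"iv_infusion"` for
#'   IV phases.
#' @export
phase_route <- function(phase) {
  phase <- match.arg(phase, pk_phases, several.ok = TRUE)
  ifelse(grepl("_embolization$", phase), "bead_intraarterial", "iv_infusion")
}

#' Treatment cycle implied by a phase label
#'
#' @inheritParams phase_route
#' @return `"primary"` or `"secondary"`.
#' @export
phase_cycle <- function(phase) {
  phase <- match.arg(phase, pk_phases, several.ok = TRUE)
  ifelse(grepl("^primary_", phase), "primary", "secondary")
}

#' Construct a concentration-time profile
#'
#' A profile is one subject/phase/analyte concentration-time series on the
#' post-administration clock, with below-LLOQ (BLOQ) censoring flags. Sample
#' points must be strictly increasing in time; BLOQ points carry no
#' concentration value.
#'
#' @param subject_id Opaque subject label.
#' @param phase Study phase; see [phase_route()].
#' @param analyte `"parent"` or `"metabolite"`.
#' @param dose_mg Administered dose in mg (for the metabolite this is the
#'   parent dose that generated it; must be positive).
#' @param points `data.frame` with columns `time_h` (hours since completion of
#'   administration), `conc_ng_ml` (ng/ml, `NA` when censored) and `bloq`
#'   (logical).
#' @param infusion_duration_h Infusion duration in hours; required for the IV
#'   route, must be absent for the bead route.
#' @return An object of class `pk_profile`.
#' @examples
#' pk_profile("s1", "primary_iv", "parent", 174,
#'            data.frame(time_h = c(0, 1, 2),
#'                       conc_ng_ml = c(1000, 500, 250),
#'                       bloq = FALSE),
#'            infusion_duration_h = 1)
#' @export
pk_profile <- function(subject_id, phase, analyte, dose_mg, points,
                       infusion_duration_h = NULL) {
  phase <- match.arg(phase, pk_phases)
  analyte <- match.arg(analyte, pk_analytes)
  route <- phase_route(phase)
  stopifnot(is.data.frame(points),
            all(c("time_h", "conc_ng_ml", "bloq") %in% names(points)))
  points <- points[, c("time_h", "conc_ng_ml", "bloq")]
  points$time_h <- as.numeric(points$time_h)
  points$conc_ng_ml <- as.numeric(points$conc_ng_ml)
  points$bloq <- as.logical(points$bloq)
  rownames(points) <- NULL
  p <- structure(
    list(subject_id = as.character(subject_id), phase = phase, route = route,
         analyte = analyte, dose_mg = as.numeric(dose_mg),
         infusion_duration_h = if (is.null(infusion_duration_h)) NULL
                               else as.numeric(infusion_duration_h),
         points = points),
    class = "pk_profile")
  validate_pk_profile(p)
}

#' Validate a concentration-time profile
#'
#' Checks the structural invariants: positive dose, strictly increasing
#' non-negative times, non-negative concentrations, BLOQ points without a
#' concentration value, and phase/route consistency (an infusion duration is
#' present exactly for the IV route).
#'
#' @param p A `pk_profile`.
#' @return `p`, invisibly unchanged, or an error describing the violation.
#' @export
validate_pk_profile <- function(p) {
  stopifnot(inherits(p, "pk_profile"))
  pts <- p$points
  if (!is.finite(p$dose_mg) || p$dose_mg <= 0)
    stop("dose_mg must be a positive number", call. = FALSE)
  if (nrow(pts) > 0) {
    if (anyNA(pts$time_h) || any(pts$time_h < 0))
      stop("sample times must be non-negative", call. = FALSE)
    if (is.unsorted(pts$time_h, strictly = TRUE))
      stop("sample times must be strictly increasing", call. = FALSE)
    if (anyNA(pts$bloq))
      stop("bloq flags must be TRUE or FALSE", call. = FALSE)
    if (any(pts$bloq & !is.na(pts$conc_ng_ml)))
      stop("BLOQ points must not carry a concentration", call. = FALSE)
    if (any(!pts$bloq & is.na(pts$conc_ng_ml)))
      stop("quantifiable points must carry a concentration", call. = FALSE)
    if (any(!is.na(pts$conc_ng_ml) & pts$conc_ng_ml < 0))
      stop("concentrations must be non-negative", call. = FALSE)
  }
  if (p$route == "iv_infusion") {
    if (is.null(p$infusion_duration_h) || !is.finite(p$infusion_duration_h) ||
        p$infusion_duration_h <= 0)
      stop("iv_infusion profiles require a positive infusion_duration_h",
           call. = FALSE)
  } else if (!is.null(p$infusion_duration_h)) {
    stop("bead_intraarterial profiles must not carry an infusion duration",
         call. = FALSE)
  }
  invisible(p)
}

#' Number of quantifiable points in a profile
#'
#' @param p A `pk_profile`.
#' @return Count of non-BLOQ sample points. A profile needs at least three to
#'   be eligible for terminal-slope estimation.
#' @export
n_quantifiable <- function(p) {
  stopifnot(inherits(p, "pk_profile"))
  sum(!p$points$bloq)
}

#' @export
print.pk_profile <- function(x, ...) {
  cat(sprintf("<pk_profile> %s / %s / %s  dose %.4g mg, %d points (%d BLOQ)\n",
              x$subject_id, x$phase, x$analyte, x$dose_mg,
              nrow(x$points), sum(x$points$bloq)))
  invisible(x)
}

#' @export
as.data.frame.pk_profile <- function(x, ...) {
  n <- nrow(x$points)
  data.frame(subject = rep(x$subject_id, n), phase = rep(x$phase, n),
             route = rep(x$route, n), analyte = rep(x$analyte, n),
             dose_mg = rep(x$dose_mg, n),
             infusion_duration_h =
               rep(if (is.null(x$infusion_duration_h)) NA_real_
                   else x$infusion_duration_h, n),
             x$points, stringsAsFactors = FALSE)
}

# Canonical CSV dialect: comma-separated, UTF-8, header row
# subject,phase,route,analyte,dose_mg,infusion_duration_h,time_h,conc_ng_ml,bloq
# with the empty string for absent values and lower-case true/false flags.
csv_columns <- c("subject", "phase", "route", "analyte", "dose_mg",
                 "infusion_duration_h", "time_h", "conc_ng_ml", "bloq")

#' Column-mapping schema for profile CSV files
#'
#' Describes how an input file maps onto the canonical dialect: a rename table
#' and the unit of the time column. The same structure can be read from a YAML
#' or JSON file with [read_schema()].
#'
#' @param columns Named character vector mapping canonical names (see
#'   `beadpk:::csv_columns`) to the column names actually present in the file.
#' @param time_unit `"h"` (default) or `"min"`; minute input is divided by 60.
#' @return A `profile_schema` list.
#' @export
profile_schema <- function(columns = NULL, time_unit = c("h", "min")) {
  time_unit <- match.arg(time_unit)
  map <- stats::setNames(csv_columns, csv_columns)
  if (!is.null(columns)) {
    columns <- unlist(columns)
    bad <- setdiff(names(columns), csv_columns)
    if (length(bad) > 0)
      stop("unknown canonical column(s) in schema: ",
           paste(bad, collapse = ", "), call. = FALSE)
    map[names(columns)] <- columns
  }
  structure(list(columns = map, time_unit = time_unit),
            class = "profile_schema")
}

#' Read a column-mapping schema from YAML or JSON
#'
#' @param path File with optional keys `columns` (rename map) and `time_unit`.
#' @return A `profile_schema`.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  profile_schema(columns = cfg$columns,
                 time_unit = if (is.null(cfg$time_unit)) "h" else cfg$time_unit)
}

#' Read concentration-time profiles from CSV
#'
#' Parses the documented CSV dialect (or a renamed variant described by
#' `schema`) into a list of [pk_profile()] objects, one per
#' (subject, phase, analyte) combination, with points sorted by time.
#' Duplicate (subject, phase, analyte, time) rows, negative times or
#' concentrations, and BLOQ rows carrying a concentration are rejected with
#' the offending data line number.
#'
#' @param path CSV file path.
#' @param schema A [profile_schema()].
#' @return List of `pk_profile` objects (empty for a header-only file).
#' @export
read_profiles <- function(path, schema = profile_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(unname(schema$columns), names(raw))
  if (length(missing_cols) > 0)
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  d <- stats::setNames(raw[, unname(schema$columns), drop = FALSE],
                       names(schema$columns))
  if (nrow(d) == 0) return(list())
  d$line <- seq_len(nrow(d)) + 1L  # header is line 1

  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  d$dose_mg <- num(d$dose_mg)
  d$infusion_duration_h <- num(d$infusion_duration_h)
  d$time_h <- num(d$time_h)
  if (schema$time_unit == "min") d$time_h <- d$time_h / 60
  d$conc_ng_ml <- num(d$conc_ng_ml)
  d$bloq <- tolower(trimws(d$bloq)) %in% c("true", "t", "1", "yes")

  bad_row <- function(cond, what) {
    if (any(cond))
      stop(sprintf("invalid row (line %d): %s", d$line[which(cond)[1]], what),
           call. = FALSE)
  }
  bad_row(is.na(d$time_h) | d$time_h < 0, "time must be a non-negative number")
  bad_row(!d$bloq & (is.na(d$conc_ng_ml) | d$conc_ng_ml < 0),
          "concentration must be a non-negative number unless bloq=true")
  bad_row(d$bloq & !is.na(d$conc_ng_ml),
          "bloq=true rows must leave the concentration empty")
  bad_row(!d$phase %in% pk_phases, "unknown phase")
  bad_row(!d$analyte %in% pk_analytes, "unknown analyte")
  bad_row(d$route != "" & d$route != phase_route(
            ifelse(d$phase %in% pk_phases, d$phase, pk_phases[1])),
          "route is inconsistent with phase")
  key <- paste(d$subject, d$phase, d$analyte, d$time_h, sep = "\r")
  bad_row(duplicated(key), "duplicate (subject, phase, analyte, time) row")

  split_key <- interaction(d$subject, d$phase, d$analyte, drop = TRUE,
                           lex.order = TRUE)
  out <- lapply(split(d, split_key), function(g) {
    g <- g[order(g$time_h), ]
    if (length(unique(g$dose_mg)) != 1)
      stop(sprintf("invalid row (line %d): dose_mg differs within one profile",
                   g$line[1]), call. = FALSE)
    dur <- unique(g$infusion_duration_h)
    pk_profile(g$subject[1], g$phase[1], g$analyte[1], g$dose_mg[1],
               data.frame(time_h = g$time_h, conc_ng_ml = g$conc_ng_ml,
                          bloq = g$bloq),
               infusion_duration_h = if (all(is.na(dur))) NULL else dur[1])
  })
  names(out) <- NULL
  out
}

#' Write concentration-time profiles to CSV
#'
#' Emits the canonical dialect at full numeric precision, so that
#' `read_profiles(write_profiles(x))` reproduces `x` exactly (times and flags
#' bit-exact, concentrations to full double precision).
#'
#' @param profiles List of `pk_profile` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(is.list(profiles))
  lapply(profiles, validate_pk_profile)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  rows <- unlist(lapply(profiles, function(p) {
    pts <- p$points
    dur <- if (is.null(p$infusion_duration_h)) NA_real_
           else p$infusion_duration_h
    sprintf("%s,%s,%s,%s,%s,%s,%s,%s,%s",
            p$subject_id, p$phase, p$route, p$analyte, fmt(p$dose_mg),
            fmt(rep(dur, nrow(pts))), fmt(pts$time_h), fmt(pts$conc_ng_ml),
            ifelse(pts$bloq, "true", "false"))
  }))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(c(paste(csv_columns, collapse = ","), rows), con)
  invisible(path)
}

#' Assemble and validate dosing records
#'
#' One row per subject and phase, with body weight and either a dose intensity
#' in mg/m2 (IV phases, converted through the allometric dose formula) or an
#' absolute dose in mg. When both an intensity and an absolute dose are given,
#' they must agree through [compute_dose()] to within 0.05 mg.
#'
#' @param subject_id,phase,weight_kg,dose_per_m2_mg,dose_mg Vectors of equal
#'   length; `dose_per_m2_mg` may be `NA` where only an absolute dose applies.
#' @param params Dose-formula constants, see [dose_calc_params()].
#' @return A `data.frame` of class `dose_records`.
#' @export
dose_records <- function(subject_id, phase, weight_kg,
                         dose_per_m2_mg = NA_real_, dose_mg = NA_real_,
                         params = dose_calc_params()) {
  d <- data.frame(subject = as.character(subject_id), phase = phase,
                  weight_kg = as.numeric(weight_kg),
                  dose_per_m2_mg = as.numeric(dose_per_m2_mg),
                  dose_mg = as.numeric(dose_mg), stringsAsFactors = FALSE)
  if (!all(d$phase %in% pk_phases)) stop("unknown phase", call. = FALSE)
  if (any(!is.finite(d$weight_kg) | d$weight_kg <= 0))
    stop("weight_kg must be positive", call. = FALSE)
  derivable <- !is.na(d$dose_per_m2_mg)
  expected <- compute_dose(d$weight_kg[derivable], d$dose_per_m2_mg[derivable],
                           params)
  missing_dose <- is.na(d$dose_mg[derivable])
  d$dose_mg[derivable][missing_dose] <- expected[missing_dose]
  if (any(abs(d$dose_mg[derivable] - expected) > 0.05))
    stop("dose_mg disagrees with the dose formula by more than 0.05 mg",
         call. = FALSE)
  if (any(is.na(d$dose_mg) | d$dose_mg <= 0))
    stop("dose_mg must be positive (or derivable from dose_per_m2_mg)",
         call. = FALSE)
  class(d) <- c("dose_records", "data.frame")
  d
}
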