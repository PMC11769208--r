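#' Baseline MSD prevalence curve
#'
#' A quadratic model of population MSD prevalence against age,
#' `y = a2 * x^2 + a1 * x + a0`. The parabola opens upward (`a2 > 0`):
#' with aging, both declining capacity and accumulated load raise the
#' probability of a disorder at an accelerating rate.
#'
#' @param region `"neck"`, `"shoulder"` or `"elbow"`.
#' @param a2 Quadratic coefficient (per year squared); must be > 0.
#' @param a1 Linear coefficient (per year).
#' @param a0 Intercept (nominal probability at age 0).
#' @param valid_age_range Ages (years) over which the curve is considered
#'   calibrated; evaluation outside warns but proceeds. Default \[20, 75\].
#' @return An object of class `msd_baseline_curve`.
#' @export
baseline_curve <- function(region, a2, a1, a0, valid_age_range = c(20, 75)) {
  region <- check_region(region)
  if (!is_scalar_number(a2) || a2 <= 0) {
    abort_input("a2 must be > 0 (upward-opening parabola)")
  }
  if (!is_scalar_number(a1) || !is_scalar_number(a0)) {
    abort_input("a1 and a0 must be finite numbers")
  }
  if (length(valid_age_range) != 2L || valid_age_range[1] < 0 ||
      diff(valid_age_range) <= 0) {
    abort_input("valid_age_range must be an increasing pair of non-negative ages")
  }
  curve <- structure(
    list(region = region, a2 = a2, a1 = a1, a0 = a0,
         valid_age_range = as.numeric(valid_age_range)),
    class = "msd_baseline_curve"
  )
  ends <- curve_poly(curve, valid_age_range)
  if (any(ends < 0) || any(ends > 1)) {
    warn_msd(sprintf("%s curve leaves [0, 1] within its nominal age range", region),
             class = "msdrisk_range_warning")
  }
  curve
}

curve_poly <- function(curve, age) curve$a2 * age^2 + curve$a1 * age + curve$a0

#' @export
print.msd_baseline_curve <- function(x, ...) {
  cat(sprintf("<msd_baseline_curve> %s: y = %.4g*x^2 + %.4g*x + %.4g  (ages %g-%g)\n",
              x$region, x$a2, x$a1, x$a0,
              x$valid_age_range[1], x$valid_age_range[2]))
  invisible(x)
}

#' Packaged baseline curves
#'
#' The published quadratic prevalence curves for the neck
#' (`y = 6.67e-5 x^2 + 0.003 x + 0.213`), shoulder
#' (`y = 3e-5 x^2 + 0.0019 x + 0.3`) and elbow
#' (`y = 1.767e-4 x^2 + 0.0047 x + 0.083`), extrapolated from five
#' large-sample prevalence studies of healthcare workers. These are the
#' canonical curves used by the risk pipeline; [fit_baseline()] exists for
#' re-derivation and sensitivity analysis but never replaces them.
#'
#' @param region Optional single region; default returns all three.
#' @return A single curve or a named list of the three curves.
#' @export
msd_baseline_curves <- function(region = NULL) {
  # The published elbow curve exceeds probability 1 near age 60, inside the
  # nominal [20, 75] range; it ships as printed, so the construction-time
  # range warning is muffled here. evaluate_baseline() still warns whenever
  # it actually clips.
  curves <- withCallingHandlers(
    list(
      neck = baseline_curve("neck", 6.67e-5, 0.003, 0.213),
      shoulder = baseline_curve("shoulder", 3e-5, 0.0019, 0.3),
      elbow = baseline_curve("elbow", 1.767e-4, 0.0047, 0.083)
    ),
    msdrisk_range_warning = function(w) invokeRestart("muffleWarning")
  )
  if (is.null(region)) return(curves)
  curves[[check_region(region)]]
}

#' Evaluate a baseline curve at given ages
#'
#' @param curve An [baseline_curve()].
#' @param age Ages in years (vectorized). Negative ages error; ages outside
#'   the curve's valid range warn.
#' @return Probabilities, clipped into \[0, 1\] (with a warning if clipping
#'   occurred).
#' @export
evaluate_baseline <- function(curve, age) {
  stopifnot(inherits(curve, "msd_baseline_curve"))
  if (any(!is.finite(age))) abort_input("age must be finite")
  if (any(age < 0)) abort_input("age must be non-negative")
  rng <- curve$valid_age_range
  if (any(age < rng[1] | age > rng[2])) {
    warn_msd(sprintf("age outside the %s curve's calibrated range [%g, %g]",
                     curve$region, rng[1], rng[2]),
             class = "msdrisk_range_warning")
  }
  y <- curve_poly(curve, age)
  if (any(y < 0 | y > 1)) {
    warn_msd("baseline probability clipped into [0, 1]",
             class = "msdrisk_clip_warning")
  }
  clip_unit(y)
}

#' Shift a baseline curve for time-horizon prognosis
#'
#' Produces the prognosis curve `Q_T` with `Q_T(age) = Q(age + horizon)`:
#' the risk a subject faces `horizon` years from now, read at their current
#' age. Equivalently the published example: if the baseline gives
#' probability 0.5 at age 40, the 5-year prognosis curve gives 0.5 at age 35.
#'
#' @param curve An [baseline_curve()].
#' @param horizon Forecast horizon in years, >= 0.
#' @return A new `msd_baseline_curve` with shifted coefficients; its valid
#'   age range moves down by `horizon` (floored at 0).
#' @export
shift_curve <- function(curve, horizon) {
  stopifnot(inherits(curve, "msd_baseline_curve"))
  if (!is_scalar_number(horizon) || horizon < 0) {
    abort_input("horizon must be a non-negative number of years")
  }
  if (horizon == 0) return(curve)
  # substitute x + T: a2 x^2 + (2 a2 T + a1) x + (a2 T^2 + a1 T + a0)
  shifted <- curve
  shifted$a1 <- 2 * curve$a2 * horizon + curve$a1
  shifted$a0 <- curve$a2 * horizon^2 + curve$a1 * horizon + curve$a0
  shifted$valid_age_range <- pmax(0, curve$valid_age_range - horizon)
  if (diff(shifted$valid_age_range) <= 0) shifted$valid_age_range <- c(0, 1)
  shifted
}

#' Read published-prevalence study records from CSV
#'
#' Expected header: `label, country, sample_size, mean_age, age_sd, neck,
#' shoulders, elbows`. Lines starting with `#` are ignored.
#'
#' @param path CSV file path.
#' @return A data frame of study records with one row per study.
#' @export
read_study_records <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("study records file not found: %s", path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("label", "country", "sample_size", "mean_age", "age_sd",
            "neck", "shoulders", "elbows")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort_io(sprintf("study records missing columns: %s", paste(missing, collapse = ", ")))
  }
  for (region_col in c("neck", "shoulders", "elbows")) {
    p <- df[[region_col]]
    if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
      abort_input(sprintf("column '%s' must hold probabilities in [0, 1]", region_col))
    }
  }
  if (any(df$sample_size < 1)) abort_input("sample_size must be >= 1")
  df
}

#' Packaged prevalence study records
#'
#' Five large-sample studies of work-related MSD prevalence among healthcare
#' workers (Portugal, India, USA, Taiwan, Sweden; n = 212 to 1914), each
#' giving the base risk per body region at the study's mean age. These are
#' the inputs from which baseline curves can be re-fitted.
#'
#' @return Data frame of study records.
#' @export
msd_study_records <- function() {
  read_study_records(system.file("extdata", "study_records.csv",
                                 package = "msdrisk", mustWork = TRUE))
}

region_study_column <- c(neck = "neck", shoulder = "shoulders", elbow = "elbows")

#' Fit a baseline curve to prevalence study records
#'
#' Weighted least-squares quadratic regression of per-study base risk
#' against study mean age, optionally weighting studies by sample size
#' (larger samples are considered to have greater impact on the trend).
#'
#' The fit is provided for re-derivation and sensitivity work. The packaged
#' canonical curves ([msd_baseline_curves()]) were not produced by this exact
#' procedure — the original extrapolation is under-determined — so
#' diagnostics report, but never enforce, agreement with them.
#'
#' @param records Data frame as returned by [read_study_records()].
#' @param region Body region to fit.
#' @param weighting `"sample_size"` (default) or `"none"`.
#' @return List with `curve` (an `msd_baseline_curve`; built with a warning
#'   suppressed to a diagnostic flag if `a2 <= 0`), `coefficients`
#'   (a0, a1, a2), `diagnostics` (per-study residuals, `a2_positive` flag,
#'   and deviation from the packaged canonical curve).
#' @export
fit_baseline <- function(records, region, weighting = c("sample_size", "none")) {
  region <- check_region(region)
  weighting <- match.arg(weighting)
  col <- region_study_column[[region]]
  if (!col %in% names(records)) abort_input(sprintf("records lack column '%s'", col))
  x <- records$mean_age
  y <- records[[col]]
  if (length(unique(x)) < 3L) {
    abort_input("need at least 3 distinct mean ages to fit a quadratic",
                class = "msdrisk_rank_deficient")
  }
  w <- if (weighting == "sample_size") records$sample_size else rep(1, nrow(records))
  fit <- stats::lm(y ~ x + I(x^2), weights = w)
  cf <- stats::coef(fit)
  a0 <- unname(cf[1]); a1 <- unname(cf[2]); a2 <- unname(cf[3])
  a2_positive <- is.finite(a2) && a2 > 0
  curve <- if (a2_positive) {
    withCallingHandlers(
      baseline_curve(region, a2, a1, a0),
      msdrisk_range_warning = function(w) invokeRestart("muffleWarning")
    )
  } else NULL
  canonical <- msd_baseline_curves(region)
  diagnostics <- list(
    residuals = data.frame(label = records$label, mean_age = x,
                           observed = y, fitted = stats::fitted(fit),
                           residual = stats::residuals(fit)),
    a2_positive = a2_positive,
    weighting = weighting,
    canonical_coefficients = c(a0 = canonical$a0, a1 = canonical$a1, a2 = canonical$a2),
    canonical_deviation = c(a0 = a0 - canonical$a0, a1 = a1 - canonical$a1,
                            a2 = a2 - canonical$a2)
  )
  list(curve = curve, coefficients = c(a0 = a0, a1 = a1, a2 = a2),
       diagnostics = diagnostics)
}

#' Serialize baseline curves to JSON
#'
#' @param curves A curve or named list of curves.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "msd_baseline_curve")) curves <- list(curves)
  payload <- lapply(unname(curves), function(cv) {
    list(region = cv$region, a2 = cv$a2, a1 = cv$a1, a0 = cv$a0,
         valid_age_range = cv$valid_age_range)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read baseline curves from JSON
#'
#' @param path File written by [write_curves()].
#' @return Named list of `msd_baseline_curve` objects.
#' @export
read_curves <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("curves file not found: %s", path))
  raw <- jsonlite::read_json(path)
  curves <- lapply(raw, function(cv) {
    baseline_curve(cv$region, cv$a2, cv$a1, cv$a0,
                   unlist(cv$valid_age_range %||% c(20, 75)))
  })
  names(curves) <- vapply(curves, `[[`, character(1), "region")
  curves
}
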