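#' Physical-readiness group from a 1-10 score
#'
#' Scores are grouped low (1-6), medium (7-8), high (9-10).
#'
#' @param score Integer score(s) between 1 and 10.
#' @return Character vector of `"low"`, `"medium"`, `"high"`.
#' @export
readiness_group <- function(score) {
  if (any(!is.finite(score)) || any(score < 1 | score > 10) ||
      any(score != round(score))) {
    abort_input("readiness score must be an integer in 1..10")
  }
  cut(score, breaks = c(0, 6, 8, 10), labels = c("low", "medium", "high")) |>
    as.character()
}

check_subjects <- function(subjects) {
  need <- c("id", "sex", "age", "height_cm", "weight_kg", "readiness_score",
            "no_belt_share", "belt_share")
  missing <- setdiff(need, names(subjects))
  if (length(missing)) {
    abort_input(sprintf("subjects table missing columns: %s",
                        paste(missing, collapse = ", ")))
  }
  invisible(subjects)
}

# Subject-level value of a parametric metric for one region: mean over the
# region's sides of the subject's per-side trial means.
subject_metric <- function(feature_set, subject_id, region, metric) {
  f <- feature_set$features
  rows <- f[f$subject_id == subject_id & f$joint == region, , drop = FALSE]
  if (nrow(rows) == 0L) {
    abort_config(sprintf("no %s features for subject '%s'", region, subject_id))
  }
  mean(rows[[metric]])
}

#' Population grand means of the parametric metrics
#'
#' Per region, the grand mean over subjects of each subject's region-level
#' metric (range of motion, maximum moment, cumulative moment). Parametric
#' element likelihoods are ratios of subject values to these means.
#'
#' @param feature_set An [extract_features()] result.
#' @return Data frame with columns `region`, `metric`, `mean`.
#' @export
population_statistics <- function(feature_set) {
  f <- feature_set$features
  subj <- stats::aggregate(f[PARAMETRIC_METRICS],
                           by = f[c("subject_id", "joint")], FUN = mean)
  out <- stats::aggregate(subj[PARAMETRIC_METRICS],
                          by = list(region = subj$joint), FUN = mean)
  stats::reshape(out, direction = "long", varying = PARAMETRIC_METRICS,
                 v.names = "mean", timevar = "metric",
                 times = PARAMETRIC_METRICS, idvar = "region") -> long
  rownames(long) <- NULL
  long[order(long$region, long$metric), c("region", "metric", "mean")]
}

population_mean <- function(population_stats, region, metric) {
  m <- population_stats$mean[population_stats$region == region &
                               population_stats$metric == metric]
  if (length(m) != 1L || !is.finite(m) || m <= 0) {
    abort_config(sprintf("population mean for %s/%s unavailable", region, metric))
  }
  m
}

PARAMETRIC_CRITERION_METRIC <- c(
  amplitude = "rom_deg",
  moment = "max_moment_Nm",
  cumulative_moment = "cumulative_moment_Nms"
)

#' Resolve one element factor per criterion for a subject
#'
#' Categorical criteria (readiness group, sex) resolve by level lookup;
#' proportional criteria (technique scenario, side symmetry) blend their two
#' level likelihoods with the subject's continuous shares; parametric
#' criteria (amplitude, moment, cumulative moment) take the ratio of the
#' subject's metric to the population mean.
#'
#' @param subject One-row data frame (or list) with the subject columns; see
#'   [generate_cohort()] for the dialect.
#' @param feature_set An [extract_features()] result covering the subject.
#' @param table The region's [criteria_table()].
#' @param population_stats From [population_statistics()].
#' @param rounding_mode Optional override of the table's mode.
#' @param likelihood_clip Clipping bounds for parametric likelihood ratios.
#' @return Data frame with one row per criterion: `criterion`, `likelihood`,
#'   `weight`, `value`.
#' @export
build_element_factors <- function(subject, feature_set, table, population_stats,
                                  rounding_mode = NULL,
                                  likelihood_clip = c(0.1, 3.0)) {
  stopifnot(inherits(table, "msd_criteria_table"))
  mode <- rounding_mode %||% table$rounding_mode
  q <- weight_coefficients(table, mode)
  region <- table$region

  resolve_likelihood <- function(cr) {
    if (cr$kind == "parametric") {
      metric <- PARAMETRIC_CRITERION_METRIC[[cr$name]]
      if (is.null(metric)) {
        abort_config(sprintf("no metric mapping for parametric criterion '%s'", cr$name))
      }
      value <- subject_metric(feature_set, subject$id, region, metric)
      return(derive_likelihood(value, population_mean(population_stats, region, metric),
                               clip = likelihood_clip))
    }
    if (cr$kind == "proportional") {
      shares <- if (cr$name == "technique_scenario") {
        stats::setNames(c(subject$no_belt_share, subject$belt_share),
                        c("no_belt", "belt"))
      } else if (cr$name == "symmetry") {
        sh <- feature_set$side_shares
        row <- sh[sh$subject_id == subject$id & sh$joint == region, , drop = FALSE]
        if (nrow(row) != 1L) {
          abort_config(sprintf("no side shares for subject '%s', region %s",
                               subject$id, region))
        }
        c(left = row$left_share, right = row$right_share)
      } else {
        abort_config(sprintf("no share source for proportional criterion '%s'", cr$name))
      }
      missing <- setdiff(names(cr$levels), names(shares))
      if (length(missing)) {
        abort_config(sprintf("criterion '%s': no shares for level(s) %s",
                             cr$name, paste(missing, collapse = ", ")))
      }
      return(blend_likelihoods(unname(cr$levels),
                               unname(shares[names(cr$levels)])))
    }
    # categorical
    level <- switch(cr$name,
      physical_readiness = readiness_group(subject$readiness_score),
      sex = as.character(subject$sex),
      as.character(subject[[cr$name]])
    )
    if (is.null(level) || length(level) != 1L || is.na(level) ||
        !level %in% names(cr$levels)) {
      abort_config(sprintf("criterion '%s': level '%s' not defined",
                           cr$name, paste(level, collapse = "/")))
    }
    unname(cr$levels[[level]])
  }

  rows <- lapply(table$criteria, function(cr) {
    a <- resolve_likelihood(cr)
    data.frame(criterion = cr$name, likelihood = a, weight = unname(q[[cr$name]]),
               value = element_factor(a, unname(q[[cr$name]]), mode),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Risk profile of one subject over forecast horizons
#'
#' For each region and horizon `T`, the probability is the baseline curve
#' shifted by `T` evaluated at the subject's current age, times the
#' subject's element-factor sum, clipped into \[0, 1\].
#'
#' @param subject One-row subject record.
#' @param feature_set An [extract_features()] result.
#' @param tables Named list of criteria tables (per region); default packaged.
#' @param curves Named list of baseline curves (per region); default packaged.
#' @param population_stats From [population_statistics()].
#' @param horizons Forecast horizons in years. Default `c(5, 10, 15)`.
#' @param rounding_mode Optional override applied to every table.
#' @param likelihood_clip Parametric likelihood clipping bounds.
#' @return Data frame with one row per region x horizon: `subject_id`,
#'   `region`, `horizon_years`, `factor_sum`, `probability`, `clipped`,
#'   `age_out_of_range`.
#' @export
subject_risk_profile <- function(subject, feature_set, tables = msd_default_criteria(),
                                 curves = msd_baseline_curves(),
                                 population_stats,
                                 horizons = c(5, 10, 15),
                                 rounding_mode = NULL,
                                 likelihood_clip = c(0.1, 3.0)) {
  if (any(horizons < 0)) abort_input("horizons must be non-negative")
  rows <- list()
  for (region in names(tables)) {
    table <- tables[[region]]
    curve <- curves[[region]]
    if (is.null(curve)) abort_config(sprintf("no baseline curve for region %s", region))
    factors <- build_element_factors(subject, feature_set, table, population_stats,
                                     rounding_mode = rounding_mode,
                                     likelihood_clip = likelihood_clip)
    sx <- sum(factors$value)
    for (h in horizons) {
      shifted <- shift_curve(curve, h)
      rng <- shifted$valid_age_range
      out_of_range <- subject$age < rng[1] || subject$age > rng[2]
      q_base <- withCallingHandlers(
        evaluate_baseline(shifted, subject$age),
        msdrisk_warning = function(w) invokeRestart("muffleWarning")
      )
      raw <- q_base * sx
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subject$id, region = region, horizon_years = h,
        factor_sum = sx, probability = clip_unit(raw),
        clipped = raw < 0 || raw > 1, age_out_of_range = out_of_range,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Risk profiles for a whole cohort
#'
#' @param subjects Subject table (one row per subject).
#' @param feature_set An [extract_features()] result for the cohort.
#' @param ... Passed to [subject_risk_profile()]; `population_stats` defaults
#'   to [population_statistics()] of the cohort itself.
#' @inheritParams subject_risk_profile
#' @return Row-bound risk profiles for all subjects.
#' @export
cohort_risk_profiles <- function(subjects, feature_set,
                                 population_stats = population_statistics(feature_set),
                                 ...) {
  check_subjects(subjects)
  profiles <- lapply(seq_len(nrow(subjects)), function(i) {
    subject_risk_profile(subjects[i, , drop = FALSE], feature_set,
                         population_stats = population_stats, ...)
  })
  do.call(rbind, profiles)
}

#' Cohort summary of risk profiles
#'
#' Per region and horizon: sample mean and SD (n - 1 denominator) of the
#' probabilities; per region: range and mean +/- SD of the element-factor
#' sum.
#'
#' @param profiles Data frame from [cohort_risk_profiles()].
#' @return List with `probability` and `factor_sum` summary data frames.
#' @export
cohort_summary <- function(profiles) {
  if (!is.data.frame(profiles) || length(unique(profiles$subject_id)) < 2L) {
    abort_input("cohort_summary needs profiles from at least 2 subjects")
  }
  prob <- stats::aggregate(
    list(mean = profiles$probability),
    by = profiles[c("region", "horizon_years")], FUN = mean
  )
  prob$sd <- stats::aggregate(list(sd = profiles$probability),
                              by = profiles[c("region", "horizon_years")],
                              FUN = stats::sd)$sd
  prob$n <- stats::aggregate(list(n = profiles$probability),
                             by = profiles[c("region", "horizon_years")],
                             FUN = length)$n
  prob <- prob[order(prob$region, prob$horizon_years), , drop = FALSE]
  rownames(prob) <- NULL

  # one factor-sum value per subject x region (constant across horizons)
  fs <- unique(profiles[c("subject_id", "region", "factor_sum")])
  fsum <- stats::aggregate(list(mean = fs$factor_sum),
                           by = fs["region"], FUN = mean)
  fsum$sd <- stats::aggregate(list(sd = fs$factor_sum), by = fs["region"],
                              FUN = stats::sd)$sd
  fsum$min <- stats::aggregate(list(min = fs$factor_sum), by = fs["region"],
                               FUN = min)$min
  fsum$max <- stats::aggregate(list(max = fs$factor_sum), by = fs["region"],
                               FUN = max)$max
  rownames(fsum) <- NULL
  list(probability = prob, factor_sum = fsum)
}

criterion_likelihood_range <- function(cr, parametric_ranges) {
  if (cr$kind == "parametric") {
    rng <- parametric_ranges[[cr$name]]
    if (is.null(rng) || length(rng) != 2L || any(!is.finite(rng)) ||
        any(rng <= 0) || rng[1] > rng[2]) {
      abort_input(sprintf("parametric_ranges must give a valid (min, max) for '%s'",
                          cr$name))
    }
    return(rng)
  }
  range(cr$levels)
}

#' Extreme-scenario probability bounds
#'
#' The minimum scenario combines, per criterion, the lowest-risk likelihood
#' (best technique, favourable readiness, balanced sides, lowest observed
#' parametric ratios); the maximum scenario the highest. For the additive
#' factor sum these bounds are attained criterion-wise, so no combinatorial
#' search is needed.
#'
#' @param table The region's [criteria_table()].
#' @param parametric_ranges Named list: for each parametric criterion a
#'   `c(min, max)` of observed likelihood ratios.
#' @param age Subject age in years.
#' @param horizon Forecast horizon in years.
#' @param curve The region's [baseline_curve()].
#' @param rounding_mode Optional override.
#' @return One-row data frame: `region`, `age`, `horizon_years`, `sx_min`,
#'   `sx_max`, `p_min`, `p_max`.
#' @export
extreme_scenarios <- function(table, parametric_ranges, age, horizon, curve,
                              rounding_mode = NULL) {
  stopifnot(inherits(table, "msd_criteria_table"),
            inherits(curve, "msd_baseline_curve"))
  mode <- rounding_mode %||% table$rounding_mode
  q <- weight_coefficients(table, mode)
  lo <- hi <- 0
  for (cr in table$criteria) {
    rng <- criterion_likelihood_range(cr, parametric_ranges)
    lo <- lo + element_factor(rng[1], q[[cr$name]], mode)
    hi <- hi + element_factor(rng[2], q[[cr$name]], mode)
  }
  q_base <- withCallingHandlers(
    evaluate_baseline(shift_curve(curve, horizon), age),
    msdrisk_warning = function(w) invokeRestart("muffleWarning")
  )
  data.frame(region = table$region, age = age, horizon_years = horizon,
             sx_min = lo, sx_max = hi,
             p_min = clip_unit(q_base * lo), p_max = clip_unit(q_base * hi),
             stringsAsFactors = FALSE)
}

#' Share of risk spread attributable to dynamic parameters
#'
#' Quantifies how much of the between-scenario spread of the element-factor
#' sum is driven by the dynamic (parametric, motion-derived) criteria rather
#' than fixed demographic ones. Because the factor sum is additive, the
#' spread decomposes exactly per criterion, and the metric is
#' `sum over parametric criteria of q * (a_max - a_min)` divided by the same
#' sum over all criteria, times 100.
#'
#' This is one plausible operationalization of "dynamic-parameter impact";
#' the definition is attached to the result so numbers are never silently
#' compared across definitions.
#'
#' @inheritParams extreme_scenarios
#' @return List with `percent`, `parametric_spread`, `total_spread`, and a
#'   `definition` string.
#' @export
dynamic_impact <- function(table, parametric_ranges, rounding_mode = NULL) {
  stopifnot(inherits(table, "msd_criteria_table"))
  mode <- rounding_mode %||% table$rounding_mode
  q <- weight_coefficients(table, mode)
  param <- total <- 0
  for (cr in table$criteria) {
    rng <- criterion_likelihood_range(cr, parametric_ranges)
    spread <- element_factor(rng[2], q[[cr$name]], mode) -
      element_factor(rng[1], q[[cr$name]], mode)
    total <- total + spread
    if (cr$kind == "parametric") param <- param + spread
  }
  if (total == 0) abort_degenerate("all criteria have zero likelihood spread")
  list(
    percent = 100 * param / total,
    parametric_spread = param,
    total_spread = total,
    definition = paste("share of the additive element-factor-sum spread",
                       "attributable to parametric (dynamic) criteria:",
                       "sum_parametric q*(a_max - a_min) /",
                       "sum_all q*(a_max - a_min) * 100")
  )
}

#' Male vs female mean-risk difference
#'
#' Percentage by which the male mean probability exceeds the female mean at
#' a given horizon, per region, with the female mean as denominator:
#' `(mean_male - mean_female) / mean_female * 100`.
#'
#' @param profiles Data frame from [cohort_risk_profiles()].
#' @param subjects Subject table supplying `id` and `sex`.
#' @param horizon Horizon (years) to compare at; default 15.
#' @return Data frame per region: `mean_male`, `mean_female`,
#'   `percent_difference`.
#' @export
sex_comparison <- function(profiles, subjects, horizon = 15) {
  p <- profiles[profiles$horizon_years == horizon, , drop = FALSE]
  if (nrow(p) == 0L) abort_input(sprintf("no profiles at horizon %g", horizon))
  p$sex <- subjects$sex[match(p$subject_id, subjects$id)]
  if (!all(c("male", "female") %in% p$sex)) {
    abort_input("both sexes must be present for a sex comparison")
  }
  rows <- lapply(split(p, p$region), function(g) {
    mm <- mean(g$probability[g$sex == "male"])
    mf <- mean(g$probability[g$sex == "female"])
    data.frame(region = g$region[1], horizon_years = horizon,
               mean_male = mm, mean_female = mf,
               percent_difference = (mm - mf) / mf * 100,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Observed parametric likelihood ranges of a cohort
#'
#' For each region and parametric criterion, the min and max over subjects
#' of the likelihood ratio (subject metric / population mean). These ranges
#' feed [extreme_scenarios()] and [dynamic_impact()].
#'
#' @param feature_set An [extract_features()] result.
#' @param population_stats From [population_statistics()].
#' @param likelihood_clip Clipping bounds, as in [derive_likelihood()].
#' @return Named list per region; each element a named list of `c(min, max)`
#'   per parametric criterion.
#' @export
observed_parametric_ranges <- function(feature_set,
                                       population_stats = population_statistics(feature_set),
                                       likelihood_clip = c(0.1, 3.0)) {
  f <- feature_set$features
  subj <- stats::aggregate(f[PARAMETRIC_METRICS],
                           by = f[c("subject_id", "joint")], FUN = mean)
  out <- list()
  for (region in unique(subj$joint)) {
    g <- subj[subj$joint == region, , drop = FALSE]
    ranges <- list()
    for (crit in names(PARAMETRIC_CRITERION_METRIC)) {
      metric <- PARAMETRIC_CRITERION_METRIC[[crit]]
      pm <- population_mean(population_stats, region, metric)
      ratios <- withCallingHandlers(
        derive_likelihood(g[[metric]], pm, clip = likelihood_clip),
        msdrisk_clip_warning = function(w) invokeRestart("muffleWarning")
      )
      ranges[[crit]] <- range(ratios)
    }
    out[[region]] <- ranges
  }
  out
}
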