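#' Read a subjects table from CSV
#'
#' Expected columns: `id, sex, age, height_cm, weight_kg, readiness_score`
#' and optionally `no_belt_share, belt_share` (default 2/3, 1/3) and
#' `readiness_group` (re-derived from the score if absent). Lines starting
#' with `#` are ignored.
#'
#' @param path CSV file path.
#' @return Subject data frame in the dialect of [generate_cohort()].
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("subjects file not found: %s", path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "sex", "age", "height_cm", "weight_kg", "readiness_score")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort_io(sprintf("subjects file missing columns: %s",
                     paste(missing, collapse = ", ")))
  }
  if (is.null(df$no_belt_share)) df$no_belt_share <- 2 / 3
  if (is.null(df$belt_share)) df$belt_share <- 1 - df$no_belt_share
  df$readiness_group <- readiness_group(df$readiness_score)
  df
}

#' Read a long-format trials table from CSV
#'
#' Expected columns: `subject_id, scenario, joint, side, time_s, angle_deg,
#' moment_Nm`, plus optional `trial`. UTF-8, dot decimal.
#'
#' @param path CSV file path.
#' @return Trial data frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("trials file not found: %s", path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  check_trial_columns(df)
  df
}

#' Assemble a pipeline run configuration
#'
#' A run configuration names the input files and the knobs of a pipeline
#' run. `subjects`/`trials` may be omitted when `simulate` is `TRUE`, in
#' which case a synthetic cohort is generated from `n_subjects` and `seed`.
#' Flags passed explicitly override values loaded from a JSON config file.
#'
#' @param config_file Optional JSON file with any of the fields below.
#' @param subjects,trials,criteria,curves Input file paths (criteria/curves
#'   default to the packaged tables and curves when `NULL`).
#' @param out_dir Output directory. Default `"msdrisk-report"`.
#' @param rounding_mode Engine rounding mode. Default `"exact"`.
#' @param horizons Forecast horizons in years. Default `c(5, 10, 15)`.
#' @param likelihood_clip Parametric likelihood clipping bounds.
#' @param simulate Generate a synthetic cohort instead of reading files.
#' @param n_subjects Synthetic cohort size (when `simulate`). Default 44.
#' @param seed Seed for simulation. Default 1.
#' @return List of class `msd_run_config`.
#' @export
run_config <- function(config_file = NULL, subjects = NULL, trials = NULL,
                       criteria = NULL, curves = NULL,
                       out_dir = NULL, rounding_mode = NULL, horizons = NULL,
                       likelihood_clip = NULL, simulate = NULL,
                       n_subjects = NULL, seed = NULL) {
  base <- list(subjects = NULL, trials = NULL, criteria = NULL, curves = NULL,
               out_dir = "msdrisk-report", rounding_mode = "exact",
               horizons = c(5, 10, 15), likelihood_clip = c(0.1, 3.0),
               simulate = FALSE, n_subjects = 44L, seed = 1L)
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) abort_io(sprintf("config file not found: %s", config_file))
    loaded <- jsonlite::read_json(config_file, simplifyVector = TRUE)
    for (nm in intersect(names(loaded), names(base))) base[[nm]] <- loaded[[nm]]
  }
  override <- list(subjects = subjects, trials = trials, criteria = criteria,
                   curves = curves, out_dir = out_dir,
                   rounding_mode = rounding_mode, horizons = horizons,
                   likelihood_clip = likelihood_clip, simulate = simulate,
                   n_subjects = n_subjects, seed = seed)
  for (nm in names(override)) if (!is.null(override[[nm]])) base[[nm]] <- override[[nm]]
  if (!base$rounding_mode %in% c("exact", "display3", "table_match")) {
    abort_config("rounding_mode must be exact, display3 or table_match")
  }
  if (any(base$horizons <= 0)) abort_config("horizons must be positive")
  structure(base, class = "msd_run_config")
}

#' Validate pipeline input files against their schemas
#'
#' Checks each referenced file: required columns, value ranges (readiness
#' score 1-10, shares summing to 1, probabilities in range), strictly
#' increasing time within each trial, criteria-table invariants, and
#' level-name consistency between subjects and criteria tables. Every
#' violation is reported with the file and (where applicable) row number.
#'
#' @param config An [run_config()].
#' @return Data frame of violations (`file`, `row`, `message`); zero rows
#'   means the inputs validate. Class `msd_validation_report`.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "msd_run_config"))
  v <- list()
  note <- function(file, row, message) {
    v[[length(v) + 1L]] <<- data.frame(file = file, row = row, message = message,
                                       stringsAsFactors = FALSE)
  }

  tables <- tryCatch(
    if (is.null(config$criteria)) msd_default_criteria() else read_criteria(config$criteria),
    msdrisk_error = function(e) {
      note(config$criteria %||% "<packaged criteria>", NA, conditionMessage(e))
      NULL
    }
  )
  if (!is.null(tables)) {
    for (tb in tables) {
      chk <- verify_normalization(tb, "exact")
      if (!chk$ok) {
        note(config$criteria %||% "<packaged criteria>", NA,
             sprintf("%s table: exact-mode weights sum to %g, not 1",
                     tb$region, 1 - chk$residual))
      }
    }
  }
  tryCatch(
    if (is.null(config$curves)) msd_baseline_curves() else read_curves(config$curves),
    msdrisk_error = function(e) note(config$curves %||% "<packaged curves>", NA,
                                     conditionMessage(e))
  )

  if (!isTRUE(config$simulate)) {
    subjects <- tryCatch(read_subjects(config$subjects),
                         msdrisk_error = function(e) {
                           note(config$subjects %||% "<missing>", NA, conditionMessage(e))
                           NULL
                         })
    if (!is.null(subjects)) {
      bad <- which(!subjects$sex %in% c("male", "female"))
      for (i in bad) note(config$subjects, i, sprintf("sex '%s' not male/female", subjects$sex[i]))
      bad <- which(!is.finite(subjects$readiness_score) |
                     subjects$readiness_score < 1 | subjects$readiness_score > 10 |
                     subjects$readiness_score != round(subjects$readiness_score))
      for (i in bad) note(config$subjects, i,
                          sprintf("readiness score %s outside 1..10", subjects$readiness_score[i]))
      bad <- which(abs(subjects$no_belt_share + subjects$belt_share - 1) > 1e-9)
      for (i in bad) note(config$subjects, i, "scenario shares do not sum to 1")
      bad <- which(!is.finite(subjects$age) | subjects$age < 0)
      for (i in bad) note(config$subjects, i, "age must be a non-negative number")
      if (anyDuplicated(subjects$id)) note(config$subjects, NA, "duplicate subject ids")
    }
    trials <- tryCatch(read_trials(config$trials),
                       msdrisk_error = function(e) {
                         note(config$trials %||% "<missing>", NA, conditionMessage(e))
                         NULL
                       })
    if (!is.null(trials)) {
      bad <- which(!trials$joint %in% REGIONS)
      for (i in utils::head(bad, 20)) {
        note(config$trials, i, sprintf("unknown joint '%s'", trials$joint[i]))
      }
      bad <- which(!trials$side %in% c("left", "right", "midline"))
      for (i in utils::head(bad, 20)) {
        note(config$trials, i, sprintf("unknown side '%s'", trials$side[i]))
      }
      if (is.null(trials$trial)) trials$trial <- 1L
      key <- interaction(trials$subject_id, trials$scenario, trials$trial,
                         trials$joint, trials$side, drop = TRUE)
      for (idx in split(seq_len(nrow(trials)), key)) {
        t <- trials$time_s[idx]
        nonmono <- which(diff(t) <= 0)
        for (k in utils::head(nonmono, 5)) {
          note(config$trials, idx[k + 1L],
               sprintf("time not strictly increasing at row %d", idx[k + 1L]))
        }
      }
      if (!is.null(subjects)) {
        orphan <- setdiff(unique(trials$subject_id), subjects$id)
        if (length(orphan)) {
          note(config$trials, NA,
               sprintf("trial subjects missing from subjects file: %s",
                       paste(orphan, collapse = ", ")))
        }
      }
    }
  }
  report <- if (length(v)) do.call(rbind, v) else
    data.frame(file = character(), row = integer(), message = character(),
               stringsAsFactors = FALSE)
  class(report) <- c("msd_validation_report", class(report))
  report
}

provenance_hash <- function(obj) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# provenance: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full risk pipeline
#'
#' Executes features -> element factors -> risk profiles -> cohort summary
#' and writes `report.csv`, `summary.csv`, `sex_comparison.csv` and
#' `report.json` into the configured output directory. Every output carries
#' a provenance hash of the configuration, package version, seed and
#' criteria tables, so identical configurations yield identical reports.
#'
#' @param config An [run_config()].
#' @param write Write output files (default `TRUE`); `FALSE` returns the
#'   bundle invisibly without touching disk.
#' @return List of class `msd_report`: `profiles`, `summary`,
#'   `sex_comparison`, `population_stats`, `provenance`.
#' @export
run_pipeline <- function(config, write = TRUE) {
  stopifnot(inherits(config, "msd_run_config"))
  report <- validate_inputs(config)
  if (nrow(report) > 0L) {
    abort_config(sprintf("input validation failed with %d violation(s); first: %s",
                         nrow(report), report$message[1]))
  }
  if (isTRUE(config$simulate)) {
    subjects <- generate_cohort(cohort_spec(n_subjects = config$n_subjects,
                                            seed = config$seed))
    trials <- generate_cohort_trials(subjects, effect_spec(), seed = config$seed)
  } else {
    subjects <- read_subjects(config$subjects)
    trials <- read_trials(config$trials)
  }
  tables <- if (is.null(config$criteria)) msd_default_criteria() else read_criteria(config$criteria)
  curves <- if (is.null(config$curves)) msd_baseline_curves() else read_curves(config$curves)

  feature_set <- extract_features(trials)
  population_stats <- population_statistics(feature_set)
  profiles <- cohort_risk_profiles(
    subjects, feature_set, population_stats = population_stats,
    tables = tables, curves = curves, horizons = config$horizons,
    rounding_mode = config$rounding_mode, likelihood_clip = config$likelihood_clip
  )
  summary <- cohort_summary(profiles)
  sex_cmp <- if (all(c("male", "female") %in% subjects$sex)) {
    sex_comparison(profiles, subjects, horizon = max(config$horizons))
  } else NULL

  criteria_digest <- provenance_hash(lapply(tables, function(tb) {
    list(region = tb$region,
         criteria = lapply(unname(tb$criteria), function(cr) {
           list(name = cr$name, weight_score = cr$weight_score,
                kind = cr$kind, levels = as.list(cr$levels))
         }))
  }))
  provenance <- list(
    package = "msdrisk",
    version = as.character(utils::packageVersion("msdrisk")),
    seed = config$seed,
    rounding_mode = config$rounding_mode,
    horizons = config$horizons,
    criteria_hash = criteria_digest,
    # hash the scientific configuration only: where the report lands must not
    # change what it says
    config_hash = provenance_hash(unclass(config)[setdiff(names(config), "out_dir")])
  )
  provenance$hash <- provenance_hash(provenance)

  bundle <- structure(
    list(profiles = profiles, summary = summary, sex_comparison = sex_cmp,
         population_stats = population_stats, provenance = provenance),
    class = "msd_report"
  )
  if (write) {
    if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
    h <- provenance$hash
    write_stamped_csv(profiles, file.path(config$out_dir, "report.csv"), h)
    write_stamped_csv(summary$probability, file.path(config$out_dir, "summary.csv"), h)
    if (!is.null(sex_cmp)) {
      write_stamped_csv(sex_cmp, file.path(config$out_dir, "sex_comparison.csv"), h)
    }
    jsonlite::write_json(
      list(provenance = provenance, summary = summary,
           sex_comparison = sex_cmp, profiles = profiles),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null"
    )
  }
  invisible(bundle)
}

#' @export
print.msd_report <- function(x, ...) {
  cat("<msd_report> provenance", x$provenance$hash, "\n")
  cat("Probability of an MSD, cohort mean (SD), by region and horizon:\n")
  p <- x$summary$probability
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-8s %2gy: %.3f (%.3f)\n", p$region[i], p$horizon_years[i],
                p$mean[i], p$sd[i]))
  }
  invisible(x)
}

#' Plot baseline curves and their horizon-shifted prognoses
#'
#' Base-graphics view of a region's baseline prevalence curve together with
#' its 5/10/15-year prognosis shifts over an age grid.
#'
#' @param curve An [baseline_curve()].
#' @param horizons Horizons to overlay. Default `c(5, 10, 15)`.
#' @param ages Age grid. Default 20-60.
#' @return The matrix of plotted probabilities, invisibly.
#' @export
plot_baseline_prognosis <- function(curve, horizons = c(5, 10, 15),
                                    ages = seq(20, 60, by = 1)) {
  stopifnot(inherits(curve, "msd_baseline_curve"))
  eval_quiet <- function(cv) withCallingHandlers(
    evaluate_baseline(cv, ages),
    msdrisk_warning = function(w) invokeRestart("muffleWarning")
  )
  y <- cbind(baseline = eval_quiet(curve))
  for (h in horizons) y <- cbind(y, eval_quiet(shift_curve(curve, h)))
  colnames(y) <- c("baseline", sprintf("+%gy", horizons))
  graphics::matplot(ages, y, type = "l", lty = 1, lwd = 2,
                    xlab = "age (years)", ylab = "MSD probability",
                    main = sprintf("%s baseline and prognosis", curve$region))
  graphics::legend("topleft", legend = colnames(y), lty = 1, lwd = 2,
                   col = seq_len(ncol(y)), bty = "n")
  invisible(y)
}
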