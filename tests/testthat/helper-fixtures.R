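# Shared fixtures: small criteria tables, random-table generator for
# property tests, and quiet evaluation wrappers.

quiet <- function(expr) {
  withCallingHandlers(expr, msdrisk_warning = function(w) invokeRestart("muffleWarning"))
}

# A minimal two-criterion categorical table.
tiny_table <- function(rounding_mode = "exact") {
  criteria_table(
    "neck",
    list(
      criterion_def("sex", 1, "categorical", c(male = 1.1, female = 0.9)),
      criterion_def("load", 1, "categorical", c(light = 0.8, heavy = 1.3))
    ),
    rounding_mode = rounding_mode
  )
}

# Random categorical/proportional/parametric table for property tests.
random_table <- function(n_criteria, seed) {
  set.seed(seed)
  kinds <- sample(c("categorical", "proportional", "parametric"),
                  n_criteria, replace = TRUE)
  criteria <- lapply(seq_len(n_criteria), function(i) {
    kind <- kinds[i]
    name <- sprintf("c%02d", i)
    score <- sample(1:4, 1)
    if (kind == "parametric") {
      criterion_def(name, score, "parametric")
    } else {
      k <- if (kind == "proportional") 2L else sample(2:4, 1)
      levels <- stats::setNames(round(stats::runif(k, 0.5, 1.5), 3),
                                paste0("lv", seq_len(k)))
      criterion_def(name, score, kind, levels)
    }
  })
  criteria_table(sample(c("neck", "shoulder", "elbow"), 1), criteria)
}

# Random parametric ranges matching a table's parametric criteria.
random_parametric_ranges <- function(table, seed) {
  set.seed(seed)
  out <- list()
  for (cr in table$criteria) {
    if (cr$kind == "parametric") {
      lo <- round(stats::runif(1, 0.5, 1), 3)
      hi <- round(stats::runif(1, 1, 1.8), 3)
      out[[cr$name]] <- c(lo, hi)
    }
  }
  out
}

# Exhaustive enumeration oracle: the factor-sum extremes over every
# combination of level choices (levels for categorical, pure-share endpoints
# for proportional, range endpoints for parametric).
enumerate_factor_sums <- function(table, parametric_ranges,
                                  rounding_mode = NULL) {
  mode <- if (is.null(rounding_mode)) table$rounding_mode else rounding_mode
  q <- weight_coefficients(table, mode)
  choices <- lapply(table$criteria, function(cr) {
    if (cr$kind == "parametric") parametric_ranges[[cr$name]] else unname(cr$levels)
  })
  grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  sums <- apply(grid, 1, function(a) {
    sum(element_factor(unname(a), unname(q), mode))
  })
  range(sums)
}

# A small deterministic cohort + trials + features, shared across tests.
small_world <- function(n = 8, seed = 42, noise_cv = 0.05) {
  subjects <- quiet(generate_cohort(cohort_spec(n_subjects = n, male_fraction = 0.5,
                                                seed = seed)))
  effects <- effect_spec(trial_noise_cv = noise_cv, trials_per_scenario = 2L)
  trials <- generate_cohort_trials(subjects, effects, seed = seed, n_points = 21L)
  fs <- extract_features(trials)
  list(subjects = subjects, trials = trials, features = fs,
       population_stats = population_statistics(fs))
}
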