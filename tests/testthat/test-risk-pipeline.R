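make_neutral_world <- function(n = 5, seed = 3) {
  # cohort whose features are identical across subjects: every likelihood
  # that depends on data resolves to exactly 1
  subjects <- quiet(generate_cohort(cohort_spec(n_subjects = n, male_fraction = 0.4,
                                                seed = seed)))
  effects <- effect_spec(male_rom_multiplier = 1, belt_moment_multiplier = 1,
                         readiness_moment_multipliers = c(low = 1, medium = 1, high = 1),
                         trial_noise_cv = 0, trials_per_scenario = 1L)
  trials <- generate_cohort_trials(subjects, effects, seed = seed, n_points = 15L)
  # normalize weights too so subject body mass does not move the moments
  trials$moment_Nm <- trials$moment_Nm /
    subjects$weight_kg[match(trials$subject_id, subjects$id)]
  fs <- extract_features(trials)
  list(subjects = subjects, features = fs,
       population_stats = population_statistics(fs))
}

neutral_tables <- function() {
  lapply(msd_default_criteria(), function(tb) {
    tb$criteria <- lapply(tb$criteria, function(cr) {
      if (cr$kind != "parametric") cr$levels[] <- 1
      cr
    })
    tb
  })
}

test_that("element factors resolve every criterion exactly once", {
  w <- small_world(n = 6, seed = 21)
  tb <- msd_default_criteria("shoulder")
  f <- build_element_factors(w$subjects[1, ], w$features, tb, w$population_stats)
  expect_setequal(f$criterion, names(tb$criteria))
  expect_equal(nrow(f), length(tb$criteria))
  expect_equal(f$value, f$likelihood * f$weight)

  # symmetry with equal shares is the mean of the left/right likelihoods
  fs_eq <- w$features
  i <- fs_eq$side_shares$subject_id == w$subjects$id[1] &
    fs_eq$side_shares$joint == "shoulder"
  fs_eq$side_shares$left_share[i] <- 0.5
  fs_eq$side_shares$right_share[i] <- 0.5
  f_eq <- build_element_factors(w$subjects[1, ], fs_eq, tb, w$population_stats)
  expect_equal(f_eq$likelihood[f_eq$criterion == "symmetry"],
               mean(c(1.009, 0.998)))

  # missing level is a configuration error naming the criterion
  bad_subject <- w$subjects[1, ]
  bad_subject$sex <- "unknown"
  expect_error(build_element_factors(bad_subject, w$features, tb, w$population_stats),
               regexp = "sex", class = "msdrisk_config_error")
})

test_that("printed neck factor chain: male, low readiness, pure no-belt, neutral parametrics", {
  w <- make_neutral_world(n = 5, seed = 3)
  subject <- w$subjects[1, ]
  subject$sex <- "male"
  subject$readiness_score <- 3
  subject$readiness_group <- "low"
  subject$no_belt_share <- 1
  subject$belt_share <- 0
  tb <- msd_default_criteria("neck", rounding_mode = "table_match")
  f <- build_element_factors(subject, w$features, tb, w$population_stats)
  # summed printed cells: 0.146 + 0.160 + 0.136 + 0.143 + 0.143 + 0.285
  expect_equal(sum(f$value), 1.013)

  # and the resulting 15-year prognosis at age 28 follows the hand chain
  subject$age <- 28
  profile <- subject_risk_profile(
    subject, w$features, tables = list(neck = tb),
    curves = msd_baseline_curves(), population_stats = w$population_stats
  )
  p15 <- profile$probability[profile$horizon_years == 15]
  expect_equal(round(p15, 4), 0.4714)
})

test_that("all-neutral subjects reproduce the shifted baselines exactly", {
  w <- make_neutral_world(n = 4, seed = 9)
  tables <- neutral_tables()
  profiles <- cohort_risk_profiles(w$subjects, w$features, tables = tables,
                                   population_stats = w$population_stats)
  expect_equal(unique(round(profiles$factor_sum, 12)), 1)
  for (i in seq_len(nrow(profiles))) {
    row <- profiles[i, ]
    expected <- quiet(evaluate_baseline(
      shift_curve(msd_baseline_curves(row$region), row$horizon_years),
      w$subjects$age[w$subjects$id == row$subject_id]
    ))
    expect_equal(row$probability, expected, tolerance = 1e-12)
  }
  # cohort mean equals the age-weighted mean of shifted baselines
  summ <- cohort_summary(profiles)
  for (j in seq_len(nrow(summ$probability))) {
    srow <- summ$probability[j, ]
    curve <- shift_curve(msd_baseline_curves(srow$region), srow$horizon_years)
    expect_equal(srow$mean, mean(quiet(evaluate_baseline(curve, w$subjects$age))),
                 tolerance = 1e-12)
  }
})

test_that("probability is non-decreasing in horizon and increasing in likelihood", {
  w <- small_world(n = 6, seed = 33)
  profiles <- cohort_risk_profiles(w$subjects, w$features,
                                   population_stats = w$population_stats)
  by_subj <- split(profiles, profiles[c("subject_id", "region")], drop = TRUE)
  for (g in by_subj) {
    g <- g[order(g$horizon_years), ]
    expect_true(all(diff(g$probability) >= 0))
  }

  # raising one likelihood strictly raises p (pre-clipping)
  tb <- msd_default_criteria("neck")
  base <- build_element_factors(w$subjects[1, ], w$features, tb, w$population_stats)
  bumped <- tb
  bumped$criteria$sex$levels[] <- bumped$criteria$sex$levels * 1.2
  f2 <- build_element_factors(w$subjects[1, ], w$features, bumped, w$population_stats)
  expect_gt(sum(f2$value), sum(base$value))
})

test_that("cohort summary computes n-1 statistics and factor-sum ranges", {
  profiles <- data.frame(
    subject_id = rep(c("a", "b"), each = 3),
    region = "neck",
    horizon_years = rep(c(5, 10, 15), 2),
    factor_sum = rep(c(1.1, 0.9), each = 3),
    probability = c(0.35, 0.38, 0.4, 0.55, 0.58, 0.6),
    clipped = FALSE, age_out_of_range = FALSE
  )
  s <- cohort_summary(profiles)
  p15 <- s$probability[s$probability$horizon_years == 15, ]
  expect_equal(p15$mean, 0.5)
  expect_equal(p15$sd, sd(c(0.4, 0.6)))
  expect_equal(round(p15$sd, 4), 0.1414)
  expect_equal(s$factor_sum$min, 0.9)
  expect_equal(s$factor_sum$max, 1.1)
  # identical profiles: zero SD
  same <- profiles
  same$probability <- 0.4
  expect_equal(unique(cohort_summary(same)$probability$sd), 0)
  expect_error(cohort_summary(profiles[profiles$subject_id == "a", ]),
               class = "msdrisk_invalid_input")
})

test_that("extreme scenarios match the exhaustive enumeration oracle", {
  curves <- msd_baseline_curves()
  # packaged tables with neutral parametric ranges
  for (tb in msd_default_criteria()) {
    pr <- list(amplitude = c(1, 1), moment = c(1, 1), cumulative_moment = c(1, 1))
    got <- extreme_scenarios(tb, pr, age = 20, horizon = 15, curves[[tb$region]])
    oracle <- enumerate_factor_sums(tb, pr)
    expect_equal(c(got$sx_min, got$sx_max), oracle, tolerance = 1e-12)
    q20 <- quiet(evaluate_baseline(shift_curve(curves[[tb$region]], 15), 20))
    expect_equal(got$p_min, min(1, q20 * oracle[1]), tolerance = 1e-12)
    expect_equal(got$p_max, min(1, q20 * oracle[2]), tolerance = 1e-12)
  }
  # randomized tables with random parametric ranges
  for (seed in 1:8) {
    tb <- random_table(n_criteria = sample(3:6, 1), seed = seed)
    pr <- random_parametric_ranges(tb, seed + 100)
    got <- extreme_scenarios(tb, pr, age = 30, horizon = 10,
                             msd_baseline_curves("neck"))
    expect_equal(c(got$sx_min, got$sx_max), enumerate_factor_sums(tb, pr),
                 tolerance = 1e-12)
  }
  # degenerate ranges with single-level criteria collapse to the baseline
  tb1 <- criteria_table("neck", list(
    criterion_def("fixed", 1, "categorical", c(only = 1)),
    criterion_def("dyn", 1, "parametric")
  ))
  got <- extreme_scenarios(tb1, list(dyn = c(1, 1)), 30, 5, msd_baseline_curves("neck"))
  expect_equal(got$p_min, got$p_max)
  expect_equal(got$p_min, evaluate_baseline(shift_curve(msd_baseline_curves("neck"), 5), 30))

  # widening a range can only widen the bounds
  tb <- msd_default_criteria("neck")
  narrow <- list(amplitude = c(0.9, 1.1), moment = c(1, 1), cumulative_moment = c(1, 1))
  wide <- narrow; wide$amplitude <- c(0.8, 1.3)
  gn <- extreme_scenarios(tb, narrow, 30, 10, msd_baseline_curves("neck"))
  gw <- extreme_scenarios(tb, wide, 30, 10, msd_baseline_curves("neck"))
  expect_lte(gw$p_min, gn$p_min)
  expect_gte(gw$p_max, gn$p_max)

  expect_error(extreme_scenarios(tb, list(), 30, 10, msd_baseline_curves("neck")),
               class = "msdrisk_invalid_input")
})

test_that("dynamic impact is the parametric share of the factor-sum spread", {
  tb <- msd_default_criteria("neck")
  # degenerate parametric ranges: all spread is categorical
  d0 <- dynamic_impact(tb, list(amplitude = c(1, 1), moment = c(1, 1),
                                cumulative_moment = c(1, 1)))
  expect_equal(d0$percent, 0)
  # flat categorical levels: all spread is parametric
  flat <- tb
  flat$criteria <- lapply(flat$criteria, function(cr) {
    if (cr$kind != "parametric") cr$levels[] <- 1
    cr
  })
  d100 <- dynamic_impact(flat, list(amplitude = c(0.8, 1.2), moment = c(0.9, 1.1),
                                    cumulative_moment = c(0.7, 1.4)))
  expect_equal(d100$percent, 100)
  expect_match(d100$definition, "a_max - a_min", fixed = TRUE)

  # randomized tables agree with brute-force enumeration of both spreads
  for (seed in 1:8) {
    tb_r <- random_table(n_criteria = sample(3:6, 1), seed = seed + 300)
    pr <- random_parametric_ranges(tb_r, seed + 400)
    kinds <- vapply(tb_r$criteria, `[[`, character(1), "kind")
    if (!any(kinds == "parametric")) next
    got <- dynamic_impact(tb_r, pr)
    total <- diff(enumerate_factor_sums(tb_r, pr))
    # parametric-only: pin every non-parametric criterion to a single level
    pinned <- tb_r
    pinned$criteria <- lapply(pinned$criteria, function(cr) {
      if (cr$kind != "parametric") cr$levels <- cr$levels[1]
      if (cr$kind == "proportional") cr$kind <- "categorical"
      criterion_def(cr$name, cr$weight_score, cr$kind, cr$levels)
    })
    pinned <- criteria_table(tb_r$region, pinned$criteria)
    param_only <- diff(enumerate_factor_sums(pinned, pr))
    expect_equal(got$percent, 100 * param_only / total, tolerance = 1e-12)
  }

  # zero total spread is degenerate
  frozen <- criteria_table("neck", list(
    criterion_def("a", 1, "categorical", c(x = 1)),
    criterion_def("b", 1, "parametric")
  ))
  expect_error(dynamic_impact(frozen, list(b = c(1, 1))),
               class = "msdrisk_degenerate_input")
})

test_that("sex comparison reports the male-vs-female percentage difference", {
  profiles <- data.frame(
    subject_id = c("m1", "f1"), region = "neck", horizon_years = 15,
    factor_sum = 1, probability = c(0.55, 0.5),
    clipped = FALSE, age_out_of_range = FALSE
  )
  subjects <- data.frame(id = c("m1", "f1"), sex = c("male", "female"))
  cmp <- sex_comparison(profiles, subjects)
  expect_equal(cmp$percent_difference, 10)

  # identical distributions: zero difference
  same <- rbind(profiles, profiles)
  same$subject_id <- c("m1", "f1", "m2", "f2")
  same$probability <- 0.4
  subjects2 <- data.frame(id = same$subject_id,
                          sex = c("male", "female", "male", "female"))
  expect_equal(sex_comparison(same, subjects2)$percent_difference, 0)

  # a +10% male shift by construction is recovered on a synthetic cohort
  w <- small_world(n = 30, seed = 77, noise_cv = 0)
  profiles_w <- cohort_risk_profiles(w$subjects, w$features,
                                     population_stats = w$population_stats,
                                     tables = neutral_tables())
  p <- profiles_w[profiles_w$horizon_years == 15, ]
  p$probability <- p$probability *
    ifelse(w$subjects$sex[match(p$subject_id, w$subjects$id)] == "male", 1.1, 1)
  # neutralize the age confound: compare against per-sex baseline means
  got <- sex_comparison(p, w$subjects)
  base <- sex_comparison(profiles_w[profiles_w$horizon_years == 15, ], w$subjects)
  for (r in got$region) {
    lift <- (1 + got$percent_difference[got$region == r] / 100) /
      (1 + base$percent_difference[base$region == r] / 100)
    expect_equal(lift, 1.1, tolerance = 1e-9)
  }

  expect_error(sex_comparison(profiles[1, ], subjects[1, ]),
               class = "msdrisk_invalid_input")
})

test_that("profiles are bit-identical across repeated runs of the same config", {
  w <- small_world(n = 5, seed = 13)
  p1 <- cohort_risk_profiles(w$subjects, w$features,
                             population_stats = w$population_stats)
  p2 <- cohort_risk_profiles(w$subjects, w$features,
                             population_stats = w$population_stats)
  expect_identical(p1, p2)
})
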