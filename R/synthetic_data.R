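#' Specification of a synthetic cohort
#'
#' Defaults reproduce the reference patient-lifting cohort: 44 subjects
#' (16 male, 28 female), age 28 +/- 12 years (truncated to \[18, 70\]),
#' height 175.11 +/- 11.58 cm, weight 75.30 +/- 12.58 kg, and a 1-10
#' physical-readiness score drawn from a triangular distribution peaking
#' at 7 (a relatively wide spread across fitness levels).
#'
#' @param n_subjects Number of subjects. Default 44.
#' @param male_fraction Fraction of male subjects; the realized split matches
#'   the fraction exactly when `n * fraction` is whole, otherwise the nearest
#'   split is used with a warning. Default 16/44.
#' @param age_mean,age_sd Age distribution (years). Defaults 28, 12.
#' @param height_mean,height_sd Height distribution (cm). Defaults 175.11, 11.58.
#' @param weight_mean,weight_sd Weight distribution (kg). Defaults 75.30, 12.58.
#' @param readiness_distribution Probability vector over scores 1..10; must
#'   sum to 1. Default triangular with apex at 7.
#' @param scenario_mix Named shares over `no_belt`/`belt` exposure, summing
#'   to 1. Default `c(no_belt = 2/3, belt = 1/3)`: of the three recorded
#'   lifting scenarios, two are beltless.
#' @param seed Master seed; every subject derives an independent stream from
#'   it, so growing the cohort never reshuffles existing subjects.
#' @return List of class `msd_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 44, male_fraction = 16 / 44,
                        age_mean = 28, age_sd = 12,
                        height_mean = 175.11, height_sd = 11.58,
                        weight_mean = 75.30, weight_sd = 12.58,
                        readiness_distribution = default_readiness_distribution(),
                        scenario_mix = c(no_belt = 2 / 3, belt = 1 / 3),
                        seed = 1L) {
  if (!is_scalar_number(n_subjects) || n_subjects < 1) {
    abort_input("n_subjects must be >= 1")
  }
  if (male_fraction < 0 || male_fraction > 1) abort_input("male_fraction must be in [0, 1]")
  sds <- c(age_sd, height_sd, weight_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) abort_input("SDs must be >= 0")
  if (length(readiness_distribution) != 10L ||
      abs(sum(readiness_distribution) - 1) > 1e-9 ||
      any(readiness_distribution < 0)) {
    abort_input("readiness_distribution must be 10 non-negative probabilities summing to 1")
  }
  if (abs(sum(scenario_mix) - 1) > 1e-9 || any(scenario_mix < 0)) {
    abort_input("scenario_mix shares must be non-negative and sum to 1")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), male_fraction = male_fraction,
         age_mean = age_mean, age_sd = age_sd,
         height_mean = height_mean, height_sd = height_sd,
         weight_mean = weight_mean, weight_sd = weight_sd,
         readiness_distribution = readiness_distribution,
         scenario_mix = scenario_mix, seed = as.integer(seed)),
    class = "msd_cohort_spec"
  )
}

default_readiness_distribution <- function() {
  w <- c(1:7, 7 * (11 - (8:10)) / 4)  # triangular apex at score 7
  w / sum(w)
}

#' Specification of injected generative effects
#'
#' The magnitudes of segment effects built into synthetic trials. The
#' reference study reports no effect sizes for these contrasts, so the
#' defaults are order-of-magnitude choices: male lifts use a 10% larger
#' range of motion, an ergonomic belt lowers joint moments by 10%, and
#' higher fitness lowers moments slightly.
#'
#' @param male_rom_multiplier Ratio applied to male angular amplitude. Default 1.1.
#' @param belt_moment_multiplier Ratio applied to moments in the belt
#'   scenario. Default 0.9.
#' @param readiness_moment_multipliers Named ratios per readiness group.
#'   Default `c(low = 1.05, medium = 1.00, high = 0.95)`.
#' @param trial_noise_cv Coefficient of variation of multiplicative
#'   trial-to-trial noise. Default 0.05.
#' @param trials_per_scenario Repeated trials per scenario. Default 3.
#' @return List of class `msd_effect_spec`.
#' @export
effect_spec <- function(male_rom_multiplier = 1.1,
                        belt_moment_multiplier = 0.9,
                        readiness_moment_multipliers = c(low = 1.05, medium = 1.00, high = 0.95),
                        trial_noise_cv = 0.05,
                        trials_per_scenario = 3L) {
  mult <- c(male_rom_multiplier, belt_moment_multiplier, readiness_moment_multipliers)
  if (any(!is.finite(mult)) || any(mult <= 0)) abort_input("multipliers must be > 0")
  if (!is_scalar_number(trial_noise_cv) || trial_noise_cv < 0) {
    abort_input("trial_noise_cv must be >= 0")
  }
  if (!is_scalar_number(trials_per_scenario) || trials_per_scenario < 1) {
    abort_input("trials_per_scenario must be >= 1")
  }
  if (!all(c("low", "medium", "high") %in% names(readiness_moment_multipliers))) {
    abort_input("readiness_moment_multipliers needs low/medium/high entries")
  }
  structure(
    list(male_rom_multiplier = male_rom_multiplier,
         belt_moment_multiplier = belt_moment_multiplier,
         readiness_moment_multipliers = readiness_moment_multipliers,
         trial_noise_cv = trial_noise_cv,
         trials_per_scenario = as.integer(trials_per_scenario)),
    class = "msd_effect_spec"
  )
}

# Deterministic per-subject substream seed below 2^31.
subject_seed <- function(seed, index, salt = 0L) {
  ((as.double(seed) %% 2147483629) * 48271 + index * 7919 + salt * 104729) %% 2147483629
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Generate a synthetic cohort
#'
#' Deterministic for a fixed spec seed; subject `i` is generated from its own
#' derived random stream, so changing `n_subjects` leaves earlier subjects
#' untouched. Sexes are allocated to match `male_fraction` exactly (the first
#' `round(n * fraction)` subjects are male), not drawn stochastically.
#'
#' @param spec An [cohort_spec()].
#' @return Subject data frame: `id, sex, age, height_cm, weight_kg,
#'   readiness_score, readiness_group, no_belt_share, belt_share`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "msd_cohort_spec"))
  n <- spec$n_subjects
  n_male <- round(n * spec$male_fraction)
  if (abs(n_male - n * spec$male_fraction) > 1e-9) {
    warn_msd(sprintf("exact male fraction %.4f impossible with n=%d; using %d males",
                     spec$male_fraction, n, n_male))
  }
  rows <- lapply(seq_len(n), function(i) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
            add = TRUE)
    set.seed(subject_seed(spec$seed, i))
    score <- sample.int(10, 1, prob = spec$readiness_distribution)
    data.frame(
      id = sprintf("S%03d", i),
      sex = if (i <= n_male) "male" else "female",
      age = rnorm_trunc(1, spec$age_mean, spec$age_sd, 18, 70),
      height_cm = rnorm_trunc(1, spec$height_mean, spec$height_sd, 120, 230),
      weight_kg = rnorm_trunc(1, spec$weight_mean, spec$weight_sd, 35, 200),
      readiness_score = score,
      readiness_group = readiness_group(score),
      no_belt_share = unname(spec$scenario_mix[["no_belt"]]),
      belt_share = unname(spec$scenario_mix[["belt"]]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Parametric lift profile constants: sin^2 excursion from the neutral pose,
# per-joint base amplitude (deg) and per-kg peak moment (N·m/kg), and a
# consistent left/right load asymmetry.
JOINT_SIDES <- data.frame(
  joint = c("neck", "shoulder", "shoulder", "elbow", "elbow"),
  side = c("midline", "left", "right", "left", "right"),
  stringsAsFactors = FALSE
)
BASE_AMPLITUDE_DEG <- c(neck = 45, shoulder = 120, elbow = 90)
MOMENT_PER_KG <- c(neck = 0.5, shoulder = 1.1, elbow = 0.7)
SIDE_FACTOR <- c(left = 0.94, right = 1.06, midline = 1)

#' Generate synthetic lifting trials for one subject and scenario
#'
#' Angle and moment follow smooth `sin^2` lift profiles starting and ending
#' in the neutral pose. Peak moment scales with body weight; the belt
#' scenario multiplies moments by the belt multiplier, male subjects use a
#' larger angular amplitude, and readiness scales moments per group.
#' Trial-to-trial variability is multiplicative with the configured CV.
#'
#' @param subject One-row subject record (see [generate_cohort()]).
#' @param scenario `"no_assist"`, `"patient_assist"` or `"belt"`.
#' @param effects An [effect_spec()].
#' @param seed Seed for this subject/scenario block.
#' @param duration_s Trial duration in seconds. Default 4.
#' @param n_points Samples per trial. Default 41.
#' @return Long-format trial data frame (`subject_id, scenario, trial, joint,
#'   side, time_s, angle_deg, moment_Nm`).
#' @export
generate_trials <- function(subject, scenario = c("no_assist", "patient_assist", "belt"),
                            effects = effect_spec(), seed = 1L,
                            duration_s = 4, n_points = 41L) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(effects, "msd_effect_spec"))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% 2147483629))

  time <- seq(0, duration_s, length.out = n_points)
  profile <- sin(pi * time / duration_s)^2
  rom_mult <- if (subject$sex == "male") effects$male_rom_multiplier else 1
  mom_mult <- unname(effects$readiness_moment_multipliers[[subject$readiness_group]])
  if (scenario == "belt") mom_mult <- mom_mult * effects$belt_moment_multiplier

  trials <- lapply(seq_len(effects$trials_per_scenario), function(tr) {
    noise <- pmax(0.2, 1 + effects$trial_noise_cv *
                    stats::rnorm(2 * nrow(JOINT_SIDES)))
    blocks <- lapply(seq_len(nrow(JOINT_SIDES)), function(j) {
      joint <- JOINT_SIDES$joint[j]
      side <- JOINT_SIDES$side[j]
      amp <- BASE_AMPLITUDE_DEG[[joint]] * rom_mult * noise[2 * j - 1]
      peak <- MOMENT_PER_KG[[joint]] * subject$weight_kg * SIDE_FACTOR[[side]] *
        mom_mult * noise[2 * j]
      data.frame(
        subject_id = subject$id, scenario = scenario, trial = tr,
        joint = joint, side = side, time_s = time,
        angle_deg = amp * profile, moment_Nm = peak * profile,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, blocks)
  })
  out <- do.call(rbind, trials)
  rownames(out) <- NULL
  out
}

#' Generate all trials for a cohort
#'
#' Every subject performs all three scenarios, `trials_per_scenario` times
#' each. Each subject x scenario block uses an independent derived stream.
#'
#' @param subjects Data frame from [generate_cohort()].
#' @param effects An [effect_spec()].
#' @param seed Master seed.
#' @param ... Passed to [generate_trials()] (`duration_s`, `n_points`).
#' @return Long-format trial data frame for the whole cohort.
#' @export
generate_cohort_trials <- function(subjects, effects = effect_spec(), seed = 1L, ...) {
  check_subjects_min(subjects)
  scenarios <- c("no_assist", "patient_assist", "belt")
  blocks <- list()
  for (i in seq_len(nrow(subjects))) {
    for (s in seq_along(scenarios)) {
      blocks[[length(blocks) + 1L]] <- generate_trials(
        subjects[i, , drop = FALSE], scenarios[s], effects,
        seed = subject_seed(seed, i, salt = s), ...
      )
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

check_subjects_min <- function(subjects) {
  need <- c("id", "sex", "weight_kg", "readiness_group")
  missing <- setdiff(need, names(subjects))
  if (length(missing)) {
    abort_input(sprintf("subjects table missing columns: %s",
                        paste(missing, collapse = ", ")))
  }
  invisible(subjects)
}

#' Map recorded scenarios onto the two technique levels
#'
#' The technique criterion has two levels (with / without belt); the two
#' beltless recording scenarios (patient assisting or not) pool into the
#' `no_belt` level.
#'
#' @param scenario Character vector of scenario labels.
#' @return Character vector of `"no_belt"` / `"belt"`.
#' @export
technique_level <- function(scenario) {
  ifelse(scenario == "belt", "belt", "no_belt")
}

#' Write a small golden reference bundle
#'
#' Generates a 6-subject cohort with one trial per scenario on a coarse
#' 11-sample grid, extracts its features, and writes `subjects.csv`,
#' `trials.csv`, `expected_features.csv` and `expected_side_shares.csv` to
#' `dir`. Byte-identical across runs for a fixed seed (values are rounded to
#' 6 significant digits before writing).
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed. Default 101.
#' @return Named character vector of file paths, invisibly.
#' @export
generate_reference_bundle <- function(dir, seed = 101L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  spec <- cohort_spec(n_subjects = 6, male_fraction = 0.5, seed = seed)
  subjects <- generate_cohort(spec)
  effects <- effect_spec(trials_per_scenario = 1L)
  trials <- generate_cohort_trials(subjects, effects, seed = seed, n_points = 11L)
  fs <- extract_features(trials)

  num <- vapply(subjects, is.numeric, logical(1))
  subjects[num] <- lapply(subjects[num], signif, 6)
  trials$time_s <- signif(trials$time_s, 6)
  trials$angle_deg <- signif(trials$angle_deg, 6)
  trials$moment_Nm <- signif(trials$moment_Nm, 6)
  feats <- fs$features
  feats[PARAMETRIC_METRICS] <- lapply(feats[PARAMETRIC_METRICS], signif, 6)
  shares <- fs$side_shares
  shares[c("left_share", "right_share")] <-
    lapply(shares[c("left_share", "right_share")], signif, 6)

  paths <- c(
    subjects = file.path(dir, "subjects.csv"),
    trials = file.path(dir, "trials.csv"),
    features = file.path(dir, "expected_features.csv"),
    side_shares = file.path(dir, "expected_side_shares.csv")
  )
  utils::write.csv(subjects, paths[["subjects"]], row.names = FALSE)
  utils::write.csv(trials, paths[["trials"]], row.names = FALSE)
  utils::write.csv(feats, paths[["features"]], row.names = FALSE)
  utils::write.csv(shares, paths[["side_shares"]], row.names = FALSE)
  invisible(paths)
}
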