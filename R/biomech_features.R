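#' Range of motion of an angle series
#'
#' The amplitude criterion: the difference between the largest and smallest
#' joint angle reached during a trial.
#'
#' @param angle_series Joint angles in degrees, length >= 2.
#' @return Range of motion in degrees (>= 0).
#' @export
compute_rom <- function(angle_series) {
  if (length(angle_series) < 2L || any(!is.finite(angle_series))) {
    abort_input("angle_series must hold at least 2 finite values")
  }
  max(angle_series) - min(angle_series)
}

#' Maximum joint moment of a series
#'
#' Peak loading is taken on the absolute moment, so flexion and extension
#' peaks are treated alike.
#'
#' @param moment_series Joint moments in N·m, length >= 1.
#' @return Maximum absolute moment in N·m.
#' @export
compute_max_moment <- function(moment_series) {
  if (length(moment_series) < 1L || any(!is.finite(moment_series))) {
    abort_input("moment_series must hold at least 1 finite value")
  }
  max(abs(moment_series))
}

#' Cumulative joint moment over a trial
#'
#' Trapezoidal integral of the absolute moment over time, in N·m·s — the
#' chronic-exposure proxy. Integrating the magnitude keeps flexion and
#' extension phases from cancelling.
#'
#' @param moment_series Joint moments in N·m.
#' @param time Strictly increasing time stamps in seconds, same length.
#' @return Cumulative moment in N·m·s (>= 0).
#' @export
compute_cumulative_moment <- function(moment_series, time) {
  if (length(moment_series) != length(time)) {
    abort_input("moment_series and time must be the same length")
  }
  if (length(time) < 2L || any(!is.finite(time)) || any(diff(time) <= 0)) {
    abort_input("time must be strictly increasing with at least 2 samples")
  }
  if (any(!is.finite(moment_series))) abort_input("moment_series must be finite")
  y <- abs(moment_series)
  sum(diff(time) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Left/right load shares from cumulative moments
#'
#' Expresses side asymmetry as the proportional contribution of each limb,
#' e.g. a 40/60 split, used as shares in [blend_likelihoods()].
#'
#' @param left_cumulative,right_cumulative Cumulative moments in N·m·s, >= 0,
#'   not both zero.
#' @return Named numeric `c(left = , right = )` summing to 1.
#' @export
compute_side_shares <- function(left_cumulative, right_cumulative) {
  if (!is_scalar_number(left_cumulative) || !is_scalar_number(right_cumulative) ||
      left_cumulative < 0 || right_cumulative < 0) {
    abort_input("cumulative moments must be non-negative numbers")
  }
  total <- left_cumulative + right_cumulative
  if (total == 0) abort_degenerate("both sides have zero cumulative moment")
  c(left = left_cumulative / total, right = right_cumulative / total)
}

#' Derive an element likelihood from segment and population means
#'
#' Under the model's linearity assumption, a segment whose mean metric is 5%
#' above the population mean carries likelihood 1.05; 10% below, 0.9. The
#' ratio is clipped (default into \[0.1, 3\]) so a single corrupt trial
#' cannot blow up the factor sum.
#'
#' @param segment_mean Segment mean of the metric (any units).
#' @param population_mean Population mean, same units, > 0.
#' @param clip Length-2 clipping bounds for the ratio.
#' @return Dimensionless likelihood ratio.
#' @export
derive_likelihood <- function(segment_mean, population_mean, clip = c(0.1, 3.0)) {
  if (!is_scalar_number(population_mean) || population_mean <= 0) {
    abort_input("population_mean must be > 0")
  }
  if (any(!is.finite(segment_mean))) abort_input("segment_mean must be finite")
  a <- segment_mean / population_mean
  if (any(a < clip[1] | a > clip[2])) {
    warn_msd(sprintf("likelihood ratio clipped into [%g, %g]", clip[1], clip[2]),
             class = "msdrisk_clip_warning")
    a <- pmin(clip[2], pmax(clip[1], a))
  }
  a
}

#' Composite parametric deviation score
#'
#' Combines the three parametric deviation ratios — range of motion, maximum
#' moment, cumulative moment — with 1:1:2 weights, prioritizing cumulative
#' moment as the long-term exposure measure: `(r + m + 2c) / 4`.
#'
#' This single-score pathway is an alternative to treating the three metrics
#' as independent criteria rows; the pipeline default keeps them independent.
#'
#' @param rom_dev,maxmom_dev,cummom_dev Deviation ratios (> 0), each the
#'   subject metric divided by the population mean.
#' @return Weighted mean ratio.
#' @export
composite_parametric_score <- function(rom_dev, maxmom_dev, cummom_dev) {
  vals <- c(rom_dev, maxmom_dev, cummom_dev)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort_input("all deviation ratios must be > 0")
  }
  (rom_dev + maxmom_dev + 2 * cummom_dev) / 4
}

PARAMETRIC_METRICS <- c("rom_deg", "max_moment_Nm", "cumulative_moment_Nms")

#' Per-trial features from a long-format trial table
#'
#' @param trials Data frame with columns `subject_id, scenario, joint, side,
#'   time_s, angle_deg, moment_Nm` and optionally `trial` (defaults to 1).
#' @return Data frame with one row per subject x scenario x trial x joint x
#'   side and columns `rom_deg`, `max_moment_Nm`, `cumulative_moment_Nms`.
#' @export
trial_features <- function(trials) {
  check_trial_columns(trials)
  if (is.null(trials$trial)) trials$trial <- 1L
  key <- interaction(trials$subject_id, trials$scenario, trials$trial,
                     trials$joint, trials$side, drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(trials)), key)
  rows <- lapply(idx, function(i) {
    i <- i[order(trials$time_s[i])]
    data.frame(
      subject_id = trials$subject_id[i[1]],
      scenario = trials$scenario[i[1]],
      trial = trials$trial[i[1]],
      joint = trials$joint[i[1]],
      side = trials$side[i[1]],
      rom_deg = compute_rom(trials$angle_deg[i]),
      max_moment_Nm = compute_max_moment(trials$moment_Nm[i]),
      cumulative_moment_Nms = compute_cumulative_moment(trials$moment_Nm[i],
                                                        trials$time_s[i]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

check_trial_columns <- function(trials) {
  need <- c("subject_id", "scenario", "joint", "side",
            "time_s", "angle_deg", "moment_Nm")
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    abort_input(sprintf("trial table missing columns: %s",
                        paste(missing, collapse = ", ")))
  }
  invisible(trials)
}

#' Subject-level feature set from trials
#'
#' Averages each parametric metric over the subject's repeated trials and
#' scenarios (per joint and side), and derives per-joint left/right load
#' shares from the side cumulative moments. Since the model assumes a
#' subject's technique is constant over the forecast horizon, these
#' per-subject averages are the features that enter the risk model.
#'
#' @param trials Long-format trial table; see [trial_features()].
#' @return List of class `msd_feature_set`: `features` (subject x joint x
#'   side metric means) and `side_shares` (subject x joint left/right
#'   shares; midline joints get 0.5/0.5).
#' @export
extract_features <- function(trials) {
  per_trial <- trial_features(trials)
  agg <- stats::aggregate(
    per_trial[PARAMETRIC_METRICS],
    by = per_trial[c("subject_id", "joint", "side")],
    FUN = mean
  )
  agg <- agg[order(agg$subject_id, agg$joint, agg$side), , drop = FALSE]
  rownames(agg) <- NULL

  share_rows <- lapply(split(agg, agg[c("subject_id", "joint")], drop = TRUE),
    function(g) {
      left <- g$cumulative_moment_Nms[g$side == "left"]
      right <- g$cumulative_moment_Nms[g$side == "right"]
      if (length(left) == 1L && length(right) == 1L) {
        sh <- compute_side_shares(left, right)
      } else {
        sh <- c(left = 0.5, right = 0.5)
      }
      data.frame(subject_id = g$subject_id[1], joint = g$joint[1],
                 left_share = unname(sh["left"]), right_share = unname(sh["right"]),
                 stringsAsFactors = FALSE)
    })
  shares <- do.call(rbind, share_rows)
  shares <- shares[order(shares$subject_id, shares$joint), , drop = FALSE]
  rownames(shares) <- NULL
  structure(list(features = agg, side_shares = shares),
            class = "msd_feature_set")
}

#' Per-segment means and derived likelihoods
#'
#' Splits rows by a grouping column, computes per-segment means of each
#' metric, and derives each segment's element likelihood as segment mean /
#' grand mean via [derive_likelihood()]. This is how categorical likelihoods
#' (by sex, readiness group, scenario, ...) are estimated from data.
#'
#' @param df Data frame holding the metrics and the grouping column.
#' @param by Name of the grouping column.
#' @param metrics Character vector of metric columns; default the three
#'   parametric metrics.
#' @param clip Likelihood clipping bounds, see [derive_likelihood()].
#' @return Data frame with one row per segment x metric: `segment`, `metric`,
#'   `n`, `segment_mean`, `grand_mean`, `likelihood`.
#' @export
segment_population <- function(df, by, metrics = PARAMETRIC_METRICS,
                               clip = c(0.1, 3.0)) {
  if (!is.data.frame(df) || nrow(df) == 0L) abort_input("df must be a non-empty data frame")
  if (!by %in% names(df)) abort_input(sprintf("grouping column '%s' not found", by))
  missing <- setdiff(metrics, names(df))
  if (length(missing)) {
    abort_input(sprintf("metric columns missing: %s", paste(missing, collapse = ", ")))
  }
  groups <- split(df, df[[by]], drop = TRUE)
  small <- names(groups)[vapply(groups, nrow, integer(1)) < 2L]
  if (length(small)) {
    warn_msd(sprintf("segments with fewer than 2 rows: %s",
                     paste(small, collapse = ", ")))
  }
  rows <- list()
  for (metric in metrics) {
    grand <- mean(df[[metric]])
    for (seg in names(groups)) {
      m <- mean(groups[[seg]][[metric]])
      rows[[length(rows) + 1L]] <- data.frame(
        segment = seg, metric = metric, n = nrow(groups[[seg]]),
        segment_mean = m, grand_mean = grand,
        likelihood = derive_likelihood(m, grand, clip = clip),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Split a continuous capture into trials at neutral-pose dwells
#'
#' Convenience segmentation of a raw capture that starts and ends each lift
#' in the neutral standing pose (N-pose): samples whose angle stays within
#' `tol_deg` of the initial angle for at least `min_dwell_s` seconds mark
#' trial boundaries. Provided as a utility; recorded data are normally
#' supplied pre-segmented.
#'
#' @param time Strictly increasing time stamps (s).
#' @param angle Joint angle series (degrees), same length.
#' @param tol_deg Angular tolerance around the initial pose. Default 5.
#' @param min_dwell_s Minimum dwell duration to count as a boundary. Default 0.5.
#' @return Integer vector of trial labels, same length as `time` (0 marks
#'   neutral dwell samples between trials).
#' @export
split_trials <- function(time, angle, tol_deg = 5, min_dwell_s = 0.5) {
  if (length(time) != length(angle)) abort_input("time and angle must align")
  if (any(diff(time) <= 0)) abort_input("time must be strictly increasing")
  neutral <- abs(angle - angle[1]) <= tol_deg
  # keep only dwells of sufficient duration as boundaries
  r <- rle(neutral)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_boundary <- rep(FALSE, length(time))
  for (k in seq_along(r$values)) {
    if (r$values[k] && time[ends[k]] - time[starts[k]] >= min_dwell_s) {
      is_boundary[starts[k]:ends[k]] <- TRUE
    }
  }
  labels <- integer(length(time))
  current <- 0L
  in_trial <- FALSE
  for (i in seq_along(time)) {
    if (is_boundary[i]) {
      in_trial <- FALSE
    } else {
      if (!in_trial) {
        current <- current + 1L
        in_trial <- TRUE
      }
      labels[i] <- current
    }
  }
  labels
}
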