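#' Define a single risk criterion
#'
#' A criterion is one row block of a criteria table: an integer weight score
#' `B` expressing its relative importance, a kind, and (for level-based kinds)
#' a set of named element likelihoods `a`. Likelihoods are dimensionless
#' ratios: values above 1 raise risk relative to the population average,
#' values below 1 lower it.
#'
#' @param name Identifier, unique within a table.
#' @param weight_score Positive integer weight score `B`.
#' @param kind One of `"categorical"` (subject belongs to exactly one level),
#'   `"proportional"` (exactly two levels blended by continuous shares, e.g.
#'   left/right symmetry or with/without an ergonomic belt), or
#'   `"parametric"` (likelihood computed per subject as a ratio of a motion
#'   metric to its population mean; no fixed levels).
#' @param levels Named numeric vector of element likelihoods; empty for
#'   parametric criteria.
#' @return An object of class `msd_criterion`.
#' @export
criterion_def <- function(name, weight_score,
                          kind = c("categorical", "parametric", "proportional"),
                          levels = numeric()) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort_input("criterion `name` must be a non-empty string")
  }
  if (!is_scalar_number(weight_score) || weight_score < 1 ||
      weight_score != round(weight_score)) {
    abort_input(sprintf("weight_score for '%s' must be a positive integer", name))
  }
  levels <- unlist(levels)
  if (kind == "parametric") {
    if (length(levels) > 0L) {
      abort_input(sprintf("parametric criterion '%s' must not define levels", name))
    }
  } else {
    if (length(levels) < 1L || is.null(names(levels)) || any(!nzchar(names(levels)))) {
      abort_input(sprintf("criterion '%s' needs named likelihood levels", name))
    }
    if (any(!is.finite(levels)) || any(levels <= 0)) {
      abort_input(sprintf("likelihoods of '%s' must all be > 0", name))
    }
    if (kind == "proportional" && length(levels) != 2L) {
      abort_input(sprintf("proportional criterion '%s' must have exactly two levels", name))
    }
  }
  structure(
    list(name = name, weight_score = as.integer(weight_score),
         kind = kind, levels = levels),
    class = "msd_criterion"
  )
}

#' Assemble a criteria table for one body region
#'
#' Houses the weight scores `B_i` and likelihood levels `a_ij` for one region
#' (neck, shoulder or elbow). Weight coefficients `q_i = B_i / sum(B)` are
#' derived on demand under the table's rounding mode.
#'
#' @param region `"neck"`, `"shoulder"` or `"elbow"`.
#' @param criteria List of [criterion_def()] objects with unique names.
#' @param rounding_mode `"exact"` (full precision; the default engine mode),
#'   `"display3"` (coefficients rounded half-even to 3 decimals), or
#'   `"table_match"` (rounded to 3 decimals, then the last largest
#'   coefficient absorbs the rounding defect so the displayed set sums to
#'   exactly 1.000 — this reproduces published tables).
#' @param notes Optional character annotation carried through serialization.
#' @return An object of class `msd_criteria_table`.
#' @export
criteria_table <- function(region, criteria,
                           rounding_mode = c("exact", "display3", "table_match"),
                           notes = NULL) {
  region <- check_region(region)
  rounding_mode <- match.arg(rounding_mode)
  if (!is.list(criteria) || length(criteria) < 1L ||
      !all(vapply(criteria, inherits, logical(1), "msd_criterion"))) {
    abort_input("`criteria` must be a non-empty list of criterion_def objects")
  }
  nms <- vapply(criteria, `[[`, character(1), "name")
  if (anyDuplicated(nms)) abort_input("criterion names must be unique")
  names(criteria) <- nms
  structure(
    list(region = region, criteria = criteria, rounding_mode = rounding_mode,
         notes = notes),
    class = "msd_criteria_table"
  )
}

#' @export
print.msd_criteria_table <- function(x, ...) {
  q <- weight_coefficients(x)
  cat(sprintf("<msd_criteria_table> region: %s, %d criteria, rounding: %s\n",
              x$region, length(x$criteria), x$rounding_mode))
  for (cr in x$criteria) {
    lv <- if (cr$kind == "parametric") "<parametric>" else
      paste(sprintf("%s=%.3f", names(cr$levels), cr$levels), collapse = ", ")
    cat(sprintf("  %-20s B=%d q=%.3f %-12s %s\n",
                cr$name, cr$weight_score, q[[cr$name]], cr$kind, lv))
  }
  if (!is.null(x$notes)) cat("  note:", x$notes, "\n")
  invisible(x)
}

#' Weight coefficients from integer weight scores
#'
#' Normalizes integer weight scores `B_i` to coefficients
#' `q_i = B_i / sum(B)`. In `exact` mode the coefficients sum to 1 to machine
#' precision. `display3` rounds each half-even to 3 decimals (displayed sets
#' may then sum to 0.999 or 1.001). `table_match` additionally adds the sum
#' defect to the last occurrence of the largest coefficient so the displayed
#' set sums to exactly 1.000, matching published table conventions.
#'
#' @param weight_scores Vector of positive integers.
#' @param rounding_mode See [criteria_table()].
#' @return Numeric vector of coefficients, same length and names as the input.
#' @examples
#' compute_weight_coefficients(c(1, 1, 1, 1, 1, 2), "table_match")
#' @export
compute_weight_coefficients <- function(weight_scores,
                                        rounding_mode = c("exact", "display3", "table_match")) {
  rounding_mode <- match.arg(rounding_mode)
  if (length(weight_scores) < 1L) abort_input("weight_scores must be non-empty")
  if (any(!is.finite(weight_scores)) || any(weight_scores < 1) ||
      any(weight_scores != round(weight_scores))) {
    abort_input("all weight scores must be positive integers")
  }
  q <- weight_scores / sum(weight_scores)
  if (rounding_mode == "exact") return(q)
  qr <- round_half_even(q, 3)
  if (rounding_mode == "table_match") {
    defect <- 1 - sum(qr)
    if (abs(defect) > 1e-12) {
      j <- max(which(qr == max(qr)))
      qr[j] <- round_half_even(qr[j] + defect, 3)
    }
  }
  qr
}

#' Weight coefficients of a criteria table
#'
#' @param table An [criteria_table()] object.
#' @param rounding_mode Optional override of the table's rounding mode.
#' @return Named numeric vector of `q_i`, one per criterion.
#' @export
weight_coefficients <- function(table, rounding_mode = NULL) {
  stopifnot(inherits(table, "msd_criteria_table"))
  mode <- rounding_mode %||% table$rounding_mode
  B <- vapply(table$criteria, `[[`, integer(1), "weight_score")
  compute_weight_coefficients(B, mode)
}

#' Element factor: likelihood times weight
#'
#' The element factor `X = a * q` is one summand of the factor sum that
#' scales the baseline probability. Under a display rounding mode the product
#' is rounded half-even to 3 decimals, matching printed table cells.
#'
#' @param likelihood Element likelihood `a` (> 0).
#' @param weight Weight coefficient `q` in (0, 1].
#' @param rounding_mode See [criteria_table()].
#' @return The factor value `X` (numeric scalar; vectorized over inputs).
#' @examples
#' element_factor(1.120, 1 / 7, rounding_mode = "display3") # 0.160
#' @export
element_factor <- function(likelihood, weight, rounding_mode = "exact") {
  if (any(!is.finite(likelihood)) || any(likelihood <= 0)) {
    abort_input("likelihood must be > 0")
  }
  if (any(!is.finite(weight)) || any(weight <= 0) || any(weight > 1)) {
    abort_input("weight must be in (0, 1]")
  }
  x <- likelihood * weight
  if (rounding_mode %in% c("display3", "table_match")) x <- round_half_even(x, 3)
  x
}

#' Blend two element likelihoods by continuous shares
#'
#' For proportional criteria (side symmetry, technique with/without belt) the
#' subject's likelihood is the share-weighted mixture
#' `a = a1 * c1 + a2 * c2` with `c1 + c2 = 1`, so a 40/60 side split blends
#' the two level likelihoods in that ratio.
#'
#' @param a_pair Numeric length-2: the two level likelihoods.
#' @param shares Numeric length-2, non-negative, summing to 1 (tolerance 1e-9).
#' @return Blended likelihood, guaranteed within `range(a_pair)`.
#' @export
blend_likelihoods <- function(a_pair, shares) {
  if (length(a_pair) != 2L || length(shares) != 2L) {
    abort_input("blend_likelihoods needs two likelihoods and two shares")
  }
  if (any(!is.finite(shares)) || any(shares < 0) || abs(sum(shares) - 1) > 1e-9) {
    abort_input("shares must be non-negative and sum to 1")
  }
  if (any(!is.finite(a_pair)) || any(a_pair <= 0)) {
    abort_input("likelihoods must be > 0")
  }
  sum(a_pair * shares)
}

#' Probability of a scenario from baseline and element factors
#'
#' Implements the weighted-sum model `p = Q * sum(X_i)`: the baseline
#' scenario probability `Q` (population prevalence at the evaluated age) is
#' scaled by the factor sum. Because the factor sum can exceed 1/Q, the
#' product is clipped into \[0, 1\] and the clip is flagged.
#'
#' @param baseline_probability Baseline probability `Q` in \[0, 1\].
#' @param factors Either a numeric vector of element-factor values `X_i` or a
#'   data frame with a `value` column (and optionally `criterion`) as
#'   produced by [build_element_factors()].
#' @param table Optional [criteria_table()]; when supplied, the factor set is
#'   checked to cover every criterion exactly once.
#' @return List with `probability`, `factor_sum`, and logical `clipped`.
#' @export
scenario_probability <- function(baseline_probability, factors, table = NULL) {
  if (!is_scalar_number(baseline_probability) ||
      baseline_probability < 0 || baseline_probability > 1) {
    abort_input("baseline_probability must be a probability in [0, 1]")
  }
  if (is.data.frame(factors)) {
    if (!is.null(table)) {
      want <- names(table$criteria)
      have <- factors$criterion
      if (is.null(have) || !setequal(want, have) || length(have) != length(want)) {
        abort_input("factors must cover every criterion of the table exactly once")
      }
    }
    values <- factors$value
  } else {
    values <- factors
    if (!is.null(table) && length(values) != length(table$criteria)) {
      abort_input("factor count does not match the criteria table")
    }
  }
  if (length(values) < 1L || any(!is.finite(values))) {
    abort_input("element factors must be finite and non-empty")
  }
  sx <- sum(values)
  raw <- baseline_probability * sx
  clipped <- raw < 0 || raw > 1
  if (clipped) warn_msd(sprintf("probability %.4f clipped into [0, 1]", raw),
                        class = "msdrisk_clip_warning")
  list(probability = clip_unit(raw), factor_sum = sx, clipped = clipped)
}

#' Check that weight coefficients are correctly normalized
#'
#' The model requires `sum(q_i) = 1`. Exact-mode coefficients satisfy this to
#' machine precision by construction; display-rounded sets may carry a small
#' residual (a published elbow table sums to 0.999).
#'
#' @param table An [criteria_table()] object.
#' @param rounding_mode Optional override of the table's mode.
#' @return List with logical `ok`, `residual` (`1 - sum(q)`), and the mode used.
#' @export
verify_normalization <- function(table, rounding_mode = NULL) {
  mode <- rounding_mode %||% table$rounding_mode
  q <- weight_coefficients(table, mode)
  residual <- 1 - sum(q)
  tol <- if (mode == "exact") 1e-12 else 0.0015
  list(ok = abs(residual) <= tol, residual = residual, rounding_mode = mode)
}

#' Serialize criteria tables to JSON
#'
#' Round-trips losslessly through [read_criteria()]. A single table or a list
#' of tables may be written; a list is stored as a JSON array.
#'
#' @param tables An `msd_criteria_table` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_criteria <- function(tables, path) {
  if (inherits(tables, "msd_criteria_table")) tables <- list(tables)
  payload <- lapply(tables, function(tb) {
    list(
      region = tb$region,
      rounding_mode = tb$rounding_mode,
      notes = tb$notes,
      criteria = lapply(unname(tb$criteria), function(cr) {
        out <- list(name = cr$name, weight_score = cr$weight_score, kind = cr$kind)
        if (cr$kind != "parametric") out$levels <- as.list(cr$levels)
        out
      })
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read criteria tables from JSON
#'
#' @param path File written by [write_criteria()].
#' @return Named list of `msd_criteria_table` objects (names = regions).
#' @export
read_criteria <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("criteria file not found: %s", path))
  raw <- jsonlite::read_json(path)
  tables <- lapply(raw, function(tb) {
    criteria <- lapply(tb$criteria, function(cr) {
      criterion_def(cr$name, cr$weight_score, cr$kind,
                    levels = unlist(cr$levels %||% numeric()))
    })
    criteria_table(tb$region, criteria, tb$rounding_mode %||% "exact",
                   notes = tb$notes)
  })
  names(tables) <- vapply(tables, `[[`, character(1), "region")
  tables
}
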