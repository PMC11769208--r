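# Packaged default criteria tables for the three body regions. Likelihoods
# are the published per-segment ratios derived from a 44-subject
# patient-lifting cohort; they ship as configuration, not as re-derived
# quantities. Amplitude (range of motion), maximum moment and cumulative
# moment are parametric: each subject's likelihood is computed at run time as
# the ratio of their metric to the population mean, with cumulative moment
# carrying double weight.

default_neck_table <- function() {
  criteria_table(
    "neck",
    list(
      criterion_def("physical_readiness", 1, "categorical",
                    c(low = 1.018, medium = 0.901, high = 0.161)),
      criterion_def("sex", 1, "categorical", c(male = 1.120, female = 0.930)),
      criterion_def("technique_scenario", 1, "proportional",
                    c(no_belt = 0.952, belt = 1.024)),
      criterion_def("amplitude", 1, "parametric"),
      criterion_def("moment", 1, "parametric"),
      criterion_def("cumulative_moment", 2, "parametric")
    ),
    notes = paste("the 'high' physical-readiness likelihood 0.161 is kept as",
                  "published; it is an outlier versus every other likelihood",
                  "(~0.9-1.1) and may reflect a transcription error")
  )
}

default_shoulder_table <- function() {
  criteria_table(
    "shoulder",
    list(
      criterion_def("physical_readiness", 1, "categorical",
                    c(low = 1.009, medium = 0.997, high = 1.030)),
      criterion_def("sex", 1, "categorical", c(male = 1.016, female = 0.991)),
      criterion_def("technique_scenario", 1, "proportional",
                    c(no_belt = 0.919, belt = 1.041)),
      criterion_def("symmetry", 2, "proportional",
                    c(left = 1.009, right = 0.998)),
      criterion_def("amplitude", 1, "parametric"),
      criterion_def("moment", 1, "parametric"),
      criterion_def("cumulative_moment", 2, "parametric")
    )
  )
}

default_elbow_table <- function() {
  criteria_table(
    "elbow",
    list(
      criterion_def("physical_readiness", 1, "categorical",
                    c(low = 1.008, medium = 0.998, high = 1.029)),
      criterion_def("sex", 1, "categorical", c(male = 1.019, female = 0.989)),
      criterion_def("technique_scenario", 1, "proportional",
                    c(no_belt = 0.976, belt = 1.017)),
      criterion_def("symmetry", 2, "proportional",
                    c(left = 1.005, right = 0.999)),
      criterion_def("amplitude", 1, "parametric"),
      criterion_def("moment", 1, "parametric"),
      criterion_def("cumulative_moment", 2, "parametric")
    )
  )
}

#' Packaged default criteria tables
#'
#' Returns the packaged criteria tables for the neck, shoulder and elbow,
#' carrying the published weight scores and element likelihoods. Tables
#' default to `exact` rounding; pass `rounding_mode` to reproduce printed
#' 3-decimal cells.
#'
#' @param region Optional single region; default returns all three.
#' @param rounding_mode Optional rounding mode applied to the returned
#'   table(s); see [criteria_table()].
#' @return A single `msd_criteria_table` if `region` is given, else a named
#'   list of all three.
#' @export
msd_default_criteria <- function(region = NULL, rounding_mode = NULL) {
  tables <- list(
    neck = default_neck_table(),
    shoulder = default_shoulder_table(),
    elbow = default_elbow_table()
  )
  if (!is.null(rounding_mode)) {
    tables <- lapply(tables, function(tb) {
      tb$rounding_mode <- match.arg(rounding_mode, c("exact", "display3", "table_match"))
      tb
    })
  }
  if (is.null(region)) return(tables)
  tables[[check_region(region)]]
}
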