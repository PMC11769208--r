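# Internal helpers: classed conditions, rounding, clipping.

abort_input <- function(msg, class = "msdrisk_invalid_input") {
  stop(structure(
    class = c(class, "msdrisk_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

abort_degenerate <- function(msg) abort_input(msg, class = "msdrisk_degenerate_input")
abort_config <- function(msg) abort_input(msg, class = "msdrisk_config_error")
abort_io <- function(msg) abort_input(msg, class = "msdrisk_io_error")

warn_msd <- function(msg, class = "msdrisk_warning") {
  warning(warningCondition(msg, class = c(class, "msdrisk_warning")))
}

# base::round() implements IEC 60559 round-half-even, which is the convention
# assumed for all 3-decimal display values.
round_half_even <- function(x, digits = 3) round(x, digits)

clip_unit <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

REGIONS <- c("neck", "shoulder", "elbow")

check_region <- function(region) {
  if (!is.character(region) || length(region) != 1L || !region %in% REGIONS) {
    abort_input(sprintf("`region` must be one of %s", paste(REGIONS, collapse = ", ")))
  }
  region
}
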