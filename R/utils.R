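# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Printed screening reports conventionally round 0.005 up to 0.01, unlike
#' [base::round()]'s banker's rounding. Raw values are always retained by the
#' callers; this is a rendering rule only.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up (away from zero), same length.
#' @examples
#' round_half_up(c(0.275, 0.125), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  scaled <- signif(abs(x) * 10^digits, 13)
  sign(x) * floor(scaled + 0.5) / 10^digits
}

# Stop with a consistent error class so callers can test for data errors.
stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("screeneval_data_error", "error")))
}

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("screeneval_param_error", "error")))
}

# Validate a 0/1 vector (NA allowed when allow_na).
check_binary <- function(x, name, allow_na = FALSE) {
  ok <- x %in% c(0L, 1L) | (allow_na & is.na(x))
  if (!all(ok)) {
    stop_data(name, " must be binary (0/1)",
              if (allow_na) " or NA", "; offending value at position ",
              which(!ok)[1])
  }
  invisible(x)
}

check_aligned <- function(a, b, name_a, name_b) {
  if (length(a) != length(b)) {
    stop_data(name_a, " and ", name_b, " have different lengths (",
              length(a), " vs ", length(b), ")")
  }
  invisible(NULL)
}
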