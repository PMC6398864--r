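# Internal helpers shared across modules.

#' Round half up to whole days, clamping to a minimum of one day
#'
#' Prescription durations are quantity / daily_dose; fractional days are
#' rounded half up (0.5 rounds away from zero) and durations under one day
#' are clamped to a single day.
#'
#' @param x numeric vector of day counts
#' @return integer vector of days, all >= 1
#' @keywords internal
round_days <- function(x) {
  pmax(1L, as.integer(floor(x + 0.5)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
}

as_date_safe <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}

# Derive a stage-specific RNG seed from the run seed, kept under 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 100000L) * 10007L + as.integer(offset)
}
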