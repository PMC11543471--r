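# Internal helpers shared across modules.

# Classed abort so tests can target specific failure modes.
stop_sfelip <- function(message, class, ...) {
  abort(message, class = c(paste0("sfelip_error_", class), "sfelip_error"), ...)
}

assert_positive <- function(x, what, class = "nonpositive") {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_sfelip(sprintf("%s must be strictly positive and finite", what), class)
  }
  invisible(x)
}

# Derive a child seed from a user seed and a stage offset; kept < 2^31.
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 7L + 1L
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Convert Celsius to Kelvin
#'
#' The thermodynamic routines take Kelvin; extraction designs are written
#' in Celsius. This is the boundary conversion.
#'
#' @param t_celsius Temperature in degrees Celsius.
#' @return Temperature in Kelvin.
#' @export
celsius_to_kelvin <- function(t_celsius) t_celsius + 273.15
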