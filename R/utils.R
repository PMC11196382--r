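# Internal helpers: typed errors and fixed-decimal rendering.

stop_schema <- function(msg, ...) {
  abort(msg, class = "nichepop_schema_error", ...)
}

stop_validation <- function(msg, ...) {
  abort(msg, class = "nichepop_validation_error", ...)
}

stop_param <- function(msg, ...) {
  abort(msg, class = "nichepop_param_error", ...)
}

stop_config <- function(msg, ...) {
  abort(msg, class = "nichepop_config_error", ...)
}

stop_lookup <- function(msg, ...) {
  abort(msg, class = "nichepop_lookup_error", ...)
}

#' Round half away from zero
#'
#' Rounds to a fixed number of decimals with halves going away from zero
#' (the convention of printed ecological tables), unlike [round()]'s
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_up(2.735, 2) # 2.74, where round() gives 2.73 or 2.74 by fp luck
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# fixed-decimal string rendering used by write_table(); half-up first so
# e.g. 1.985 -> "1.99" regardless of sprintf's platform rounding
fmt_num <- function(x, digits = 2) {
  out <- sprintf(paste0("%.", digits, "f"), round_half_up(x, digits))
  out[is.na(x)] <- ""
  out
}
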