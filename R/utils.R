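#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed tables in this field round
#' half away from zero (2.45 -> 2.5, -2.45 -> -2.5), so percentage columns
#' use this helper.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.05, 0.15, -0.05), 1)
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ale <- function(..., class = "aleoverlap_error") {
  rlang::abort(paste0(...), class = class)
}

# integer draw on [lo, hi], inclusive
draw_int <- function(n, range) {
  if (range[1] > range[2]) stop_ale("invalid integer range")
  range[1] + sample.int(range[2] - range[1] + 1L, n, replace = TRUE) - 1L
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
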