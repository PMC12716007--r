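#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero ("half-up" for positive
#' values), the convention used throughout the scoring system. Base R's
#' `round()` rounds ties to even, which would turn e.g. 37.5 into 38 but
#' 12.5 into 12; score tables are printed with half-up ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(43.75, 1)  # 43.8
#' round_half_up(12.5)      # 13
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  # 1e-9 guard: values like 43.75 can sit just below the tie in binary
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

stop_phytoscreen <- function(msg, class) {
  stop(structure(
    class = c(class, "phytoscreen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
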