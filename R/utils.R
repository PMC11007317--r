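#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map_chr map_lgl imap walk
#' @importFrom stats cor qt pt sd var quantile rnorm runif fft lm residuals
#' @importFrom utils head tail
NULL

stop_swatopo <- function(msg, class) {
  abort(msg, class = c(class, "swatopo_error"))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_swatopo(
      sprintf("`%s` must be a single number in [%s, %s].", name, lower, upper),
      "swatopo_parameter_error"
    )
  }
  invisible(x)
}

# format a number with enough digits to round-trip a double exactly
fmt17 <- function(x) formatC(x, digits = 17, format = "g")

#' Sleep stage alphabet
#'
#' The five stage symbols used throughout the package: wake, NREM stages 1-3
#' and REM sleep, scored per 30-s epoch.
#' @export
STAGES <- c("W", "N1", "N2", "N3", "REM")

NREM_STAGES <- c("N1", "N2", "N3")
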