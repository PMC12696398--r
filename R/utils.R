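#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can distinguish failure modes.
stop_mediaforge <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "mediaforge_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' Round half to even at a given number of decimals
#'
#' Base `round()` already implements IEEE round-half-even; this wrapper exists
#' so display code states its rounding mode explicitly.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded numeric vector.
#' @export
round_half_even <- function(x, digits = 2) round(x, digits)

# Fixed-decimal formatting for checklists (never scientific notation).
fmt_num <- function(x, digits = 2) {
  formatC(round(x, digits), format = "f", digits = digits)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is_scalar_number(x)) {
    stop_mediaforge("mediaforge_domain_error",
                    sprintf("`%s` must be a single finite number", name))
  }
  bad <- if (strict) x <= min else x < min
  if (bad) {
    cmp <- if (strict) ">" else ">="
    stop_mediaforge("mediaforge_domain_error",
                    sprintf("`%s` must be %s %g (got %g)", name, cmp, min, x))
  }
  invisible(x)
}
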