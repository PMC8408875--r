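# Internal helpers shared across modules.

# Stop with a consistent, caller-facing error.
pp_stop <- function(...) stop(..., call. = FALSE)

# Check that `df` has the named columns; error listing what is missing.
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    pp_stop(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

check_numeric <- function(x, name) {
  if (!is.numeric(x)) pp_stop(sprintf("`%s` must be numeric", name))
  invisible(x)
}

# Trapezoidal integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(0.5 * (y[-1] + y[-n]) * diff(x))
}

#' Report a value using the cohort print conventions
#'
#' Percent figures in postprandial-response reports follow two print
#' conventions: integer percentages are rounded to the nearest integer
#' (e.g. 168.75 -> 169) while one-decimal percentages are truncated
#' (e.g. 42.77 -> 42.7, 100.95 -> 100.9). Both are provided so reported
#' tables can be matched digit-for-digit.
#'
#' @param x Numeric vector of percentages (or any values on the print scale).
#' @param style `"integer"` rounds to the nearest whole number;
#'   `"one_decimal"` truncates to one decimal place.
#' @return Numeric vector formatted per the chosen convention.
#' @examples
#' format_percent(168.75, "integer")     # 169
#' format_percent(42.769, "one_decimal") # 42.7
#' @export
format_percent <- function(x, style = c("one_decimal", "integer")) {
  style <- match.arg(style)
  if (style == "integer") {
    round(x)
  } else {
    # small guard so values computed as 13.599999... still print as 13.6
    trunc(x * 10 + sign(x) * 1e-9) / 10
  }
}
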