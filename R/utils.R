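# Shared helpers: code normalization, half-up rounding, small assertions.

#' Normalize a diagnosis code for comparison
#'
#' Codes are stored as printed (dotted, mixed case) but compared after
#' uppercasing and stripping dots, so `"I13.2"` and `"i132"` normalize
#' identically. Whitespace is trimmed.
#'
#' @param code Character vector of vocabulary-native codes.
#' @return Character vector of normalized codes.
#' @export
#' @examples
#' normalize_code(c("I13.2", "i132", " 250.40 "))
normalize_code <- function(code) {
  gsub(".", "", toupper(trimws(as.character(code))), fixed = TRUE)
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; report tables use conventional half-up
#' rounding to match printed precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a class so callers can distinguish contract violations
#' @noRd
abort_cci <- function(msg, class) {
  stop(structure(
    class = c(class, "snomedcci_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @noRd
assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_cci(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      "snomedcci_schema_error"
    )
  }
  invisible(df)
}

#' @noRd
as_date_safe <- function(x, what = "date") {
  d <- suppressWarnings(as.Date(x))
  if (anyNA(d) && !all(is.na(x))) {
    bad <- unique(x[is.na(d) & !is.na(x)])
    abort_cci(
      sprintf("malformed %s value(s): %s", what,
              paste(utils::head(bad, 5), collapse = ", ")),
      "snomedcci_value_error"
    )
  }
  d
}
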