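# Shared helpers: commercial rounding, percent formatting, validation.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even (4.25 -> 4.2). Clinical reports in
#' this workflow round half up (a mean lead time of 4.25 months prints as
#' 4.3), so all user-facing rounding goes through this helper.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(4.25, 1)  # 4.3
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Format a fraction as a percentage string
#'
#' Renders fractions the way cohort reports print them: a decimal place is
#' kept only when the percentage is exact at that precision, otherwise the
#' value rounds half-up to a whole percent. So 1/8 renders "12.5%" while
#' 8/17 renders "47%" and 27/33 renders "82%".
#'
#' @param x Fraction in \[0, 1\].
#' @param digits Maximum decimal places to keep when exact (default 1); pass
#'   an explicit value with `exact_only = FALSE` to force fixed precision.
#' @param exact_only Keep decimals only when they represent `x` exactly.
#' @return Character vector like "12.5%".
#' @examples
#' fmt_percent(1 / 8)
#' fmt_percent(8 / 17)
#' @export
fmt_percent <- function(x, digits = 1, exact_only = TRUE) {
  vapply(x, function(xi) {
    if (is.na(xi)) {
      return(NA_character_)
    }
    pct <- 100 * xi
    use_digits <- digits
    if (exact_only && abs(pct - round_half_up(pct, digits)) > 1e-9) {
      use_digits <- 0
    }
    out <- formatC(round_half_up(pct, use_digits), format = "f", digits = use_digits)
    out <- sub("\\.0+$", "", out)
    paste0(out, "%")
  }, character(1))
}

check_probability <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name), class = "mrdtrace_config_error")
  }
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` = %s is outside its valid probability range.", name, format(x)),
      class = "mrdtrace_config_error"
    )
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min),
      class = "mrdtrace_config_error"
    )
  }
  invisible(as.integer(x))
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(
      sprintf("%s is missing required column(s): %s.", what, paste(missing, collapse = ", ")),
      class = "mrdtrace_schema_error"
    )
  }
  invisible(df)
}

# Hamming distance between equal-length strings; positions where either
# string carries an N count as mismatches unless both are N (UMIs with
# ambiguous bases must never merge across differing N positions).
hamming <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(av) != length(bv)) {
    abort("hamming() requires equal-length strings.")
  }
  sum(av != bv)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
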