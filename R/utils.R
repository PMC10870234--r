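#' @importFrom stats rbinom rnorm rpois runif
#' @importFrom utils head
NULL

# FAERS dates are bare numerals: 4 digits = year, 6 = year-month, 8 = full day.
# They are carried as strings so partial precision survives a round trip.

#' Precision of a partial FAERS date
#'
#' @param x character vector of FAERS date numerals (4, 6 or 8 digits; `NA`
#'   for absent).
#' @return character vector with values `"year"`, `"month"`, `"day"` or `NA`.
#' @keywords internal
date_precision <- function(x) {
  out <- rep(NA_character_, length(x))
  out[!is.na(x) & nchar(x) == 4L] <- "year"
  out[!is.na(x) & nchar(x) == 6L] <- "month"
  out[!is.na(x) & nchar(x) == 8L] <- "day"
  out
}

is_partial_date <- function(x) {
  !is.na(x) & grepl("^\\d{4}(\\d{2}(\\d{2})?)?$", x)
}

#' Earliest and latest completions of a partial date
#'
#' A year-only date can stand for any day of that year; a year-month date for
#' any day of that month. Window tests use the completion interval, so a
#' partial date is only excluded when no completion can fall in the window.
#'
#' @param x character vector of 4/6/8-digit date numerals.
#' @return a `Date` vector (`NA` where `x` is absent or malformed).
#' @keywords internal
date_min_completion <- function(x) {
  out <- rep(as.Date(NA), length(x))
  ok <- is_partial_date(x)
  n <- nchar(x[ok])
  full <- character(sum(ok))
  full[n == 4L] <- paste0(x[ok][n == 4L], "0101")
  full[n == 6L] <- paste0(x[ok][n == 6L], "01")
  full[n == 8L] <- x[ok][n == 8L]
  out[ok] <- as.Date(full, format = "%Y%m%d")
  out
}

#' @rdname date_min_completion
#' @keywords internal
date_max_completion <- function(x) {
  out <- rep(as.Date(NA), length(x))
  ok <- is_partial_date(x)
  xs <- x[ok]
  n <- nchar(xs)
  res <- as.Date(rep(NA_real_, length(xs)))
  if (any(n == 4L)) {
    res[n == 4L] <- as.Date(paste0(xs[n == 4L], "1231"), format = "%Y%m%d")
  }
  if (any(n == 6L)) {
    y <- as.integer(substr(xs[n == 6L], 1, 4))
    m <- as.integer(substr(xs[n == 6L], 5, 6))
    nxt_y <- ifelse(m == 12L, y + 1L, y)
    nxt_m <- ifelse(m == 12L, 1L, m + 1L)
    res[n == 6L] <- as.Date(sprintf("%04d-%02d-01", nxt_y, nxt_m)) - 1L
  }
  if (any(n == 8L)) {
    res[n == 8L] <- as.Date(xs[n == 8L], format = "%Y%m%d")
  }
  out[ok] <- res
  out
}

#' Round half away from zero
#'
#' Percent columns in rendered tables use commercial (half-up) rounding so
#' that e.g. 63.85 prints as 63.9; base `round()` rounds half to even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` under `seed` and restore the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_window <- function(window) {
  stopifnot(length(window) == 2L)
  w <- as.Date(window)
  if (anyNA(w)) stop("window bounds must be full ISO dates", call. = FALSE)
  if (w[1] > w[2]) stop("inverted window: start is after end", call. = FALSE)
  w
}
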