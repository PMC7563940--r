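# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Presentation-layer rounding used for all printed table cells. Base R's
#' `round()` rounds half to even; clinical tables here use the conventional
#' half-up rule (2.345 -> 2.35 at 2 dp).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half away from zero to `digits` places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # epsilon guard: 1.945 stored as 1.94499999... must still round up
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Add whole months to a Date, clamping to the end of the target month
# (2020-01-31 + 1 month -> 2020-02-29).
add_months <- function(date, n) {
  lt <- as.POSIXlt(date)
  y <- lt$year + 1900L
  m <- lt$mon + n
  y <- y + m %/% 12L
  m <- m %% 12L
  day <- lt$mday
  last <- days_in_month(y, m + 1L)
  day <- pmin(day, last)
  as.Date(sprintf("%04d-%02d-%02d", y, m + 1L, day))
}

days_in_month <- function(year, month) {
  dm <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- dm[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  d[month == 2L & leap] <- 29L
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bcmets <- function(msg, class) {
  stop(structure(
    class = c(class, "bcmets_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
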