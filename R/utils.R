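## Small shared helpers. Dates are handled as `Date` at the interfaces and
## as integer days internally.

#' Convert day counts to months
#'
#' Durations are reported in months using the calendar-average month length
#' of 30.44 days.
#'
#' @param days Numeric vector of day counts.
#' @param months_per_unit Days per month (default 30.44).
#' @return Numeric vector of months.
#' @export
days_to_months <- function(days, months_per_unit = 30.44) {
  days / months_per_unit
}

#' Shift a date by calendar months
#'
#' Month-length-aware date arithmetic: the day of month is preserved and
#' clamped to the last day of the target month (e.g. 31 Mar minus one month
#' is 28 Feb in a non-leap year).
#'
#' @param date A `Date` vector.
#' @param months Integer number of months to add (may be negative).
#' @return A `Date` vector.
#' @export
shift_months <- function(date, months) {
  lt <- as.POSIXlt(date)
  m0 <- lt$year * 12L + lt$mon + as.integer(months)
  y <- m0 %/% 12L
  m <- m0 %% 12L
  yr <- y + 1900L
  leap <- (yr %% 4L == 0L) & (yr %% 100L != 0L | yr %% 400L == 0L)
  last <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[m + 1L]
  last <- ifelse(m == 1L & leap, 29L, last)
  lt$year <- y
  lt$mon <- m
  lt$mday <- pmin(lt$mday, last)
  as.Date(lt)
}

## Calendar year of a Date, vectorised.
.year_of <- function(date) {
  as.POSIXlt(date)$year + 1900L
}

#' Age in whole years at a dispensing
#'
#' Year precision only: age is the dispensing year minus the year of birth,
#' matching claims sources that record year of birth but not date of birth.
#'
#' @param year_of_birth Integer vector.
#' @param date `Date` vector of dispensing dates.
#' @return Integer vector of ages.
#' @export
age_at <- function(year_of_birth, date) {
  .year_of(date) - as.integer(year_of_birth)
}

.assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

## Run code with a private RNG stream, restoring the caller's state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
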