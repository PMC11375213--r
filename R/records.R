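#' Titleholder transition records
#'
#' A titleholder table holds one row per record-holder transition: the time
#' `t` (decimal calendar year) at which the incumbent oldest person dies at
#' age `y`, and the age `z` of the successor at that moment.  Because the
#' successor of transition `i` is the incumbent of transition `i + 1`, the
#' triples must satisfy the birth-date consistency relation
#' \eqn{t_i - z_i = t_{i+1} - y_{i+1}}.
#'
#' @param t Transition times (decimal years), sorted increasing.
#' @param y Incumbent ages at death (years).
#' @param z Successor ages at the transition (years), `0 < z < y`.
#' @param tol Consistency tolerance in years (see [validate_records()]).
#' @return A data frame of class `titleholder_records` with columns
#'   `t`, `y`, `z`.
#' @export
titleholder_records <- function(t, y, z, tol = 0.01) {
  df <- data.frame(t = as.numeric(t), y = as.numeric(y), z = as.numeric(z))
  if (is.unsorted(df$t)) stop("titleholder_records: transitions must be time-sorted")
  class(df) <- c("titleholder_records", "data.frame")
  validate_records(df, tol = tol)
}

#' Validate a titleholder table
#'
#' Checks `0 < z < y` row-wise and the birth-date consistency relation
#' `t[i] - z[i] = t[i+1] - y[i+1]` between consecutive rows.  Ages from
#' day-resolved sources rounded to decimal years carry up to ~1/365 year of
#' slack, hence the default tolerance of 0.01 year.
#'
#' @param records A data frame with columns `t`, `y`, `z`.
#' @param tol Allowed absolute residual in the consistency relation, years.
#' @return The records, unchanged, invisibly classed as
#'   `titleholder_records`.
#' @export
validate_records <- function(records, tol = 0.01) {
  df <- as.data.frame(records)
  stopifnot(all(c("t", "y", "z") %in% names(df)))
  bad <- which(!(df$z > 0 & df$z < df$y))
  if (length(bad))
    stop(sprintf("record %d violates 0 < z < y (y = %.4f, z = %.4f)",
                 bad[1], df$y[bad[1]], df$z[bad[1]]))
  if (nrow(df) > 1) {
    res <- (df$t[-nrow(df)] - df$z[-nrow(df)]) - (df$t[-1] - df$y[-1])
    bad <- which(abs(res) > tol)
    if (length(bad))
      stop(sprintf("consistency relation violated at record %d: residual %.4g years exceeds %g",
                   bad[1] + 1L, res[bad[1]], tol))
  }
  if (!inherits(df, "titleholder_records"))
    class(df) <- c("titleholder_records", "data.frame")
  df
}

#' @export
print.titleholder_records <- function(x, ...) {
  cat(sprintf("titleholder records: %d transitions, %.2f-%.2f\n",
              nrow(x), min(x$t), max(x$t)))
  NextMethod()
}

#' Convert calendar dates to decimal years
#'
#' Single centralized conversion: days since January 1 of the year divided
#' by 365.2425 (the mean Gregorian year).
#'
#' @param dates A `Date` vector or something coercible by [as.Date()].
#' @return Decimal calendar years.
#' @export
decimal_year <- function(dates) {
  if (is.character(dates) || is.factor(dates))
    dates <- as.Date(as.character(dates), format = "%Y-%m-%d")
  else dates <- as.Date(dates)
  out <- rep(NA_real_, length(dates))
  ok <- !is.na(dates)
  if (any(ok)) {
    yr <- as.integer(format(dates[ok], "%Y"))
    jan1 <- as.Date(sprintf("%04d-01-01", yr))
    out[ok] <- yr + as.numeric(dates[ok] - jan1) / 365.2425
  }
  out
}

#' Read a titleholder CSV
#'
#' Supported dialects:
#' \describe{
#'   \item{`decimal_year`}{columns `date_death` (decimal year),
#'     `age_death_years`, `successor_age_years`;}
#'   \item{`iso_dates`}{the same columns with `date_death` an ISO date
#'     (`YYYY-MM-DD`), converted via [decimal_year()];}
#'   \item{`days_lived`}{columns `date_death` (ISO), `days_lived`,
#'     `successor_days_lived` — ages in days divided by 365.2425.}
#' }
#'
#' @param path CSV file path (header required).
#' @param dialect One of `"decimal_year"`, `"iso_dates"`, `"days_lived"`.
#' @param tol Consistency tolerance passed to [validate_records()].
#' @return A [titleholder_records()] table sorted by time.
#' @export
read_titleholders <- function(path, dialect = c("decimal_year", "iso_dates", "days_lived"),
                              tol = 0.01) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty titleholder file: ", path)
  need <- switch(dialect,
                 decimal_year = ,
                 iso_dates = c("date_death", "age_death_years", "successor_age_years"),
                 days_lived = c("date_death", "days_lived", "successor_days_lived"))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  t <- if (dialect == "decimal_year") as.numeric(df$date_death)
       else decimal_year(df$date_death)
  if (any(is.na(t))) stop("malformed date_death at line ", which(is.na(t))[1] + 1L)
  if (dialect == "days_lived") {
    y <- as.numeric(df$days_lived) / 365.2425
    z <- as.numeric(df$successor_days_lived) / 365.2425
  } else {
    y <- as.numeric(df$age_death_years)
    z <- as.numeric(df$successor_age_years)
  }
  if (any(is.na(y)) || any(is.na(z)))
    stop("malformed age at line ", which(is.na(y) | is.na(z))[1] + 1L)
  ord <- order(t)
  titleholder_records(t[ord], y[ord], z[ord], tol = tol)
}

#' Write a titleholder CSV in the decimal-year dialect
#'
#' @param records A [titleholder_records()] table.
#' @param path Output path.
#' @export
write_titleholders <- function(records, path) {
  df <- data.frame(date_death = sprintf("%.6f", records$t),
                   age_death_years = sprintf("%.6f", records$y),
                   successor_age_years = sprintf("%.6f", records$z))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
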