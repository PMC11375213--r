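#' Exponential entry-age cohort intensity
#'
#' The rate at which people reach the entry age `E` is modelled as an
#' exponential function of calendar time,
#' \eqn{\lambda_E(t) = C_E e^{\kappa_E t}}, with `t` in decimal calendar
#' years.  The constants are obtained by regressing log cohort counts on
#' time (see [fit_exponential_intensity()]); packaged defaults for
#' `E = 0, 30, 60` are available through [default_birth_intensity()].
#'
#' @param C Intensity scale (persons/year), positive.  Because `t` is a raw
#'   calendar year, `C` is the nominal rate at year 0.
#' @param kappa Exponential growth rate (1/year).
#' @param E Entry age in years.
#' @return An object of class `birth_intensity`.
#' @export
birth_intensity <- function(C, kappa, E = 0) {
  stopifnot(C > 0, is.finite(kappa), E >= 0)
  structure(list(C = C, kappa = kappa, E = E), class = "birth_intensity")
}

#' @export
print.birth_intensity <- function(x, ...) {
  cat(sprintf("birth intensity lambda_E(t) = C exp(kappa t)\n  C = %g, kappa = %g, E = %g\n",
              x$C, x$kappa, x$E))
  cat(sprintf("  doubling time %.1f years; rate at 2000: %.4g persons/year\n",
              log(2) / x$kappa, intensity_at(x, 2000)))
  invisible(x)
}

#' Cohort intensity at a calendar time
#'
#' @param bi A [birth_intensity()].
#' @param t Calendar time in decimal years (vectorized).
#' @return Rate in persons/year.
#' @export
intensity_at <- function(bi, t) {
  out <- bi$C * exp(bi$kappa * t)
  if (any(!is.finite(out))) stop("intensity_at: overflow at t = ", t[!is.finite(out)][1])
  out
}

#' Thinned intensity of people reaching an entry age
#'
#' An individual born at time `t - E` is alive at age `E` with probability
#' \eqn{1 - F_{t-E}(E)}; thinning the birth process accordingly gives the
#' rate at which people turn `E` at time `t`:
#' \eqn{\lambda_E(t) = \lambda(t-E)(1 - F_{t-E}(E))}.
#'
#' @param raw_rate Function of time giving the age-0 birth rate
#'   \eqn{\lambda(t)}.
#' @param trend A [mortality_trend()] describing the age-0 cohort lifespan
#'   family.
#' @param E Entry age in years.
#' @param t Calendar time (vectorized).
#' @return Rate in persons/year.
#' @export
thinned_intensity <- function(raw_rate, trend, E, t) {
  stopifnot(E >= 0)
  surv <- vapply(t, function(tt) ggm_sf(cohort_law(trend, tt - E), E),
                 numeric(1))
  raw_rate(t - E) * surv
}

#' Fit an exponential intensity to cohort counts
#'
#' Ordinary least squares of log counts on calendar year, the standard way
#' to summarize near-exponential growth of annual cohort sizes.
#'
#' @param counts A data frame (or matrix) whose first two columns are the
#'   calendar year and the cohort count (persons/year); counts must be
#'   positive and at least two are required.
#' @param E Entry age recorded on the result.
#' @return A [birth_intensity()] with `C = exp(intercept)`,
#'   `kappa = slope`.
#' @export
fit_exponential_intensity <- function(counts, E = 0) {
  counts <- as.data.frame(counts)
  if (nrow(counts) < 2) stop("at least two (year, count) rows are required")
  year <- as.numeric(counts[[1]])
  n <- as.numeric(counts[[2]])
  if (any(!is.finite(n)) || any(n <= 0))
    stop("cohort counts must be positive")
  fit <- stats::lm(log(n) ~ year)
  birth_intensity(C = exp(stats::coef(fit)[[1]]), kappa = stats::coef(fit)[[2]], E = E)
}
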