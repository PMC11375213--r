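#' Time-varying mortality level for a birth cohort
#'
#' In the fitted model the gamma-Gompertz rate of aging `b` and frailty
#' variance `gamma` are constant, while the initial mortality level of the
#' cohort reaching the entry age `E` at calendar time `t` declines
#' exponentially,
#' \deqn{a_E(t) = K_E\, e^{-\alpha_E (t - 2000)},}
#' so that `K` is the mortality level of the cohort at entry in the year
#' 2000.  Referencing the year 2000 keeps the fitted constants on a sane
#' numerical scale.
#'
#' @param K Mortality level at calendar year 2000 (1/year), positive.
#' @param alpha Exponential decline rate (1/year), non-negative; `alpha = 0`
#'   gives a time-constant level.
#' @param b Rate of aging (1/year), positive.
#' @param gamma Frailty variance, positive.
#' @param E Entry age in years (non-negative); ages in the conditioned law
#'   are measured from `E`.
#' @param c Extrinsic (Makeham) mortality, carried through but 0 by default.
#' @return An object of class `mortality_trend`.
#' @examples
#' tr <- mortality_trend(K = 2.951e-5, alpha = 0.01277, b = 0.09, gamma = 0.08596)
#' mortality_level(tr, 2000)  # = K
#' @export
mortality_trend <- function(K, alpha, b, gamma, E = 0, c = 0) {
  stopifnot(K > 0, alpha >= 0, b > 0, gamma > 0, E >= 0, c >= 0)
  structure(list(K = K, alpha = alpha, b = b, gamma = gamma, E = E, c = c),
            class = "mortality_trend")
}

#' @export
print.mortality_trend <- function(x, ...) {
  cat(sprintf(paste0("mortality trend a_E(t) = K exp(-alpha (t - 2000))\n",
                     "  K = %g, alpha = %g, b = %g, gamma = %g, E = %g, c = %g\n"),
              x$K, x$alpha, x$b, x$gamma, x$E, x$c))
  invisible(x)
}

#' Mortality level at a calendar time
#'
#' @param trend A [mortality_trend()].
#' @param t Calendar time in decimal years (vectorized).
#' @return \eqn{a_E(t) = K e^{-\alpha(t - 2000)}} in 1/year.
#' @export
mortality_level <- function(trend, t) {
  trend$K * exp(-trend$alpha * (t - 2000))
}

#' Lifespan law of the cohort entering at calendar time t
#'
#' Builds the [lifespan_law()] whose level parameter is frozen at
#' `mortality_level(trend, t)`.  Under an entry age `E > 0` this is the law
#' of the remaining lifetime past age `E` for the cohort that reaches `E`
#' at time `t`.
#'
#' @inheritParams mortality_level
#' @return A [lifespan_law()].
#' @export
cohort_law <- function(trend, t) {
  lifespan_law(mortality_level(trend, t), trend$b, trend$gamma, trend$c)
}

#' Entry-age conditioning of a cohort lifespan family
#'
#' Given the family of cohort laws defined by `trend` (interpreted as laws
#' of full lifespans, entry age 0), returns the conditional law of the
#' remaining lifetime of a person who reaches age `E` at calendar time `t`:
#' \deqn{F_t^E(x) = \frac{F_{t-E}(x+E) - F_{t-E}(E)}{1 - F_{t-E}(E)},\qquad
#'       f_t^E(x) = \frac{f_{t-E}(x+E)}{1 - F_{t-E}(E)}.}
#'
#' @param trend A [mortality_trend()] describing the age-0 cohort family.
#' @param t Calendar time at which the person reaches age `E`.
#' @param E Entry age in years.
#' @return A list with vectorized functions `cdf(x)` and `pdf(x)` of the age
#'   past entry, and the conditioning survival `entry_survival`.
#' @export
entry_age_transform <- function(trend, t, E) {
  stopifnot(E >= 0)
  base <- cohort_law(trend, t - E)
  FE <- ggm_cdf(base, E)
  if (1 - FE <= .Machine$double.eps)
    stop("entry_age_transform: survival to the entry age is numerically zero")
  list(
    cdf = function(x) (ggm_cdf(base, x + E) - FE) / (1 - FE),
    pdf = function(x) ggm_pdf(base, x + E) / (1 - FE),
    entry_survival = 1 - FE,
    base = base
  )
}
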