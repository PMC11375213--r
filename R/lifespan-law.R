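#' Gamma-Gompertz(-Makeham) lifespan law
#'
#' Parameter bundle for the gamma-Gompertz (GG) lifespan distribution and its
#' Makeham extension (GGM).  The force of mortality is a Gompertz hazard
#' \eqn{a e^{bx}} with a multiplicative gamma-distributed frailty of variance
#' \eqn{\gamma}, plus an optional age-independent extrinsic component \eqn{c}.
#' Marginally,
#' \deqn{1 - F(x) = e^{-cx}\left(1 + \frac{a\gamma}{b}(e^{bx}-1)\right)^{-1/\gamma}.}
#' The frailty mixture makes the population hazard decelerate and plateau at
#' \eqn{b/\gamma + c} at extreme ages, the regime relevant for longevity
#' records.
#'
#' @param a Initial mortality level (1/year), positive.
#' @param b Rate of aging (1/year), positive.
#' @param gamma Frailty variance (dimensionless), positive.
#' @param c Extrinsic (Makeham) mortality (1/year), non-negative; `c = 0`
#'   selects the pure gamma-Gompertz submodel.
#' @return An object of class `lifespan_law`.
#' @seealso [ggm_cdf()], [ggm_pdf()], [ggm_hazard()], [survival_integral()]
#' @examples
#' law <- lifespan_law(a = 2.951e-5, b = 0.09, gamma = 0.08596)
#' ggm_cdf(law, 110)
#' @export
lifespan_law <- function(a, b, gamma, c = 0) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(gamma), is.numeric(c))
  if (any(a <= 0) || b <= 0 || gamma <= 0)
    stop("lifespan_law: a, b and gamma must be positive")
  if (c < 0) stop("lifespan_law: c must be non-negative")
  structure(list(a = a, b = b, gamma = gamma, c = c), class = "lifespan_law")
}

#' @export
print.lifespan_law <- function(x, ...) {
  kind <- if (x$c > 0) "gamma-Gompertz-Makeham" else "gamma-Gompertz"
  cat(sprintf("%s lifespan law\n  a = %g, b = %g, gamma = %g, c = %g\n",
              kind, x$a[1], x$b, x$gamma, x$c))
  cat(sprintf("  hazard plateau b/gamma + c = %g per year\n", x$b / x$gamma + x$c))
  invisible(x)
}

.check_age <- function(x) {
  if (any(x < 0)) stop("age x must be non-negative")
  x
}

#' Cumulative distribution function of the GG/GGM lifespan law
#'
#' @param law A [lifespan_law()].
#' @param x Age in years (vectorized), non-negative.
#' @return \eqn{F(x)}, the probability of dying before age `x`.
#' @export
ggm_cdf <- function(law, x) {
  .check_age(x)
  1 - exp(.ggm_log_sf(law$a, law$b, law$gamma, law$c, x))
}

# log survival, vectorized over x and a (recycled)
.ggm_log_sf <- function(a, b, gamma, c, x) {
  -c * x - log1p(a * gamma / b * expm1(b * x)) / gamma
}

#' Survival function of the GG/GGM lifespan law
#'
#' Computed directly on the log scale, so deep-tail values keep full
#' relative precision (while `1 - ggm_cdf(law, x)` loses digits once the
#' survival drops below ~1e-8).
#'
#' @inheritParams ggm_cdf
#' @return \eqn{1 - F(x)}.
#' @export
ggm_sf <- function(law, x) {
  .check_age(x)
  exp(.ggm_log_sf(law$a, law$b, law$gamma, law$c, x))
}

#' Probability density of the GG/GGM lifespan law
#'
#' For `c = 0` this is \eqn{a e^{bx} (1 + \frac{a\gamma}{b}(e^{bx}-1))^{-1-1/\gamma}};
#' with a Makeham term the density picks up the extrinsic hazard as well.
#'
#' @inheritParams ggm_cdf
#' @return Density in 1/year.
#' @export
ggm_pdf <- function(law, x) {
  .check_age(x)
  a <- law$a; b <- law$b; g <- law$gamma; c <- law$c
  lz <- log1p(a * g / b * expm1(b * x))
  # survival * hazard; hazard = c + a e^{bx} / (1 + a g (e^{bx}-1)/b)
  exp(-c * x - (1 + 1 / g) * lz) * (c * (b - a * g) + a * (b + c * g) * exp(b * x)) / b
}

#' Hazard (force of mortality) of the GG/GGM lifespan law
#'
#' @inheritParams ggm_cdf
#' @return Hazard in 1/year; increases with age and approaches the plateau
#'   `b/gamma + c`.
#' @export
ggm_hazard <- function(law, x) {
  .check_age(x)
  a <- law$a; b <- law$b; g <- law$gamma; c <- law$c
  c + a * exp(b * x) / (1 + a * g / b * expm1(b * x))
}

#' Quantile function of the GG/GGM lifespan law
#'
#' Closed-form inverse for the gamma-Gompertz (`c = 0`); monotone
#' root-finding on the cdf when a Makeham term is present.
#'
#' @param law A [lifespan_law()].
#' @param p Probabilities in `[0, 1)` (vectorized).
#' @return Ages `x` with `ggm_cdf(law, x) = p`.
#' @export
ggm_quantile <- function(law, p) {
  if (any(p < 0 | p >= 1)) stop("p must lie in [0, 1)")
  a <- law$a; b <- law$b; g <- law$gamma
  if (law$c == 0) {
    return(log1p(expm1(-g * log1p(-p)) * b / (a * g)) / b)
  }
  vapply(p, function(pp) {
    if (pp == 0) return(0)
    f <- function(x) ggm_cdf(law, x) - pp
    upper <- 10
    while (f(upper) < 0) upper <- upper * 2
    stats::uniroot(f, c(0, upper), tol = 1e-12)$root
  }, numeric(1))
}

#' Sample lifespans from a GG/GGM law by inverse-cdf sampling
#'
#' @param n Number of draws.
#' @param law A [lifespan_law()].
#' @param min_age Condition the draws on survival to this age (default 0,
#'   i.e. unconditional).
#' @return Numeric vector of lifespans (total age at death).
#' @export
rggm <- function(n, law, min_age = 0) {
  lo <- if (min_age > 0) ggm_cdf(law, min_age) else 0
  ggm_quantile(law, lo + stats::runif(n) * (1 - lo))
}

#' Expected lifespan under a GG/GGM law
#'
#' The integral of the survival function over all ages,
#' \eqn{\int_0^\infty (1 - F(u))\,du}.
#'
#' @param law A [lifespan_law()].
#' @return Expected lifespan in years.
#' @export
expected_lifespan <- function(law) {
  survival_integral(law, 0)
}
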