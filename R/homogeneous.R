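#' Homogeneous (stationary) record-age model
#'
#' The special case with a constant birth rate \eqn{\lambda} and a
#' time-constant lifespan law.  Here the record-age process is stationary
#' and the record-age, peaks (age at death of record holders) and
#' reign-length distributions have closed expressions in terms of the
#' integrated survival function \eqn{G(x) = \int_x^\infty (1-F(u))\,du}:
#' \deqn{h(x) = e^{-\lambda G(x)}\lambda(1-F(x)),\qquad m = e^{-\lambda G(0)},}
#' with \eqn{m} the probability that nobody is alive.
#'
#' @param lambda Constant birth rate in persons/year, positive.
#' @param law A [lifespan_law()].
#' @return An object of class `homogeneous_spec`.
#' @examples
#' spec <- homogeneous_spec(1, lifespan_law(1, 0.09, 0.09))  # Exp(1) lifespans
#' stationary_point_mass(spec)  # exp(-1)
#' @export
homogeneous_spec <- function(lambda, law) {
  stopifnot(lambda > 0, inherits(law, "lifespan_law"))
  structure(list(lambda = lambda, law = law, cache = new.env(parent = emptyenv())),
            class = "homogeneous_spec")
}

#' @export
print.homogeneous_spec <- function(x, ...) {
  cat(sprintf("homogeneous record model: lambda = %g persons/year\n", x$lambda))
  print(x$law)
  invisible(x)
}

# G(x) = integral of survival; closed form via the hypergeometric integral
.G <- function(spec, x) survival_integral(spec$law, x)

#' Stationary record-age density
#'
#' @param spec A [homogeneous_spec()].
#' @param x Age in years (vectorized), non-negative.
#' @return \eqn{h(x) = e^{-\lambda G(x)} \lambda (1 - F(x))}.
#' @seealso [stationary_point_mass()], [stationary_cdf()]
#' @export
stationary_density <- function(spec, x) {
  .check_age(x)
  sf <- ggm_sf(spec$law, x)
  exp(-spec$lambda * .G(spec, x)) * spec$lambda * sf
}

#' Stationary probability that nobody is alive
#'
#' \eqn{m = e^{-\lambda\, E[\mathrm{lifespan}]}}.
#'
#' @param spec A [homogeneous_spec()].
#' @export
stationary_point_mass <- function(spec) {
  exp(-spec$lambda * .G(spec, 0))
}

#' Stationary record-age distribution function
#'
#' \eqn{P(Y \le x) = e^{-\lambda G(x)}} (the atom at 0 is included at
#' `x = 0`).
#'
#' @inheritParams stationary_density
#' @export
stationary_cdf <- function(spec, x) {
  .check_age(x)
  exp(-spec$lambda * vapply(x, function(xx) .G(spec, xx), numeric(1)))
}

#' Jump (successor-age) density in the homogeneous model
#'
#' Given the record holder dies at age `y`, the successor's age has density
#' \eqn{j_y(x) = e^{-\lambda\int_x^y(1-F)}\lambda(1-F(x))} on `[0, y)` and
#' an atom [jump_point_mass_hom()] at 0.
#'
#' @param spec A [homogeneous_spec()].
#' @param y Incumbent's age at death.
#' @param x Successor ages, `0 <= x < y` (vectorized).
#' @export
jump_density_hom <- function(spec, y, x) {
  if (any(x >= y)) stop("jump_density_hom: requires x < y")
  .check_age(x)
  Gy <- .G(spec, y)
  vapply(x, function(xx) {
    exp(-spec$lambda * (.G(spec, xx) - Gy)) * spec$lambda * ggm_sf(spec$law, xx)
  }, numeric(1))
}

#' Probability that the record jumps to zero
#'
#' @inheritParams jump_density_hom
#' @export
jump_point_mass_hom <- function(spec, y) {
  exp(-spec$lambda * (.G(spec, 0) - .G(spec, y)))
}

# age around which the stationary density concentrates (lambda * G = 1)
.hom_center <- function(spec) {
  .cache(spec, "center", {
    f <- function(x) spec$lambda * .G(spec, x) - 1
    if (f(0) < 0) 0
    else stats::uniroot(f, c(0, 200), tol = 1e-9, extendInt = "downX")$root
  })
}

.cache <- function(spec, key, expr) {
  if (is.null(spec$cache[[key]])) spec$cache[[key]] <- force(expr)
  spec$cache[[key]]
}

#' Stationary density of the peaks process
#'
#' The ages at which successive record holders die form a Markov chain; its
#' stationary density is
#' \eqn{z(x) \propto f(x)\, e^{-\lambda G(x)}}.
#'
#' @inheritParams stationary_density
#' @export
peaks_density <- function(spec, x) {
  .check_age(x)
  num <- ggm_pdf(spec$law, x) * exp(-spec$lambda * vapply(x, function(xx) .G(spec, xx), numeric(1)))
  num / .peaks_norm(spec)
}

.peaks_norm <- function(spec) {
  .cache(spec, "peaks_norm", {
    ctr <- .hom_center(spec)
    .quad_split(function(y) ggm_pdf(spec$law, y) *
                  exp(-spec$lambda * vapply(y, function(yy) .G(spec, yy), numeric(1))),
                0, .hom_xmax(spec), ctr)
  })
}

.hom_xmax <- function(spec) {
  # age beyond which survival is negligible for quadrature purposes
  .cache(spec, "xmax", max(150, .hom_center(spec) + 60))
}

#' Reign-length density of a record holder
#'
#' The time a record holder spends as the oldest person has density
#' \deqn{r(w) = \frac{\int_0^\infty h(y) f(y+w)\,dy +
#'   m \int_0^w f(z)\,\lambda e^{-\lambda(w-z)}\,dz}
#'   {\int_0^\infty h(y)(1-F(y))\,dy + m}.}
#' The first term covers successions where a new holder of age `y` reigns
#' until death at age `y + w`; the `m`-weighted term covers reigns started
#' from an empty population (the waiting time to the next birth plus that
#' person's whole lifespan), measured from the previous holder's death.
#'
#' @param spec A [homogeneous_spec()].
#' @param w Reign length(s) in years, non-negative.
#' @return Density in 1/year.
#' @export
reign_length_density <- function(spec, w) {
  .check_age(w)
  den <- .reign_norm(spec)
  vapply(w, function(ww) .reign_num(spec, ww) / den, numeric(1))
}

.reign_num <- function(spec, w) {
  ctr <- .hom_center(spec)
  main <- .quad_split(function(y) stationary_density(spec, y) * ggm_pdf(spec$law, y + w),
                      0, .hom_xmax(spec), ctr)
  m <- stationary_point_mass(spec)
  extra <- 0
  if (m > 1e-300 && w > 0) {
    lam <- spec$lambda
    extra <- m * stats::integrate(function(z) ggm_pdf(spec$law, z) * lam * exp(-lam * (w - z)),
                                  0, w, rel.tol = 1e-10, abs.tol = 1e-14,
                                  subdivisions = 500L)$value
  }
  main + extra
}

.reign_norm <- function(spec) {
  .cache(spec, "reign_norm", {
    ctr <- .hom_center(spec)
    .quad_split(function(y) stationary_density(spec, y) * ggm_sf(spec$law, y),
                0, .hom_xmax(spec), ctr) + stationary_point_mass(spec)
  })
}

#' Expected reign length in the homogeneous model
#'
#' \eqn{E[W] = \int_0^\infty w\, r(w)\,dw} with `r` from
#' [reign_length_density()].
#'
#' @param spec A [homogeneous_spec()].
#' @param w_max Upper truncation for the reign-length integral; the density
#'   decays at least exponentially, and 60 years is far beyond any
#'   realistic reign.
#' @export
expected_reign_length <- function(spec, w_max = 60) {
  .cache(spec, "mean_reign", {
    stats::integrate(function(w) vapply(w, function(ww) ww * .reign_num(spec, ww), numeric(1)),
                     0, w_max, rel.tol = 1e-8, abs.tol = 1e-12,
                     subdivisions = 500L)$value / .reign_norm(spec)
  })
}

#' Homogeneous model frozen at the fixed point of a calendar year
#'
#' Builds the homogeneous specification used to evaluate reign lengths of
#' the full time-varying model at a calendar year `t`: the delay `d*` is
#' obtained from [mean_age_fixed_point()], the mortality level is frozen at
#' \eqn{a_E(t - d^*)} and the birth rate at either \eqn{\lambda_E(t - d^*)}
#' (`freeze = "cohort"`, the birth rate experienced by the record holder's
#' cohort — the same frozen-cohort logic as the fixed point itself) or
#' \eqn{\lambda_E(t)} (`freeze = "current"`).
#'
#' @param spec A [model_spec()].
#' @param t Calendar year.
#' @param freeze Freezing convention for the birth rate.
#' @param n_iter Fixed-point iterations.
#' @return A [homogeneous_spec()] with attribute `"fixed_point"`.
#' @export
frozen_homogeneous_spec <- function(spec, t, freeze = c("cohort", "current"),
                                    n_iter = 10) {
  freeze <- match.arg(freeze)
  fp <- mean_age_fixed_point(spec, t, n_iter = n_iter)
  a <- mortality_level(spec$trend, t - fp$mean)
  law <- lifespan_law(a, spec$trend$b, spec$trend$gamma, spec$trend$c)
  lam <- intensity_at(spec$bi, if (freeze == "cohort") t - fp$mean else t)
  out <- homogeneous_spec(lam, law)
  attr(out, "fixed_point") <- fp
  out
}

#' Expected reign length of the record holder in a calendar year
#'
#' Convenience adapter: freezes the full model at the fixed point for year
#' `t` (see [frozen_homogeneous_spec()]) and returns the expected reign
#' length of the resulting homogeneous model.
#'
#' @inheritParams frozen_homogeneous_spec
#' @export
reign_length_at <- function(spec, t, freeze = c("cohort", "current"), n_iter = 10) {
  expected_reign_length(frozen_homogeneous_spec(spec, t, freeze, n_iter))
}
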