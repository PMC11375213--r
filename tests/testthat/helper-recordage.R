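# Shared fixtures and small numeric helpers for the test suite.

# packaged full model (entry age 0, b = 0.09)
spec_default <- function() default_model_spec()

# homogeneous model frozen at the 1955 fixed point (cached across tests)
frozen_1955 <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- frozen_homogeneous_spec(spec_default(), 1955)
    val
  }
})

# moderate-rate homogeneous model: finite differences of its densities are
# numerically well-conditioned (values of order 1, no extreme exponents)
moderate_hom <- function() homogeneous_spec(100, lifespan_law(0.01, 0.1, 0.12))

# exponential lifespans via the a*gamma = b reduction: Exp(1), lambda = 1
toy_exponential <- function() homogeneous_spec(1, lifespan_law(1, 0.09, 0.09))

# cdf from a density tabulated on a regular grid (cumulative trapezoid)
cdf_from_grid <- function(x, dens) {
  stats::approxfun(x, c(pracma::cumtrapz(x, dens)), rule = 2)
}

# scale-free residual of the stationary-density second-order ODE at x
ode_residual_h <- function(spec, x, step = 1e-3) {
  lam <- spec$lambda; law <- spec$law
  f <- function(u) ggm_pdf(law, u)
  S <- ggm_sf(law, x)
  h <- function(u) stationary_density(spec, u)
  h0 <- h(x)
  h1 <- (h(x + step) - h(x - step)) / (2 * step)
  h2 <- (h(x + step) - 2 * h0 + h(x - step)) / step^2
  fp <- (f(x + step) - f(x - step)) / (2 * step)
  terms <- c(h2, (2 * f(x) / S - lam * S) * h1, (2 * f(x)^2 / S^2 + fp / S) * h0)
  sum(terms) / max(abs(terms))
}

# scale-free residual of the peaks-ratio second-order ODE at x
ode_residual_g <- function(spec, x, step = 1e-3) {
  lam <- spec$lambda; law <- spec$law
  g <- function(u) peaks_density(spec, u) / ggm_pdf(law, u)
  g0 <- g(x)
  g1 <- (g(x + step) - g(x - step)) / (2 * step)
  g2 <- (g(x + step) - 2 * g0 + g(x - step)) / step^2
  terms <- c(g2, -lam * ggm_sf(law, x) * g1, lam * ggm_pdf(law, x) * g0)
  sum(terms) / max(abs(terms))
}
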