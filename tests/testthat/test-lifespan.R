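# Frozen oracle: gamma-Gompertz cdf at the fitted level, computed with an
# independent extended-precision transcription of the distribution function.
test_that("gamma-Gompertz cdf matches the extended-precision reference", {
  law <- lifespan_law(a = 2.951e-5, b = 0.09, gamma = 0.08596)
  expect_lt(abs(ggm_cdf(law, 110) - 0.9944054371141433), 1e-14)
  expect_identical(ggm_cdf(law, 0), 0)
})

test_that("the a*gamma = b case collapses to an exponential law", {
  law <- lifespan_law(a = 1, b = 0.09, gamma = 0.09)   # Exp(1)
  x <- c(0.1, 1, 5, 20)
  expect_equal(ggm_sf(law, x), exp(-x), tolerance = 1e-13)
  expect_equal(ggm_pdf(law, x), exp(-x), tolerance = 1e-13)
  expect_equal(survival_integral(law, 0), 1, tolerance = 1e-12)
})

test_that("cdf/pdf/hazard are a consistent distribution family", {
  laws <- list(lifespan_law(2.951e-5, 0.09, 0.08596),
               lifespan_law(1e-4, 0.11, 0.12, c = 0.001),
               lifespan_law(0.01208, 0.09, 0.08026))
  for (law in laws) {
    x <- seq(0, 140, by = 5)
    Fx <- ggm_cdf(law, x)
    expect_true(all(diff(Fx) >= 0))
    expect_true(all(Fx >= 0 & Fx <= 1))
    # strictly increasing wherever the survival has not underflowed
    live <- ggm_sf(law, x[-1]) > 1e-12
    expect_true(all(diff(Fx)[live] > 0))
    expect_equal(ggm_cdf(law, 0), 0)
    expect_gt(ggm_cdf(law, 200), 1 - 1e-6)
    # density at 0 equals a (+ c for the Makeham variant)
    expect_equal(ggm_pdf(law, 0), law$a + law$c, tolerance = 1e-12)
    # density integrates to one
    expect_equal(stats::integrate(function(u) ggm_pdf(law, u), 0, 300,
                                  rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
    # central difference of the survival reproduces the density (the
    # survival keeps full relative precision deep in the tail)
    s <- 1e-5
    fd <- -(ggm_sf(law, 80 + s) - ggm_sf(law, 80 - s)) / (2 * s)
    expect_lt(abs(fd - ggm_pdf(law, 80)) / ggm_pdf(law, 80), 1e-6)
    # hazard = pdf / survival, non-negative, increasing for c = 0
    hz <- ggm_hazard(law, x)
    expect_equal(hz, ggm_pdf(law, x) / ggm_sf(law, x), tolerance = 1e-12)
    expect_true(all(hz >= 0))
  }
})

test_that("the hazard plateaus at b/gamma + c at extreme ages", {
  for (E in c(0, 30, 60)) {
    tr <- default_mortality_trend(E)
    law <- cohort_law(tr, 2000)
    plateau <- tr$b / tr$gamma + tr$c
    # convergence rate is 1/(1 + a*gamma*e^{bx}/b): by 200 years every
    # fitted law is within 1%, approaching from below
    expect_lt(abs(ggm_hazard(law, 200) - plateau) / plateau, 0.01)
    expect_lt(ggm_hazard(law, 200), plateau)
    x <- seq(50, 200, by = 10)
    expect_true(all(diff(ggm_hazard(law, x)) > 0))
  }
})

test_that("quantile function inverts the cdf, with and without Makeham term", {
  for (law in list(lifespan_law(2.951e-5, 0.09, 0.08596),
                   lifespan_law(1e-4, 0.11, 0.12, c = 0.002))) {
    p <- c(0, 0.1, 0.5, 0.9, 0.999)
    expect_equal(ggm_cdf(law, ggm_quantile(law, p)), p, tolerance = 1e-8)
  }
  expect_error(ggm_quantile(lifespan_law(1, 1, 1), 1), "\\[0, 1\\)")
})

test_that("domain violations raise errors", {
  expect_error(lifespan_law(-1, 0.09, 0.1), "positive")
  expect_error(lifespan_law(1, 0.09, 0.1, c = -0.1), "non-negative")
  law <- lifespan_law(1, 0.09, 0.1)
  expect_error(ggm_cdf(law, -1), "non-negative")
  expect_error(ggm_pdf(law, -0.5), "non-negative")
})

test_that("survival integral: closed form equals quadrature on a generic law", {
  law <- lifespan_law(1e-4, 0.11, 0.12, c = 0.001)
  for (x in c(0, 50, 100)) {
    closed <- survival_integral(law, x)
    quad <- survival_integral(law, x, method = "quadrature")
    expect_lt(abs(closed - quad) / quad, 1e-8)
  }
  # frozen extended-precision references
  expect_lt(abs(survival_integral(law, 0) - 57.258035906665696) / 57.258035906665696, 1e-12)
  expect_lt(abs(survival_integral(law, 100) - 5.5120411748862742e-8) / 5.5120411748862742e-8, 1e-10)
})

test_that("survival integral vanishes monotonically in the deep tail", {
  law <- lifespan_law(2.951e-5, 0.09, 0.08596)
  xs <- c(100, 120, 150, 200)
  vals <- survival_integral(law, xs)
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[length(vals)], 1e-10)
})

test_that("mortality level follows the exponential cohort trend", {
  tr0 <- default_mortality_trend(0)
  expect_identical(mortality_level(tr0, 2000), tr0$K)      # K at the anchor year
  expect_equal(mortality_level(tr0, 2000 + 1 / tr0$alpha), tr0$K / exp(1),
               tolerance = 1e-12)
  tr30 <- default_mortality_trend(30)
  expect_equal(mortality_level(tr30, 1950), tr30$K * exp(50 * tr30$alpha),
               tolerance = 1e-12)
  # strictly decreasing in time
  expect_true(all(diff(mortality_level(tr0, seq(1900, 2100, 25))) < 0))
})

test_that("entry-age conditioning yields a proper conditional law", {
  tr <- default_mortality_trend(0)
  # E = 0 is the identity
  e0 <- entry_age_transform(tr, 2000, 0)
  base <- cohort_law(tr, 2000)
  x <- c(1, 50, 110)
  expect_equal(e0$cdf(x), ggm_cdf(base, x), tolerance = 1e-12)
  expect_equal(e0$pdf(x), ggm_pdf(base, x), tolerance = 1e-12)
  # generic E: starts at zero, integrates to one, cdf matches integrated pdf
  e60 <- entry_age_transform(tr, 2000, 60)
  expect_equal(e60$cdf(0), 0)
  expect_equal(stats::integrate(e60$pdf, 0, 120, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-8)
  quad <- stats::integrate(e60$pdf, 0, 50, rel.tol = 1e-11)$value
  expect_lt(abs(e60$cdf(50) - quad), 1e-8)
})
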