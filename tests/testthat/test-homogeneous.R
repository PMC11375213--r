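test_that("exponential lifespans give the closed-form atom and mass split", {
  toy <- toy_exponential()      # lambda = 1, Exp(1) lifespans
  expect_equal(stationary_point_mass(toy), exp(-1), tolerance = 1e-12)
  tot <- stats::integrate(function(x) stationary_density(toy, x), 0, 80,
                          rel.tol = 1e-10)$value
  expect_equal(tot, 1 - exp(-1), tolerance = 1e-8)
})

test_that("stationary, peaks and reign densities are normalized", {
  hs <- frozen_1955()
  ctr <- recordage:::.hom_center(hs)
  tot_h <- recordage:::.quad_split(function(y) stationary_density(hs, y),
                                   0, 150, ctr)
  expect_lt(abs(tot_h + stationary_point_mass(hs) - 1), 1e-6)
  tot_z <- recordage:::.quad_split(function(y) peaks_density(hs, y), 0, 150, ctr)
  expect_lt(abs(tot_z - 1), 1e-6)
  tot_r <- stats::integrate(function(w) reign_length_density(hs, w), 0, 60,
                            rel.tol = 1e-8)$value
  expect_lt(abs(tot_r - 1), 1e-6)
})

test_that("jump law integrates to one and recovers the stationary density as y grows", {
  hs <- frozen_1955()
  y <- 118
  tot <- stats::integrate(function(x) jump_density_hom(hs, y, x), 0, y - 1e-9,
                          rel.tol = 1e-9)$value + jump_point_mass_hom(hs, y)
  expect_lt(abs(tot - 1), 1e-8)
  # the y -> infinity limit of j_y is the stationary density h
  for (x in c(105, 110, 114)) {
    expect_lt(abs(jump_density_hom(hs, 150, x) - stationary_density(hs, x)) /
                stationary_density(hs, x), 1e-10)
  }
  expect_error(jump_density_hom(hs, 100, 101), "x < y")
})

test_that("first-derivative identity of the jump density holds", {
  hm <- moderate_hom()
  lam <- hm$lambda; law <- hm$law
  y <- 60; s <- 1e-4
  for (x in c(30, 42, 50)) {
    fd <- (jump_density_hom(hm, y, x + s) - jump_density_hom(hm, y, x - s)) / (2 * s)
    expected <- jump_density_hom(hm, y, x) *
      (lam * ggm_sf(law, x) - ggm_hazard(law, x))
    expect_lt(abs(fd - expected) / max(abs(expected), abs(fd)), 1e-5)
  }
})

test_that("stationary density satisfies its second-order ODE", {
  # residuals are scale-free (normalized by the largest term); evaluated
  # where the density carries mass, on two very different specs
  hm <- moderate_hom()
  ctr_m <- recordage:::.hom_center(hm)
  for (x in ctr_m + c(-4, 0, 6, 16)) {
    expect_lt(abs(ode_residual_h(hm, x)), 1e-6)
  }
  hs <- frozen_1955()
  ctr <- recordage:::.hom_center(hs)
  for (x in ctr + c(-1, 1, 3, 6)) {
    expect_lt(abs(ode_residual_h(hs, x)), 1e-6)
  }
})

test_that("peaks density satisfies its second-order ODE", {
  hm <- moderate_hom()
  ctr_m <- recordage:::.hom_center(hm)
  for (x in ctr_m + c(-4, 0, 6)) {
    expect_lt(abs(ode_residual_g(hm, x)), 1e-6)
  }
  hs <- frozen_1955()
  ctr <- recordage:::.hom_center(hs)
  for (x in ctr + c(-1, 1, 3)) {
    expect_lt(abs(ode_residual_g(hs, x)), 1e-6)
  }
})

test_that("peaks density solves its defining integral equation", {
  hs <- frozen_1955()
  law <- hs$law
  ctr <- recordage:::.hom_center(hs)
  eq15 <- function(x) {
    inner <- function(w) {
      upper <- min(x, w)
      if (upper <= 0) return(0)
      stats::integrate(function(y) jump_density_hom(hs, w, y) *
                         ggm_pdf(law, x) / ggm_sf(law, y),
                       0, upper, rel.tol = 1e-9, abs.tol = 1e-13,
                       subdivisions = 400L)$value
    }
    outer_v <- recordage:::.quad_split(function(w)
      vapply(w, function(ww) peaks_density(hs, ww) * inner(ww), numeric(1)),
      0, 150, ctr)
    atom <- recordage:::.quad_split(function(w)
      vapply(w, function(ww) peaks_density(hs, ww) * jump_point_mass_hom(hs, ww),
             numeric(1)), 0, 150, ctr) * ggm_pdf(law, x)
    (outer_v + atom - peaks_density(hs, x)) / peaks_density(hs, x)
  }
  for (x in c(108, 112, 116)) {
    expect_lt(abs(eq15(x)), 1e-4)
  }
})

test_that("point-mass balance holds where the atom is non-negligible", {
  toy <- toy_exponential()
  m <- stationary_point_mass(toy)
  rhs <- stats::integrate(function(y) vapply(y, function(yy)
    stationary_density(toy, yy) * ggm_hazard(toy$law, yy) *
      jump_density_hom(toy, yy, 0), numeric(1)),
    0, 60, rel.tol = 1e-10, abs.tol = 1e-14, subdivisions = 500L)$value
  expect_lt(abs(m * toy$lambda - rhs) / (m * toy$lambda), 1e-8)
})

test_that("reign-length normalizer identity holds", {
  # int f e^{-lambda G} dy (peaks normalizer) = int h (1-F) dy + m
  for (spec in list(frozen_1955(), toy_exponential())) {
    lhs <- recordage:::.peaks_norm(spec)
    rhs <- recordage:::.reign_norm(spec)
    expect_lt(abs(lhs - rhs) / rhs, 1e-8)
  }
})

test_that("reign length differs from the stationary remaining reign", {
  hs <- frozen_1955()
  law <- hs$law
  ctr <- recordage:::.hom_center(hs)
  log_sf <- function(u) -log1p(law$a * law$gamma / law$b * expm1(law$b * u)) / law$gamma
  rr_num <- function(w) recordage:::.quad_split(function(y) {
    v <- stationary_density(hs, y) *
      exp(log(pmax(ggm_pdf(law, y + w), 1e-300)) - log_sf(y))
    ifelse(is.finite(v), v, 0)
  }, 0, 150, ctr)
  rr_tot <- stats::integrate(function(w) vapply(w, rr_num, numeric(1)), 0, 60,
                             rel.tol = 1e-7)$value
  rr_mean <- stats::integrate(function(w) vapply(w, function(ww) ww * rr_num(ww),
                                                 numeric(1)), 0, 60,
                              rel.tol = 1e-7)$value / rr_tot
  expect_gt(abs(rr_mean - expected_reign_length(hs)), 0.01)
})

test_that("expected reign length matches direct Monte Carlo for the toy model", {
  toy <- toy_exponential()
  EW <- expected_reign_length(toy)
  pop <- simulate_population(function(t) rep(1, length(t)),
                             function(p, t) ggm_quantile(toy$law, p),
                             c(-40, 1.2e5), seed = 7)
  tr <- extract_record_trajectory(pop, c(0, 1.2e5))
  mc <- mean(tr$holders$reign)
  se <- stats::sd(tr$holders$reign) / sqrt(nrow(tr$holders))
  expect_lt(abs(mc - EW), 3 * se)
})
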