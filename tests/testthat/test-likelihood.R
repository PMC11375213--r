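test_that("titleholder validation enforces ordering and the birth-date relation", {
  # consistent pair: both rows give birth date 1880.0 for the successor
  ok <- titleholder_records(t = c(1990.0, 1992.5), y = c(112.0, 112.5),
                            z = c(110.0, 111.0), tol = 1e-6)
  expect_s3_class(ok, "titleholder_records")
  expect_equal(nrow(ok), 2)
  # perturbing the second death age breaks the relation by 0.1 years
  expect_error(titleholder_records(t = c(1990.0, 1992.5), y = c(112.0, 112.6),
                                   z = c(110.0, 111.0), tol = 1e-6),
               "record 2.*0\\.1")
  # successor older than the incumbent's death age
  expect_error(titleholder_records(t = 1990, y = 110, z = 112), "0 < z < y")
  expect_error(titleholder_records(t = c(1992, 1990), y = c(112, 112),
                                   z = c(110, 110)), "sorted")
})

test_that("one-record log-likelihood matches an independent quadrature transcription", {
  spec <- spec_default()
  bi <- spec$bi; tr <- spec$trend
  rec <- list(t = 1997.5, y = 114.2, z = 111.3)
  # independent transcription: written from scratch against the formulas,
  # using only base R and adaptive quadrature
  a_at <- function(s) tr$K * exp(-tr$alpha * (s - 2000))
  sf <- function(x, a) (1 + a * tr$gamma / tr$b * expm1(tr$b * x))^(-1 / tr$gamma)
  pdf <- function(x, a) a * exp(tr$b * x) *
    (1 + a * tr$gamma / tr$b * expm1(tr$b * x))^(-1 - 1 / tr$gamma)
  lam <- function(s) bi$C * exp(bi$kappa * s)
  expo <- stats::integrate(function(u) lam(rec$t - u) * sf(u, a_at(rec$t - u)),
                           rec$z, rec$y, rel.tol = 1e-12, abs.tol = 1e-14)$value
  oracle <- log(pdf(rec$y, a_at(rec$t - rec$y))) - expo +
    log(lam(rec$t - rec$z)) + log(sf(rec$z, a_at(rec$t - rec$z)))
  expect_lt(abs(record_loglik_term(spec, rec) - oracle), 1e-8)
  # conditioning on the previous successor age subtracts a log-survival
  prev <- 109.4
  expect_equal(record_loglik_term(spec, rec, prev_z = prev),
               oracle - log(sf(prev, a_at(rec$t - rec$y))), tolerance = 1e-8)
  expect_error(record_loglik_term(spec, rec, prev_z = 115), "below the death age")
})

test_that("per-record terms telescope to the full-sample log-likelihood", {
  spec <- spec_default()
  recs <- make_synthetic_titleholders(spec, c(1955, 1975), seed = 3)
  df <- as.data.frame(recs)
  terms <- vapply(seq_len(nrow(df)), function(i)
    record_loglik_term(spec, df[i, ], if (i > 1) df$z[i - 1] else NULL),
    numeric(1))
  ll <- log_likelihood(recs, alpha = spec$trend$alpha, K = spec$trend$K,
                       gamma = spec$trend$gamma, b = spec$trend$b,
                       include_constants = TRUE)
  expect_lt(abs(sum(terms) - ll), 1e-8)
  # constants are n log C + sum kappa (t - z + E)
  ll0 <- log_likelihood(recs, spec$trend$alpha, spec$trend$K, spec$trend$gamma)
  expect_equal(ll - ll0,
               nrow(df) * log(spec$bi$C) + sum(spec$bi$kappa * (df$t - df$z)),
               tolerance = 1e-10)
})

test_that("the packaged optimum is a local maximum in gamma on synthetic data", {
  spec <- spec_default()
  recs <- make_synthetic_titleholders(spec, c(1955, 2019), seed = 12)
  fit <- fit_parameters(recs)
  at <- function(g) log_likelihood(recs, fit$alpha, fit$K, g)
  expect_gt(at(fit$gamma), at(fit$gamma * 0.5))
  expect_gt(at(fit$gamma), at(fit$gamma * 1.5))
})

test_that("meta-optimization recovers generating parameters and keeps a monotone trace", {
  spec <- spec_default()
  recs <- make_synthetic_titleholders(spec, c(1955, 2019), seed = 5)
  fit <- fit_parameters(recs)
  expect_lt(abs(fit$alpha / spec$trend$alpha - 1), 0.3)
  expect_lt(abs(fit$gamma / spec$trend$gamma - 1), 0.3)
  expect_true(fit$K / spec$trend$K > 0.4 && fit$K / spec$trend$K < 2.5)
  expect_true(all(diff(fit$trace$loglik) >= 0))
  expect_true(all(diff(fit$trace$tol) <= 0))
  expect_gt(fit$loglik_full, fit$loglik)   # constants are positive here
})

test_that("log-space and raw-space optimization reach the same optimum", {
  spec <- spec_default()
  recs <- make_synthetic_titleholders(spec, c(1955, 2019), seed = 5)
  guard <- function(v) if (is.finite(v)) v else 1e10
  nll_log <- function(th) guard(tryCatch(
    -log_likelihood(recs, exp(th[1]), exp(th[2]), exp(th[3])),
    error = function(e) NA_real_))
  nll_raw <- function(p) {
    if (any(p <= 0)) return(1e10)
    guard(tryCatch(-log_likelihood(recs, p[1], p[2], p[3]),
                   error = function(e) NA_real_))
  }
  run_meta <- function(fn, par) {
    best <- fn(par)
    for (i in 1:6) {
      o <- stats::optim(par, fn, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-12))
      if (o$value < best) { best <- o$value; par <- o$par }
    }
    best
  }
  init <- c(0.01, 1e-4, 0.1)
  expect_lt(abs(run_meta(nll_log, log(init)) - run_meta(nll_raw, init)), 1e-4)
})

test_that("free rate-of-aging optimization degenerates towards zero mortality", {
  # the known failure mode: with b free, the level K collapses below 1e-10
  # ('almost no mortality before 100') while the likelihood barely improves
  spec <- spec_default()
  recs <- make_synthetic_titleholders(spec, c(1955, 2019), seed = 5)
  nll4 <- function(th) {
    v <- tryCatch(-log_likelihood(recs, alpha = exp(th[1]), K = exp(th[2]),
                                  gamma = exp(th[4]), b = exp(th[3])),
                  error = function(e) NA_real_)
    if (is.finite(v)) v else 1e10
  }
  th <- log(c(0.01, 1e-4, 0.09, 0.1))
  for (i in 1:3) {
    th <- stats::optim(th, nll4, method = "Nelder-Mead",
                       control = list(maxit = 4000, reltol = 1e-13))$par
  }
  expect_lt(exp(th[2]), 1e-10)
  # survival to age 100 is essentially 1 under the degenerate law
  degen <- lifespan_law(exp(th[2]), exp(th[3]), exp(th[4]))
  expect_gt(ggm_sf(degen, 100), 0.9)
  # and the guard in the constrained fitter fires in that regime
  expect_warning(
    fit_parameters(recs, init = c(alpha = 0.01, K = 5e-11, gamma = 0.1),
                   meta = list(max_meta = 1L, maxit = 2L)),
    "degenerate")
})

test_that("sensitivity scan returns the full grid with gamma increasing in b", {
  spec <- spec_default()
  recs <- make_synthetic_titleholders(spec, c(1955, 2019), seed = 8)
  scan <- sensitivity_scan(recs, E = 0, b = c(0.09, 0.13))
  expect_equal(nrow(scan), 2)
  expect_true(all(scan$error == ""))
  expect_gt(scan$gamma[scan$b == 0.13], scan$gamma[scan$b == 0.09])
})

test_that("backtest splits records and reports band coverage", {
  spec <- spec_default()
  recs <- make_synthetic_titleholders(spec, c(1955, 2019), seed = 21)
  bt <- backtest_split(recs, cutoff = 1988)
  expect_lt(max(bt$fit$n), nrow(recs))
  expect_equal(nrow(bt$holdout), sum(recs$t > 1988))
  expect_true(all(c("pred_mean", "pred_sd", "inside_band") %in% names(bt$holdout)))
  expect_equal(bt$coverage, 1 - bt$n_outside / nrow(bt$holdout))
  # degenerate split: cutoff beyond the last record trains on everything
  bt2 <- backtest_split(recs, cutoff = 2025)
  expect_equal(bt2$fit$n, nrow(recs))
  expect_null(bt2$holdout)
  expect_error(backtest_split(recs, cutoff = 1956), "fewer than 10")
})

test_that("near-stationary data give consistent train and full fits", {
  trend0 <- mortality_trend(K = 2e-4, alpha = 1e-9, b = 0.09, gamma = 0.086)
  spec0 <- model_spec(birth_intensity(C = 6e7, kappa = 1e-9), trend0)
  recs0 <- make_synthetic_titleholders(spec0, c(1900, 2019), seed = 9)
  bt <- backtest_split(recs0, cutoff = 1960, bi = spec0$bi)
  full <- fit_parameters(recs0, bi = spec0$bi)
  expect_lt(abs(bt$fit$gamma / full$gamma - 1), 0.25)
  expect_true(bt$fit$K / full$K > 0.5 && bt$fit$K / full$K < 2)
  expect_gt(bt$coverage, 0.5)
})
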