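#' Log-likelihood contribution of one titleholder transition
#'
#' The likelihood of the transition `(t, y, z)` given the previous
#' successor age `prev_z` factorizes as the death density of the incumbent
#' (conditioned on having already reached age `prev_z`) times the jump
#' density of the successor's age:
#' \deqn{\frac{f^E_{t-y+E}(y-E)}{1 - F^E_{t-y+E}(\mathrm{prev}_z - E)}\;
#'   j^E_{y,t}(z).}
#' For the first record the conditioning factor is absent.  The jump factor
#' contributes the exponent integral
#' \eqn{-\int_z^y \lambda_E(t-u+E)(1-F^E_{t-u+E}(u-E))\,du} plus
#' \eqn{\log \lambda_E(t-z+E) + \log(1-F^E_{t-z+E}(z-E))}; the survival
#' factor cancels with the next record's conditioning when terms are
#' chained, which is exactly the telescoped full-sample log-likelihood.
#'
#' @param spec A [model_spec()].
#' @param rec A list or one-row data frame with `t`, `y`, `z`.
#' @param prev_z Previous successor age, or `NULL` for the first record.
#' @return The log-likelihood contribution (a scalar).
#' @export
record_loglik_term <- function(spec, rec, prev_z = NULL) {
  E <- spec$E
  tr <- spec$trend; bi <- spec$bi
  t <- rec$t; y <- rec$y; z <- rec$z
  if (y - E <= 0) stop("record_loglik_term: death age is below the entry age")
  if (!is.null(prev_z) && prev_z >= y)
    stop("record_loglik_term: prev_z must be below the death age y")
  a_death <- mortality_level(tr, t - y + E)
  out <- log(ggm_pdf(lifespan_law(a_death, tr$b, tr$gamma, tr$c), y - E))
  if (!is.null(prev_z))
    out <- out - .ggm_log_sf(a_death, tr$b, tr$gamma, tr$c, prev_z - E)
  # jump term: exponent integral + log intensity + log survival at z
  out <- out - .exponent(spec, t, z, upper = y)
  a_z <- mortality_level(tr, t - z + E)
  out + log(intensity_at(bi, t - z + E)) +
    .ggm_log_sf(a_z, tr$b, tr$gamma, tr$c, z - E)
}

# fixed Gauss-Legendre rule for the per-record exponent integrals
.gl_nodes <- local({
  cache <- NULL
  function(n = 25) {
    if (is.null(cache)) cache <<- pracma::gaussLegendre(n, -1, 1)
    cache
  }
})

#' Log-likelihood of a titleholder sample
#'
#' The telescoped full-sample log-likelihood for the gamma-Gompertz model
#' with exponential entry-cohort intensity: for each record, the log death
#' density of the incumbent minus the exponent integral over `[z, y]`, plus
#' the final survival term of the last successor.  The parameter-free terms
#' \eqn{n \log C + \sum_i \kappa (t_i - z_i + E)} are omitted by default
#' (they do not affect the maximization) and restored with
#' `include_constants = TRUE` for absolute comparisons.
#'
#' The per-record exponent integrals use a fixed 25-point Gauss-Legendre
#' rule (the integrand is smooth on the short interval `[z, y]`); the
#' mortality level inside the integrand varies with the integration
#' variable, so no closed form applies.
#'
#' @param records A [titleholder_records()] table (validated).
#' @param alpha,K,gamma Mortality-trend parameters to evaluate.
#' @param b Fixed rate of aging.
#' @param E Entry age.
#' @param bi A [birth_intensity()]; defaults to the packaged constants for
#'   `E`.
#' @param c Extrinsic mortality (0 in the fitted model).
#' @param include_constants Restore the parameter-free terms.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(records, alpha, K, gamma, b = 0.09, E = 0,
                           bi = default_birth_intensity(E), c = 0,
                           include_constants = FALSE) {
  df <- as.data.frame(records)
  t <- df$t; y <- df$y; z <- df$z
  if (any(y - E <= 0)) stop("death age below entry age at record ",
                            which(y - E <= 0)[1])
  a_death <- K * exp(-alpha * (t - y + E - 2000))
  lz <- log1p(a_death * gamma / b * expm1(b * (y - E)))
  logf <- log(a_death) + b * (y - E) - (1 + 1 / gamma) * lz
  if (c > 0) {
    law_f <- function(a, x) log(ggm_pdf(lifespan_law(a, b, gamma, c), x))
    logf <- mapply(law_f, a_death, y - E)
  }
  # exponent integrals over [z_i, y_i], Gauss-Legendre on each interval
  gl <- .gl_nodes()
  mid <- (y + z) / 2; half <- (y - z) / 2
  u <- outer(half, gl$x) + mid                     # n x 25 ages
  tc <- t - u + E                                  # cohort-entry times
  a_u <- K * exp(-alpha * (tc - 2000))
  lsf <- .ggm_log_sf(a_u, b, gamma, c, u - E)
  integ <- bi$C * exp(bi$kappa * tc) * exp(lsf)
  I <- as.vector((half * integ) %*% gl$w)
  # final survival term for the last successor
  n <- length(t)
  a_last <- K * exp(-alpha * (t[n] - z[n] + E - 2000))
  last <- .ggm_log_sf(a_last, b, gamma, c, z[n] - E)
  ll <- sum(logf) - sum(I) + last
  if (!is.finite(ll)) {
    bad <- which(!is.finite(logf - I))
    stop("non-finite log-likelihood contribution at record ",
         if (length(bad)) bad[1] else n)
  }
  if (include_constants)
    ll <- ll + n * log(bi$C) + sum(bi$kappa * (t - z + E))
  ll
}

#' Maximum-likelihood fit of the mortality trend
#'
#' Fits \eqn{(\alpha, K, \gamma)} for a fixed rate of aging `b` by repeated
#' Nelder-Mead runs in log-parameter space (positivity is enforced by the
#' parameterization).  After each run the convergence tolerance is rescaled
#' by the ratio of achieved improvements, clamped to `[0.1, 1]`, and the
#' next run warm-starts from the current optimum — a dynamic-tolerance
#' schedule in the spirit of learning-rate scheduling.  The meta-loop stops
#' when the improvement falls below `stop_improvement` or after
#' `max_meta` rounds.
#'
#' Freeing `b` as a fourth parameter drives the optimizer into degenerate
#' gamma-Gompertz laws (the level `K` collapses towards zero, leaving
#' almost no mortality before age 100, because titleholder data only
#' constrain the lifespan tail); a guard warns when `K` drops below
#' `1e-10`.
#'
#' @param records A [titleholder_records()] table.
#' @param E Entry age.
#' @param b Fixed rate of aging.
#' @param init Starting values `c(alpha, K, gamma)`.
#' @param bi A [birth_intensity()].
#' @param meta List of meta-schedule settings: `tol0` (initial relative
#'   tolerance), `stop_improvement`, `max_meta`, `maxit` per run.
#' @return An object of class `record_fit`: a list with `alpha`, `K`,
#'   `gamma`, `b`, `E`, `loglik` (constants omitted), `loglik_full`
#'   (constants restored), `trace` (per-round log-likelihood and
#'   tolerance), `convergence`.
#' @export
fit_parameters <- function(records, E = 0, b = 0.09,
                           init = c(alpha = 0.01, K = 1e-4, gamma = 0.1),
                           bi = default_birth_intensity(E),
                           meta = list()) {
  records <- validate_records(records)
  meta <- utils::modifyList(list(tol0 = 1e-3, stop_improvement = 1e-6,
                                 max_meta = 12L, maxit = 2000L), meta)
  nll <- function(theta) {
    p <- exp(theta)
    if (p[2] < 1e-10)
      warning("K below 1e-10: the optimizer is entering the degenerate regime ",
              "with almost no mortality before age 100", call. = FALSE)
    -log_likelihood(records, alpha = p[1], K = p[2], gamma = p[3],
                    b = b, E = E, bi = bi)
  }
  theta <- log(unname(init))
  tol <- meta$tol0
  prev <- nll(theta)
  prev_imp <- NA_real_
  trace <- data.frame(round = integer(), loglik = numeric(), tol = numeric())
  for (k in seq_len(meta$max_meta)) {
    opt <- stats::optim(theta, nll, method = "Nelder-Mead",
                        control = list(reltol = tol, maxit = meta$maxit))
    imp <- prev - opt$value
    if (opt$value <= prev) { theta <- opt$par; prev <- opt$value }
    trace <- rbind(trace, data.frame(round = k, loglik = -prev, tol = tol))
    if (imp < meta$stop_improvement) break
    if (!is.na(prev_imp) && prev_imp > 0)
      tol <- tol * min(1, max(0.1, imp / prev_imp))
    else
      tol <- tol * 0.1
    prev_imp <- imp
  }
  p <- exp(theta)
  out <- list(alpha = p[1], K = p[2], gamma = p[3], b = b, E = E,
              loglik = -prev,
              loglik_full = log_likelihood(records, p[1], p[2], p[3], b = b,
                                           E = E, bi = bi,
                                           include_constants = TRUE),
              trace = trace, init = init, n = nrow(records))
  class(out) <- "record_fit"
  out
}

#' @export
print.record_fit <- function(x, ...) {
  cat(sprintf(paste0("record-process ML fit (E = %g, b fixed at %g, n = %d)\n",
                     "  alpha = %.5g, K = %.5g, gamma = %.5g\n",
                     "  loglik = %.4f (with constants: %.4f), %d meta-rounds\n"),
              x$E, x$b, x$n, x$alpha, x$K, x$gamma,
              x$loglik, x$loglik_full, nrow(x$trace)))
  invisible(x)
}

#' Sensitivity scan over entry ages and rates of aging
#'
#' Refits the trend on a grid of `E` and fixed `b` values, the standard
#' sensitivity analysis for the fixed-`b` design.  Failures in single cells
#' are recorded and the scan continues.
#'
#' @param records A [titleholder_records()] table.
#' @param E Entry ages to scan. Only ages with packaged birth constants
#'   (0, 30, 60) are supported unless `bi_list` supplies intensities.
#' @param b Rates of aging to scan.
#' @param bi_list Optional named list (by entry age) of
#'   [birth_intensity()] objects.
#' @param ... Passed to [fit_parameters()].
#' @return A data frame with one row per grid cell: `E`, `b`, `alpha`,
#'   `K`, `gamma`, `loglik`, `loglik_full`, `error`.
#' @export
sensitivity_scan <- function(records, E = c(0, 30, 60),
                             b = c(0.09, 0.11, 0.13, 0.15),
                             bi_list = NULL, ...) {
  grid <- expand.grid(E = E, b = b)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    Ei <- grid$E[i]; bi_par <- grid$b[i]
    bi <- if (!is.null(bi_list)) bi_list[[as.character(Ei)]]
          else default_birth_intensity(Ei)
    res <- tryCatch(fit_parameters(records, E = Ei, b = bi_par, bi = bi, ...),
                    error = function(e) e)
    if (inherits(res, "error"))
      data.frame(E = Ei, b = bi_par, alpha = NA, K = NA, gamma = NA,
                 loglik = NA, loglik_full = NA, error = conditionMessage(res))
    else
      data.frame(E = Ei, b = bi_par, alpha = res$alpha, K = res$K,
                 gamma = res$gamma, loglik = res$loglik,
                 loglik_full = res$loglik_full, error = "")
  })
  do.call(rbind, rows)
}

#' Backtest: fit on early records, compare predictions with the holdout
#'
#' Fits the trend on records up to `cutoff`, then compares the
#' fixed-point mean +/- one standard deviation band predicted by the
#' trained model against the held-out record ages.
#'
#' @param records A [titleholder_records()] table.
#' @param cutoff Calendar year splitting train and holdout.
#' @param E,b,... Passed to [fit_parameters()].
#' @return A list with `fit` (on the training records), `holdout` (data
#'   frame of held-out transitions with predicted mean/sd and an
#'   `inside_band` flag), `n_outside`, `coverage`.
#' @export
backtest_split <- function(records, cutoff, E = 0, b = 0.09, ...) {
  df <- as.data.frame(records)
  train <- df[df$t <= cutoff, ]
  test <- df[df$t > cutoff, ]
  if (nrow(train) < 10)
    stop("backtest_split: fewer than 10 training records before the cutoff")
  fit <- fit_parameters(validate_records(train), E = E, b = b, ...)
  spec <- model_spec(default_birth_intensity(E),
                     mortality_trend(K = fit$K, alpha = fit$alpha, b = b,
                                     gamma = fit$gamma, E = E))
  holdout <- NULL
  if (nrow(test) > 0) {
    pred <- lapply(test$t, function(tt) mean_age_fixed_point(spec, tt))
    holdout <- data.frame(t = test$t, y = test$y,
                          pred_mean = vapply(pred, `[[`, numeric(1), "mean"),
                          pred_sd = vapply(pred, `[[`, numeric(1), "sd"))
    holdout$inside_band <- abs(holdout$y - holdout$pred_mean) <= holdout$pred_sd
  }
  list(fit = fit, holdout = holdout,
       n_outside = if (is.null(holdout)) 0L else sum(!holdout$inside_band),
       coverage = if (is.null(holdout)) NA_real_ else mean(holdout$inside_band))
}
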