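# Packaged parameter constants for the titleholder model.
#
# Birth-intensity constants come from log-linear regressions of United
# Nations cohort counts (newborns, 30-year-olds, 60-year-olds since 1950);
# they are shipped as authoritative constants and never re-derived here.
# Mortality-trend constants are the maximum-likelihood estimates on the
# 1955-2019 oldest-person titleholder record for each entry age E and
# several fixed values of the rate of aging b.

.birth_constants <- list(
  `0`  = list(C = 6270,      kappa = 0.004987),
  `30` = list(C = 4.680e-9,  kappa = 0.01876),
  `60` = list(C = 3.249e-11, kappa = 0.02085)
)

# fitted (alpha, K, gamma) by rate of aging b, then entry age E
.trend_constants <- list(
  `0.09` = list(
    `0`  = list(alpha = 0.01277, K = 2.951e-5, gamma = 0.08596, loglik = -119.64),
    `30` = list(alpha = 0.01124, K = 5.950e-4, gamma = 0.08061, loglik = -117.68),
    `60` = list(alpha = 0.01110, K = 0.01208,  gamma = 0.08026, loglik = -117.27)
  ),
  `0.11` = list(
    `0`  = list(alpha = 0.01561, K = 3.728e-6, gamma = 0.1160, loglik = -119.48),
    `30` = list(alpha = 0.01376, K = 1.495e-4, gamma = 0.1117, loglik = -117.51),
    `60` = list(alpha = 0.01352, K = 5.901e-3, gamma = 0.1110, loglik = -117.09)
  ),
  `0.13` = list(
    `0`  = list(alpha = 0.01845, K = 4.530e-7, gamma = 0.1441,  loglik = -119.37),
    `30` = list(alpha = 0.01628, K = 3.613e-5, gamma = 0.14065, loglik = -117.40),
    `60` = list(alpha = 0.01596, K = 2.784e-3, gamma = 0.1399,  loglik = -116.98)
  ),
  `0.15` = list(
    `0`  = list(alpha = 0.02129, K = 5.362e-8, gamma = 0.1708, loglik = -119.31),
    `30` = list(alpha = 0.01880, K = 8.500e-6, gamma = 0.1681, loglik = -117.34),
    `60` = list(alpha = 0.01842, K = 1.281e-3, gamma = 0.1674, loglik = -116.91)
  )
)

# parameters refitted on the 1955-1988 titleholder subsample (E = 0, b = 0.09)
.backtest_constants <- list(alpha = 0.01516, K = 2.064e-5, gamma = 0.08413)

#' Packaged birth-intensity constants
#'
#' Returns the exponential cohort-intensity constants \eqn{C_E, \kappa_E}
#' for entry age `E` in 0, 30 or 60 as a [birth_intensity()].
#'
#' @param E Entry age: 0, 30 or 60.
#' @export
default_birth_intensity <- function(E = 0) {
  key <- as.character(E)
  if (is.null(.birth_constants[[key]]))
    stop("packaged birth constants exist only for E in {0, 30, 60}")
  p <- .birth_constants[[key]]
  birth_intensity(C = p$C, kappa = p$kappa, E = E)
}

#' Packaged fitted mortality-trend constants
#'
#' Returns the maximum-likelihood \eqn{(\alpha_E, K_E, \gamma_E)} constants
#' for entry age `E` in 0, 30, 60 and fixed rate of aging `b` in 0.09,
#' 0.11, 0.13 or 0.15 as a [mortality_trend()].
#'
#' @param E Entry age: 0, 30 or 60.
#' @param b Rate of aging: 0.09 (default), 0.11, 0.13 or 0.15.
#' @export
default_mortality_trend <- function(E = 0, b = 0.09) {
  bk <- sprintf("%.2f", b)
  if (is.null(.trend_constants[[bk]]))
    stop("packaged trend constants exist only for b in {0.09, 0.11, 0.13, 0.15}")
  p <- .trend_constants[[bk]][[as.character(E)]]
  if (is.null(p)) stop("packaged trend constants exist only for E in {0, 30, 60}")
  mortality_trend(K = p$K, alpha = p$alpha, b = b, gamma = p$gamma, E = E)
}

#' Reported maximized log-likelihood for a packaged parameter column
#'
#' @inheritParams default_mortality_trend
#' @return The maximized log-likelihood (including the parameter-free
#'   constant terms) associated with the packaged fit.
#' @export
default_fit_loglik <- function(E = 0, b = 0.09) {
  .trend_constants[[sprintf("%.2f", b)]][[as.character(E)]]$loglik
}

#' Mortality trend refitted on pre-1988 titleholder data
#'
#' The backtest column: parameters estimated with entry age 0 and
#' `b = 0.09` using only records up to 1988 (the accession of the
#' longest-lived titleholder).
#'
#' @export
backtest_mortality_trend <- function() {
  p <- .backtest_constants
  mortality_trend(K = p$K, alpha = p$alpha, b = 0.09, gamma = p$gamma, E = 0)
}

#' Packaged full model specification
#'
#' Convenience constructor combining [default_birth_intensity()] and
#' [default_mortality_trend()] into a [model_spec()].
#'
#' @inheritParams default_mortality_trend
#' @param x_max Age truncation in years.
#' @export
default_model_spec <- function(E = 0, b = 0.09, x_max = 150) {
  model_spec(default_birth_intensity(E), default_mortality_trend(E, b), x_max = x_max)
}
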