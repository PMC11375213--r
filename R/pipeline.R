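#' Read a model configuration file
#'
#' Flat YAML (or JSON-compatible YAML) keys: `E`, `C`, `kappa`, `K`,
#' `alpha`, `b`, `gamma`, `c` (optional, default 0), `x_max` (optional).
#' Any field left `NULL` falls back to the packaged defaults for `E`/`b`.
#'
#' @param path Config file path.
#' @return A [model_spec()].
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  E <- cfg$E %||% 0
  b <- cfg$b %||% 0.09
  bi <- if (is.null(cfg$C) || is.null(cfg$kappa)) default_birth_intensity(E)
        else birth_intensity(cfg$C, cfg$kappa, E)
  trend <- if (is.null(cfg$K) || is.null(cfg$alpha) || is.null(cfg$gamma))
    default_mortality_trend(E, b)
  else mortality_trend(K = cfg$K, alpha = cfg$alpha, b = b,
                       gamma = cfg$gamma, E = E, c = cfg$c %||% 0)
  model_spec(bi, trend, x_max = cfg$x_max %||% 150)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a model configuration file
#'
#' @param spec A [model_spec()].
#' @param path Output YAML path.
#' @export
write_model_config <- function(spec, path) {
  yaml::write_yaml(list(E = spec$E, C = spec$bi$C, kappa = spec$bi$kappa,
                        K = spec$trend$K, alpha = spec$trend$alpha,
                        b = spec$trend$b, gamma = spec$trend$gamma,
                        c = spec$trend$c, x_max = spec$x_max), path)
  invisible(path)
}

#' Run a titleholder-model workflow
#'
#' Thin programmatic entry point behind the command-line script: executes
#' one of the `fit`, `predict`, `simulate`, `homogeneous` or `backtest`
#' workflows and writes its artifacts (JSON for fits, CSV for densities
#' and simulations) under `out_dir`.
#'
#' @param command One of `"fit"`, `"predict"`, `"simulate"`,
#'   `"homogeneous"`, `"backtest"`.
#' @param spec A [model_spec()] (see [read_model_config()]); for `fit` it
#'   supplies the birth intensity and initial values context.
#' @param out_dir Output directory (created if missing).
#' @param data Path to a titleholder CSV (for `fit` / `backtest`).
#' @param years Evaluation years (for `predict`).
#' @param window Simulation window (for `simulate`).
#' @param seed Seed (for `simulate`).
#' @param cutoff Backtest cutoff year.
#' @param lambda,law Optional constant birth rate and [lifespan_law()] for
#'   the `homogeneous` workflow; by default the full model is frozen at the
#'   fixed point of `window[2]` instead.
#' @param grid_step Age-grid step for densities.
#' @param dialect CSV dialect for `data`.
#' @param quiet Suppress progress messages.
#' @return A list with the computed results (also written to `out_dir`).
#' @export
run_pipeline <- function(command = c("fit", "predict", "simulate",
                                     "homogeneous", "backtest"),
                         spec = default_model_spec(), out_dir = ".",
                         data = NULL, years = seq(1960, 2100, by = 20),
                         window = c(1955, 2019), seed = 1, cutoff = 1988,
                         lambda = NULL, law = NULL,
                         grid_step = 0.05, dialect = "decimal_year",
                         quiet = FALSE) {
  command <- match.arg(command)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }
  log_lines <- c(sprintf("recordage %s | command=%s | seed=%d | grid_step=%g",
                         as.character(utils::packageVersion("recordage")),
                         command, seed, grid_step),
                 sprintf("spec: E=%g b=%g alpha=%g K=%g gamma=%g C=%g kappa=%g x_max=%g",
                         spec$E, spec$trend$b, spec$trend$alpha, spec$trend$K,
                         spec$trend$gamma, spec$bi$C, spec$bi$kappa, spec$x_max))
  result <- switch(
    command,
    fit = {
      recs <- stage("read", read_titleholders(data, dialect = dialect))
      fit <- stage("fit", fit_parameters(recs, E = spec$E, b = spec$trend$b,
                                         bi = spec$bi))
      out <- list(alpha = fit$alpha, K = fit$K, gamma = fit$gamma,
                  b = fit$b, E = fit$E, loglik = fit$loglik,
                  loglik_with_constants = fit$loglik_full,
                  trace = fit$trace, n = fit$n)
      .write_json(out, file.path(out_dir, "fit.json"))
      say("fit: alpha=%.5g K=%.5g gamma=%.5g loglik=%.3f",
          fit$alpha, fit$K, fit$gamma, fit$loglik)
      fit
    },
    predict = {
      dists <- stage("predict", predict_age_density_series(spec, years,
                                                           step = grid_step))
      dens <- do.call(rbind, lapply(dists, function(d)
        data.frame(year = d$t, age = d$x, density = d$density)))
      summ <- do.call(rbind, lapply(years, function(t) {
        fp <- mean_age_fixed_point(spec, t)
        data.frame(year = t, mean = fp$mean, sd = fp$sd)
      }))
      utils::write.csv(dens, file.path(out_dir, "densities.csv"), row.names = FALSE)
      utils::write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
      say("predict: %d years written", length(years))
      list(densities = dens, summary = summ)
    },
    simulate = {
      recs <- stage("simulate",
                    make_synthetic_titleholders(spec, window, seed,
                                                path = file.path(out_dir, "titleholders.csv")))
      say("simulate: %d transitions on [%g, %g]", nrow(recs), window[1], window[2])
      recs
    },
    homogeneous = {
      hspec <- if (!is.null(lambda) && !is.null(law))
        stage("build", homogeneous_spec(lambda, law))
      else
        stage("freeze", frozen_homogeneous_spec(spec, window[2]))
      ages <- seq(0, spec$x_max, by = max(grid_step, 0.05))
      tab <- data.frame(age = ages,
                        record_density = stationary_density(hspec, ages),
                        peaks_density = peaks_density(hspec, ages))
      ws <- seq(0, 20, by = max(grid_step, 0.05))
      reign <- data.frame(length = ws, density = reign_length_density(hspec, ws))
      utils::write.csv(tab, file.path(out_dir, "stationary.csv"), row.names = FALSE)
      utils::write.csv(reign, file.path(out_dir, "reign.csv"), row.names = FALSE)
      say("homogeneous: lambda = %g, expected reign %.3f years",
          hspec$lambda, expected_reign_length(hspec))
      list(stationary = tab, reign = reign)
    },
    backtest = {
      recs <- stage("read", read_titleholders(data, dialect = dialect))
      bt <- stage("backtest", backtest_split(recs, cutoff, E = spec$E,
                                             b = spec$trend$b))
      out <- list(alpha = bt$fit$alpha, K = bt$fit$K, gamma = bt$fit$gamma,
                  loglik = bt$fit$loglik, n_outside = bt$n_outside,
                  coverage = bt$coverage)
      .write_json(out, file.path(out_dir, "backtest.json"))
      if (!is.null(bt$holdout))
        utils::write.csv(bt$holdout, file.path(out_dir, "backtest_holdout.csv"),
                         row.names = FALSE)
      say("backtest: cutoff %g, coverage %.2f", cutoff, bt$coverage)
      bt
    })
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(result)
}

.write_json <- function(x, path) {
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    # minimal fallback: scalar fields only
    flat <- x[!vapply(x, is.data.frame, logical(1))]
    vals <- vapply(flat, function(v) {
      if (is.character(v)) sprintf('"%s"', v) else format(v, digits = 15)
    }, character(1))
    writeLines(paste0("{", paste(sprintf('"%s": %s', names(flat), vals),
                                 collapse = ", "), "}"), path)
  }
  invisible(path)
}
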