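# Synthetic solubility datasets with the study's statistical structure:
# mole fractions generated from a chosen density model on the experimental
# (T, P, rho) grid with multiplicative lognormal replicate noise, so that
# fitting and post-processing stages can be exercised against a known truth.

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the study conditions: the 4 x 7 (T, P) grid with the
#' tabulated CO2 densities, triplicate measurements, and a relative standard
#' deviation of 4 % (the reported replicate precision bound).
#'
#' @param model_id generating model, one of [model_ids()]
#' @param true_params generating parameter vector
#' @param grid data frame with columns `T_K`, `P_MPa`, `rho_kg_m3`
#'   (default: the packaged binary grid)
#' @param cosolvent_levels numeric vector of y3 levels; use `0` for a
#'   binary dataset (cosolvent models require positive levels)
#' @param noise_rsd relative standard deviation of the multiplicative noise,
#'   in `[0, 0.2]`
#' @param seed integer RNG seed
#' @param n_replicates replicate draws averaged per record
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(model_id, true_params,
                             grid = NULL, cosolvent_levels = 0,
                             noise_rsd = 0.04, seed = 1L, n_replicates = 3L) {
  spec <- model_spec(model_id)
  if (length(true_params) != spec$n_params)
    stop(sprintf("'%s' takes %d parameters, got %d", model_id, spec$n_params,
                 length(true_params)))
  if (spec$requires_cosolvent && (!length(cosolvent_levels) ||
                                  any(cosolvent_levels <= 0)))
    stop("cosolvent models need positive cosolvent_levels")
  if (noise_rsd < 0 || noise_rsd > 0.2)
    stop("noise_rsd must lie in [0, 0.2]")
  if (is.null(grid)) {
    b <- builtin_dataset("binary")
    grid <- data.frame(T_K = b$T_K, P_MPa = b$P_MPa, rho_kg_m3 = b$rho_kg_m3)
  }
  if (!nrow(grid)) stop("grid must be non-empty")
  structure(list(model_id = model_id, true_params = as.numeric(true_params),
                 grid = grid, cosolvent_levels = cosolvent_levels,
                 noise_rsd = noise_rsd, seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates)),
            class = "synthetic_config")
}

#' Generate a synthetic solubility dataset
#'
#' Evaluates the generating model on the grid at each cosolvent level and
#' perturbs each record with multiplicative lognormal noise,
#' y = mean of n_replicates draws of y_model * exp(eps),
#' eps ~ N(0, noise_rsd); the replicate standard deviation column is
#' populated from the draws. Multiplicative noise keeps every generated
#' mole fraction strictly positive across the two orders of magnitude the
#' data span. The generating truth travels with the result as the
#' `"truth"` attribute.
#'
#' @param config a [synthetic_config()]
#' @return a `solubility_table` with attribute `truth` (list: `model_id`,
#'   `params`, `noise_rsd`, `seed`)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  d <- do.call(rbind, lapply(config$cosolvent_levels, function(y3) {
    g <- config$grid; g$y3 <- y3; g
  }))
  resp <- evaluate_model(config$model_id, config$true_params, d)
  y_true <- response_to_mole_fraction(config$model_id, resp, d)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  reps <- matrix(y_true, nrow(d), config$n_replicates) *
    exp(matrix(stats::rnorm(nrow(d) * config$n_replicates, 0,
                            config$noise_rsd),
               nrow(d), config$n_replicates))
  y <- rowMeans(reps)
  sd <- if (config$n_replicates > 1) apply(reps, 1, stats::sd) else 0
  out <- solubility_table(d$T_K, d$P_MPa, d$rho_kg_m3, y, d$y3, sd,
                          system = paste0("synthetic:", config$model_id))
  attr(out, "truth") <- list(model_id = config$model_id,
                             params = config$true_params,
                             noise_rsd = config$noise_rsd,
                             seed = config$seed)
  out
}

#' Parameter-recovery experiment
#'
#' Repeatedly generates a dataset from known parameters and refits the
#' generating model, reporting per-parameter bias and RMSE and the
#' distribution of fitted AARD values.
#'
#' @param model_id generating/fitted model
#' @param true_params generating parameter vector
#' @param noise_rsd relative noise level
#' @param n_trials number of generate-fit cycles
#' @param seed base seed; trial t uses `seed + t`
#' @param config an [optimizer_config()] for the refits
#' @param ... further arguments to [synthetic_config()]
#' @return list with `params` (data frame: truth, mean estimate, bias, rmse
#'   per parameter), `aard_percent` (vector over trials) and `estimates`
#'   (trials x params matrix)
#' @export
recovery_experiment <- function(model_id, true_params, noise_rsd = 0.04,
                                n_trials = 10L, seed = 1L,
                                config = optimizer_config(n_restarts = 2L,
                                                          iters_per_temp = 50L),
                                ...) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  est <- matrix(NA_real_, n_trials, length(true_params))
  aards <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    sc <- synthetic_config(model_id, true_params, noise_rsd = noise_rsd,
                           seed = seed + t, ...)
    dat <- generate_dataset(sc)
    cfg <- config
    cfg$seed <- seed + t
    fit <- fit_model(model_id, dat, cfg)
    est[t, ] <- fit$params
    aards[t] <- fit$metrics$aard_percent
  }
  colnames(est) <- names(ols_start(model_id, generate_dataset(
    synthetic_config(model_id, true_params, noise_rsd = 0, seed = seed, ...))))
  list(params = data.frame(
    parameter = colnames(est), truth = true_params,
    estimate = colMeans(est), bias = colMeans(est) - true_params,
    rmse = sqrt(colMeans(sweep(est, 2, true_params)^2))),
    aard_percent = aards, estimates = est)
}
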