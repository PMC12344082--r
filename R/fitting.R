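# Model fitting: AARD/R^2/AICc metrics and a seeded bounded simulated-
# annealing optimizer with a derivative-free simplex polish. Every model in
# the registry is linear in its parameters on the transformed scale, so an
# ordinary least-squares solve in the linearised coordinates seeds the
# annealer (and doubles as an independent oracle in the tests).

#' Average absolute relative deviation, in percent
#'
#' @param observed,predicted equal-length numeric vectors; `observed` must be
#'   strictly nonzero
#' @return mean of |predicted - observed| / |observed| x 100
#' @export
#' @examples
#' aard(c(1, 2), c(1.1, 1.8))  # 10
aard <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted lengths differ")
  if (length(observed) < 1) stop("empty vectors")
  if (any(observed == 0)) stop("AARD undefined for zero observed values")
  mean(abs(predicted - observed) / abs(observed)) * 100
}

#' Coefficient of determination
#'
#' @param observed,predicted equal-length numeric vectors, length >= 2;
#'   `observed` must not be constant
#' @return 1 - SSE / SStot
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted lengths differ")
  if (length(observed) < 2) stop("need at least two points")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("R^2 undefined for constant observations")
  1 - sum((observed - predicted)^2) / sst
}

#' Small-sample corrected Akaike information criterion
#'
#' Gaussian-likelihood form n log(SSE/n) + 2k + 2k(k+1)/(n-k-1).
#'
#' @param sse residual sum of squares (> 0)
#' @param n_points number of observations
#' @param n_params number of adjustable parameters k; requires
#'   `n_points > n_params + 1`
#' @return AICc value
#' @export
aicc <- function(sse, n_points, n_params) {
  if (n_points <= n_params + 1)
    stop("AICc requires n_points > n_params + 1")
  if (sse <= 0) stop("sse must be positive")
  n_points * log(sse / n_points) + 2 * n_params +
    2 * n_params * (n_params + 1) / (n_points - n_params - 1)
}

#' Optimizer settings for model fitting
#'
#' Controls the seeded simulated-annealing search: geometric cooling from
#' `t_initial` to `t_min` by `cooling` with `iters_per_temp` proposals per
#' temperature, repeated over `n_restarts` independent restarts, followed by
#' a Nelder-Mead polish when `polish = TRUE`. Bounds default to a window
#' around the least-squares start and are widened once (x10) if the best
#' parameters land on a boundary.
#'
#' @param seed integer RNG seed; the entire fit is deterministic given it
#' @param n_restarts independent annealing restarts (>= 1)
#' @param t_initial,t_min,cooling geometric cooling schedule (relative to
#'   the objective at the start point)
#' @param iters_per_temp proposals per temperature level
#' @param polish run a final derivative-free simplex refinement
#' @param bounds optional 2 x k matrix (rows: lower, upper) overriding the
#'   automatic bounds
#' @return an `optimizer_config` list
#' @export
optimizer_config <- function(seed = 1L, n_restarts = 8L, t_initial = 1,
                             t_min = 1e-3, cooling = 0.95,
                             iters_per_temp = 200L, polish = TRUE,
                             bounds = NULL) {
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  if (!is.null(bounds)) {
    bounds <- as.matrix(bounds)
    if (nrow(bounds) != 2 || any(!is.finite(bounds)) ||
        any(bounds[1, ] >= bounds[2, ]))
      stop("bounds must be a finite 2 x k matrix with lower < upper")
  }
  structure(list(seed = as.integer(seed), n_restarts = as.integer(n_restarts),
                 t_initial = t_initial, t_min = t_min, cooling = cooling,
                 iters_per_temp = as.integer(iters_per_temp),
                 polish = isTRUE(polish), bounds = bounds),
            class = "optimizer_config")
}

# Bounded simulated annealing with geometric cooling; Gaussian proposals
# whose scale shrinks with temperature, reflected into the box. Restart 1
# starts from `start`, the rest from uniform draws in the box. Ties across
# restarts resolve to the lowest restart index (which.min).
sa_minimize <- function(fn, lower, upper, config, start = NULL) {
  k <- length(lower)
  f_wrap <- function(p) {
    v <- suppressWarnings(tryCatch(fn(p), error = function(e) Inf))
    if (!is.finite(v)) Inf else v
  }
  range <- upper - lower
  results <- vector("list", config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    par <- if (r == 1 && !is.null(start))
      pmin(pmax(start, lower), upper)
    else lower + stats::runif(k) * range
    f <- f_wrap(par)
    best_par <- par; best_f <- f
    t_scale <- max(abs(f), 1e-8)
    if (!is.finite(t_scale)) t_scale <- 1
    temp <- config$t_initial
    n_evals <- 0L
    while (temp > config$t_min) {
      step_sd <- 0.1 * range * max(temp, 0.01)
      for (it in seq_len(config$iters_per_temp)) {
        cand <- par + stats::rnorm(k, 0, step_sd)
        # reflect into the box
        cand <- pmin(pmax(cand, 2 * lower - cand), upper)
        cand <- pmin(pmax(cand, lower), upper)
        f_cand <- f_wrap(cand)
        n_evals <- n_evals + 1L
        accept <- if (f_cand < f) TRUE
        else if (is.finite(f_cand) && is.finite(f))
          stats::runif(1) < exp(-(f_cand - f) / (temp * t_scale))
        else FALSE
        if (accept) {
          par <- cand; f <- f_cand
          if (f < best_f) { best_f <- f; best_par <- par }
        }
      }
      temp <- temp * config$cooling
    }
    results[[r]] <- list(par = best_par, value = best_f, evals = n_evals)
  }
  vals <- vapply(results, `[[`, 0, "value")
  if (all(!is.finite(vals)))
    stop("all annealing restarts failed to reach a finite objective")
  best <- which.min(vals)
  out <- results[[best]]
  out$restart <- best
  out$restart_values <- vals
  out
}

# Shared driver: seeded SA (+ optional simplex polish) over fn within bounds.
# Restores the caller's RNG state.
run_optimizer <- function(fn, start, config, widen_on_boundary = TRUE) {
  k <- length(start)
  if (!is.null(config$bounds)) {
    lower <- config$bounds[1, ]; upper <- config$bounds[2, ]
    if (ncol(config$bounds) != k) stop("bounds have wrong dimension")
  } else {
    half <- pmax(5 * abs(start), 1)
    lower <- start - half; upper <- start + half
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  res <- sa_minimize(fn, lower, upper, config, start = start)
  widened <- FALSE
  on_edge <- any(abs(res$par - lower) < 1e-8 * pmax(abs(lower), 1)) ||
    any(abs(res$par - upper) < 1e-8 * pmax(abs(upper), 1))
  if (widen_on_boundary && on_edge && is.null(config$bounds)) {
    centre <- (lower + upper) / 2; half <- (upper - lower) / 2 * 10
    res2 <- sa_minimize(fn, centre - half, centre + half, config,
                        start = res$par)
    if (res2$value < res$value) { res <- res2; widened <- TRUE }
  }
  if (config$polish) {
    pol <- suppressWarnings(stats::optim(
      res$par, function(p) {
        v <- tryCatch(fn(p), error = function(e) Inf)
        if (is.finite(v)) v else 1e10
      },
      method = "Nelder-Mead",
      control = list(maxit = 2000, reltol = 1e-12)))
    if (is.finite(pol$value) && pol$value <= res$value) {
      res$par <- pol$par; res$value <- pol$value
    }
  }
  res$widened <- widened
  res
}

# Least-squares parameters in the model's linearised coordinates.
ols_start <- function(model_id, collection) {
  m <- .model_registry[[match_model(model_id)]]
  d <- as_conditions(collection)
  check_cosolvent(m, d)
  resp <- observed_response(model_id, d)
  X <- m$design(d)
  y <- m$lhs(d, resp)
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  # rank-deficient designs (e.g. ln(y3*rho*T) alongside its own summands)
  # leave unidentified directions NA; pin them at zero
  coefs[is.na(coefs)] <- 0
  stats::setNames(coefs, colnames(X))
}

compute_metrics <- function(obs, pred, n_params) {
  sse <- sum((obs - pred)^2)
  structure(list(aard_percent = aard(obs, pred),
                 r_squared = r_squared(obs, pred),
                 # a numerically perfect fit has no defined AICc scale
                 aicc = if (sse > 0) aicc(sse, length(obs), n_params) else -Inf,
                 sse = sse,
                 n_points = length(obs), n_params = n_params),
            class = "fit_metrics")
}

#' Fit a density model to a solubility table
#'
#' Minimises the chosen objective over the model's adjustable parameters by
#' seeded simulated annealing started from (and bounded around) the
#' least-squares solution in the model's linearised coordinates, then
#' polishes with a derivative-free simplex. The default objective is the
#' AARD itself; `sse_log` (sum of squared log-residuals, the least-squares
#' objective of the linearised fit) and `sse` are available for sensitivity
#' checks.
#'
#' @param model_id one of [model_ids()]
#' @param collection a `solubility_table`; cosolvent models need `y3 > 0`
#'   and at least `n_params + 2` records
#' @param config an [optimizer_config()]
#' @param objective one of `"aard"`, `"sse_log"`, `"sse"`
#' @return a `fitted_model`: `spec`, `params`, `metrics` (AARD%, R^2, AICc,
#'   SSE on the model's response scale), `metrics_y` (same metrics in
#'   mole-fraction space), and `trace` (restart objectives, evaluations,
#'   seed)
#' @export
#' @examples
#' \donttest{
#' fit <- fit_model("kumar_johnston", builtin_dataset("binary"),
#'                  optimizer_config(seed = 1, n_restarts = 2))
#' fit$metrics$aard_percent
#' }
fit_model <- function(model_id, collection, config = optimizer_config(),
                      objective = c("aard", "sse_log", "sse")) {
  objective <- match.arg(objective)
  spec <- model_spec(model_id)
  d <- as_conditions(collection)
  if (nrow(d) < spec$n_params + 2)
    stop("need at least n_params + 2 records to fit '", model_id, "'")
  m <- .model_registry[[model_id]]
  check_cosolvent(m, d)
  obs <- observed_response(model_id, d)
  X <- m$design(d)
  obj_fn <- switch(objective,
    aard = function(p) aard(obs, m$invert(drop(X %*% p), d)),
    sse_log = function(p) {
      lhs_obs <- m$lhs(d, obs)
      sum((lhs_obs - drop(X %*% p))^2)
    },
    sse = function(p) sum((obs - m$invert(drop(X %*% p), d))^2))
  start <- ols_start(model_id, collection)
  res <- run_optimizer(obj_fn, start, config)
  pred <- m$invert(drop(X %*% res$par), d)
  metrics <- compute_metrics(obs, pred, spec$n_params)
  obs_y <- d$y2
  pred_y <- response_to_mole_fraction(model_id, pred, d)
  structure(list(
    spec = spec,
    params = stats::setNames(res$par, colnames(X)),
    metrics = metrics,
    metrics_y = compute_metrics(obs_y, pred_y, spec$n_params),
    objective = objective,
    ols_start = start,
    trace = list(seed = config$seed, restart = res$restart,
                 restart_values = res$restart_values,
                 best_objective = res$value, evals = res$evals,
                 bounds_widened = isTRUE(res$widened))),
    class = "fitted_model")
}

#' Fit several models and rank them
#'
#' @param collection a `solubility_table`
#' @param models character vector of model ids (default: all models
#'   applicable to the collection)
#' @param config an [optimizer_config()]
#' @param objective passed to [fit_model()]
#' @return list with `fits` (named list of `fitted_model` or error message
#'   per id) and `summary` (data frame ranked by AICc: model, AARD%, R^2,
#'   AICc, n_params)
#' @export
fit_all <- function(collection, models = NULL, config = optimizer_config(),
                    objective = "aard") {
  d <- as_conditions(collection)
  if (is.null(models))
    models <- model_ids(ternary_only = FALSE)[
      if (all(d$y3 > 0)) TRUE else !vapply(.model_registry, `[[`, TRUE,
                                           "requires_cosolvent")]
  fits <- stats::setNames(vector("list", length(models)), models)
  for (id in models)
    fits[[id]] <- tryCatch(fit_model(id, collection, config, objective),
                           error = function(e) conditionMessage(e))
  ok <- vapply(fits, inherits, TRUE, "fitted_model")
  summary <- data.frame(
    model = models,
    aard_percent = vapply(fits, function(f)
      if (inherits(f, "fitted_model")) f$metrics$aard_percent else NA_real_, 0),
    r_squared = vapply(fits, function(f)
      if (inherits(f, "fitted_model")) f$metrics$r_squared else NA_real_, 0),
    aicc = vapply(fits, function(f)
      if (inherits(f, "fitted_model")) f$metrics$aicc else NA_real_, 0),
    n_params = vapply(fits, function(f)
      if (inherits(f, "fitted_model")) as.numeric(f$spec$n_params)
      else NA_real_, 0),
    error = vapply(fits, function(f)
      if (inherits(f, "fitted_model")) "" else as.character(f), ""),
    row.names = NULL)
  summary <- summary[order(!ok, summary$aicc), , drop = FALSE]
  list(fits = fits, summary = summary)
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model> %s (objective %s)\n", x$spec$model_id,
              x$objective))
  cat("  params:", paste(sprintf("%s=%.6g", names(x$params), x$params),
                         collapse = ", "), "\n")
  cat(sprintf("  AARD %.3f%%  R^2 %.4f  AICc %.1f  (n=%d, k=%d)\n",
              x$metrics$aard_percent, x$metrics$r_squared, x$metrics$aicc,
              x$metrics$n_points, x$metrics$n_params))
  invisible(x)
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("<fit_metrics> AARD %.3f%%  R^2 %.4f  AICc %.1f  SSE %.3g (n=%d, k=%d)\n",
              x$aard_percent, x$r_squared, x$aicc, x$sse, x$n_points,
              x$n_params))
  invisible(x)
}
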