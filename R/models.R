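# Semi-empirical density-model registry.
#
# Every model here is linear in its adjustable parameters after a log (or
# T*log) transform of the response, so each entry defines:
#   lhs(cond, response)  - the transformed response ("linear predictor" scale)
#   design(cond)         - the matrix X with lhs = X %*% params on-model
#   invert(eta, cond)    - back-transform of the linear predictor to the
#                          response (mole fraction, or g/L for Chrastil)
#
# Unit conventions (fixed; parameter values depend on them):
#   T in K, rho1 in kg/m^3; P in bar for the P_ref-bearing forms (Bartle,
#   MST binary/ternary) with P_ref = 1 bar; P in MPa everywhere else.
#   Bartle reference density rho_ref = 700 kg/m^3.

.P_REF_BAR <- 1
.RHO_REF <- 700

.bar <- function(P_MPa) P_MPa * 10

.model_registry <- list(
  chrastil = list(
    n_params = 3, requires_cosolvent = FALSE, response = "mass_solubility",
    lhs = function(d, resp) log(resp),
    design = function(d) cbind(log_rho = log(d$rho_kg_m3), inv_T = 1 / d$T_K,
                               const = 1),
    invert = function(eta, d) exp(eta)),
  kumar_johnston = list(
    n_params = 3, requires_cosolvent = FALSE, response = "mole_fraction",
    lhs = function(d, resp) log(resp),
    design = function(d) cbind(const = 1, rho = d$rho_kg_m3, inv_T = 1 / d$T_K),
    invert = function(eta, d) exp(eta)),
  bartle = list(
    n_params = 3, requires_cosolvent = FALSE, response = "mole_fraction",
    lhs = function(d, resp) log(resp * .bar(d$P_MPa) / .P_REF_BAR),
    design = function(d) cbind(const = 1, inv_T = 1 / d$T_K,
                               drho = d$rho_kg_m3 - .RHO_REF),
    invert = function(eta, d) exp(eta) * .P_REF_BAR / .bar(d$P_MPa)),
  mst_binary = list(
    n_params = 3, requires_cosolvent = FALSE, response = "mole_fraction",
    lhs = function(d, resp) d$T_K * log(resp * .bar(d$P_MPa) / .P_REF_BAR),
    design = function(d) cbind(const = 1, rho = d$rho_kg_m3, T = d$T_K),
    invert = function(eta, d) exp(eta / d$T_K) * .P_REF_BAR / .bar(d$P_MPa)),
  mst_ternary = list(
    n_params = 4, requires_cosolvent = TRUE, response = "mole_fraction",
    lhs = function(d, resp) d$T_K * log(resp * .bar(d$P_MPa) / .P_REF_BAR),
    design = function(d) cbind(const = 1, rho = d$rho_kg_m3, T = d$T_K,
                               y3 = d$y3),
    invert = function(eta, d) exp(eta / d$T_K) * .P_REF_BAR / .bar(d$P_MPa)),
  sodeifian_sajadian = list(
    n_params = 4, requires_cosolvent = TRUE, response = "mole_fraction",
    lhs = function(d, resp) log(resp),
    design = function(d) cbind(log_rho = log(d$rho_kg_m3),
                               rho_logrho_T = d$rho_kg_m3 * log(d$rho_kg_m3) / d$T_K,
                               rho = d$rho_kg_m3,
                               log_y3P = log(d$y3 * d$P_MPa)),
    invert = function(eta, d) exp(eta)),
  gonzalez = list(
    n_params = 4, requires_cosolvent = TRUE, response = "mole_fraction",
    lhs = function(d, resp) log(resp),
    design = function(d) cbind(log_rho = log(d$rho_kg_m3), log_y3 = log(d$y3),
                               inv_T = 1 / d$T_K, const = 1),
    invert = function(eta, d) exp(eta)),
  soltani_mazloumi = list(
    n_params = 5, requires_cosolvent = TRUE, response = "mole_fraction",
    lhs = function(d, resp) log(resp),
    # note the sign: the published form subtracts the a3 ln(P) term
    design = function(d) cbind(const = 1, inv_T = 1 / d$T_K,
                               rho_T = d$rho_kg_m3 / d$T_K,
                               neg_logP = -log(d$P_MPa),
                               log_y3rhoT = log(d$y3 * d$rho_kg_m3 * d$T_K)),
    invert = function(eta, d) exp(eta)),
  jouyban = list(
    n_params = 7, requires_cosolvent = TRUE, response = "mole_fraction",
    lhs = function(d, resp) log(resp),
    design = function(d) cbind(const = 1, y3 = d$y3, rho = d$rho_kg_m3,
                               P2 = d$P_MPa^2, PT = d$P_MPa * d$T_K,
                               T_P = d$T_K / d$P_MPa,
                               log_rho = log(d$rho_kg_m3)),
    invert = function(eta, d) exp(eta)),
  garlapati_madras = list(
    n_params = 7, requires_cosolvent = TRUE, response = "mole_fraction",
    lhs = function(d, resp) log(resp),
    design = function(d) cbind(const = 1, log_rho = log(d$rho_kg_m3),
                               rho = d$rho_kg_m3, inv_T = 1 / d$T_K,
                               log_T = log(d$T_K), log_y3 = log(d$y3),
                               log_y3rhoT = log(d$y3 * d$rho_kg_m3 * d$T_K)),
    invert = function(eta, d) exp(eta))
)

#' List the available density-model identifiers
#'
#' @param ternary_only if TRUE, only models requiring a cosolvent term
#' @return character vector of model ids
#' @export
model_ids <- function(ternary_only = FALSE) {
  ids <- names(.model_registry)
  if (ternary_only)
    ids <- ids[vapply(.model_registry, `[[`, TRUE, "requires_cosolvent")]
  ids
}

#' Describe a density model
#'
#' @param model_id one of [model_ids()]
#' @return a `model_spec` list: `model_id`, `n_params`, `requires_cosolvent`,
#'   `response` ("mole_fraction" or "mass_solubility" in g/L), and the fixed
#'   `constants` (P_ref in bar, rho_ref in kg/m^3)
#' @export
#' @examples
#' model_spec("kumar_johnston")$n_params
model_spec <- function(model_id) {
  m <- .model_registry[[match_model(model_id)]]
  structure(list(model_id = match_model(model_id), n_params = m$n_params,
                 requires_cosolvent = m$requires_cosolvent,
                 response = m$response,
                 constants = list(P_ref_bar = .P_REF_BAR,
                                  rho_ref_kg_m3 = .RHO_REF)),
            class = "model_spec")
}

match_model <- function(model_id) {
  if (!is.character(model_id) || length(model_id) != 1 ||
      !model_id %in% names(.model_registry))
    stop("unknown model '", model_id, "'; available: ",
         paste(names(.model_registry), collapse = ", "))
  model_id
}

as_conditions <- function(conditions) {
  d <- as.data.frame(conditions)
  need <- c("T_K", "P_MPa", "rho_kg_m3")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("conditions lack column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(d$y3)) d$y3 <- 0
  d
}

check_cosolvent <- function(m, d) {
  if (m$requires_cosolvent && any(d$y3 <= 0))
    stop("this model contains ln(y3) terms and is undefined at y3 = 0")
}

#' Evaluate a density model at given conditions
#'
#' Computes the model's predicted response — mole fraction for every model
#' except Chrastil, whose natural response is the mass solubility in g/L —
#' from a parameter vector and a set of (T, P, rho, y3) conditions.
#'
#' @param model_id one of [model_ids()]
#' @param params numeric parameter vector of length `n_params`
#' @param conditions data frame with columns `T_K`, `P_MPa`, `rho_kg_m3` and,
#'   for cosolvent models, `y3 > 0`
#' @return numeric vector of predicted responses, one per condition row
#' @export
#' @examples
#' evaluate_model("gonzalez", c(1, 0.5, -1000, -10),
#'                data.frame(T_K = 308, P_MPa = 12, rho_kg_m3 = 700, y3 = 0.03))
evaluate_model <- function(model_id, params, conditions) {
  m <- .model_registry[[match_model(model_id)]]
  if (length(params) != m$n_params)
    stop(sprintf("'%s' takes %d parameters, got %d", model_id, m$n_params,
                 length(params)))
  d <- as_conditions(conditions)
  check_cosolvent(m, d)
  eta <- drop(m$design(d) %*% as.numeric(params))
  out <- m$invert(eta, d)
  if (any(!is.finite(out)))
    stop("model evaluation produced non-finite predictions")
  out
}

#' Self-consistency coordinates of a fitted model
#'
#' Returns the coordinates of the model's linear self-consistency plot: the
#' fitted linear predictor (x) against the observed transformed response (y).
#' Data generated exactly by the model fall on the identity line, so the R^2
#' of a straight-line regression of y on x measures internal consistency.
#'
#' @param model_id one of [model_ids()]
#' @param params fitted parameter vector
#' @param collection a `solubility_table` (or data frame with the same columns)
#' @return list with numeric vectors `x` and `y` and the regression
#'   `r_squared`
#' @export
linearized_coordinates <- function(model_id, params, collection) {
  m <- .model_registry[[match_model(model_id)]]
  if (length(params) != m$n_params)
    stop(sprintf("'%s' takes %d parameters, got %d", model_id, m$n_params,
                 length(params)))
  d <- as_conditions(collection)
  if (nrow(d) < 2) stop("at least two records are needed for a regression")
  check_cosolvent(m, d)
  resp <- observed_response(model_id, d)
  x <- drop(m$design(d) %*% as.numeric(params))
  y <- m$lhs(d, resp)
  fit <- stats::lm.fit(cbind(1, x), y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(x = x, y = y, r_squared = r2)
}

# Observed response on the model's natural scale: mole fraction, or g/L
# mass solubility (Chrastil) computed from y2 and the CO2 density.
observed_response <- function(model_id, d) {
  m <- .model_registry[[match_model(model_id)]]
  if (m$response == "mass_solubility")
    mass_solubility(d$y2, d$rho_kg_m3)
  else d$y2
}

# Inverse response: map a predicted response back to mole fraction.
response_to_mole_fraction <- function(model_id, resp, d) {
  m <- .model_registry[[match_model(model_id)]]
  if (m$response == "mass_solubility")
    mass_to_mole_fraction(resp, d$rho_kg_m3)
  else resp
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: %d parameters, %s response%s\n", x$model_id,
              x$n_params, x$response,
              if (x$requires_cosolvent) ", requires cosolvent" else ""))
  invisible(x)
}
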