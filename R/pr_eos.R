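# Peng-Robinson equation of state with two-parameter van der Waals (vdW2)
# mixing rules: pure and mixture parameters, compressibility roots, analytic
# fugacity coefficients (with the covolume interaction term l12), a
# boiling-point sublimation-pressure correlation, the solid-fluid solubility
# equation and regression of (k12, l12) against binary data.
#
# Units inside this module are SI (Pa, m^3, mol, K); the dataset's MPa and
# kg/m^3 are converted at the boundary.

.SQRT2 <- sqrt(2)

#' Define an equation-of-state component
#'
#' @param critical_temperature K
#' @param critical_pressure Pa
#' @param acentric_factor dimensionless
#' @param molar_mass g/mol
#' @return an `eos_component` list
#' @export
eos_component <- function(critical_temperature, critical_pressure,
                          acentric_factor, molar_mass) {
  vals <- c(critical_temperature, critical_pressure, acentric_factor,
            molar_mass)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("component constants must be positive and finite")
  structure(list(critical_temperature = critical_temperature,
                 critical_pressure = critical_pressure,
                 acentric_factor = acentric_factor, molar_mass = molar_mass),
            class = "eos_component")
}

#' CO2 as an EoS component (Tc = 304.13 K, Pc = 7.377 MPa, omega = 0.225)
#' @return an `eos_component`
#' @export
co2_component <- function() eos_component(304.13, 7.377e6, 0.225, .M_CO2)

#' Methyldopa as an EoS component, from [methyldopa_props()]
#' @param props a `solute_props`
#' @return an `eos_component`
#' @export
solute_component <- function(props = methyldopa_props()) {
  eos_component(props$critical_temperature, props$critical_pressure * 1e6,
                props$acentric_factor, props$molar_mass)
}

#' Pure-component PR parameters
#'
#' a_i = 0.45724 R^2 Tc^2 / Pc * alpha(T), b_i = 0.07780 R Tc / Pc with
#' alpha = (1 + kappa (1 - sqrt(T/Tc)))^2 and
#' kappa = 0.37464 + 1.54226 w - 0.26992 w^2.
#'
#' @param component an `eos_component`
#' @param T_K temperature, K
#' @return list with `a` (Pa m^6/mol^2) and `b` (m^3/mol)
#' @export
pr_pure_params <- function(component, T_K) {
  if (T_K <= 0) stop("temperature must be positive")
  Tc <- component$critical_temperature
  Pc <- component$critical_pressure
  w <- component$acentric_factor
  kappa <- 0.37464 + 1.54226 * w - 0.26992 * w^2
  alpha <- (1 + kappa * (1 - sqrt(T_K / Tc)))^2
  list(a = 0.45724 * .R_GAS^2 * Tc^2 / Pc * alpha,
       b = 0.07780 * .R_GAS * Tc / Pc)
}

# Pairwise a_ij, b_ij matrices under vdW2 combining rules.
pair_matrices <- function(components, T_K, k12, l12) {
  n <- length(components)
  pp <- lapply(components, pr_pure_params, T_K = T_K)
  a <- vapply(pp, `[[`, 0, "a"); b <- vapply(pp, `[[`, 0, "b")
  K <- matrix(0, n, n); L <- matrix(0, n, n)
  if (n == 2) { K[1, 2] <- K[2, 1] <- k12; L[1, 2] <- L[2, 1] <- l12 }
  aij <- sqrt(outer(a, a)) * (1 - K)
  bij <- outer(b, b, function(x, y) (x + y) / 2) * (1 - L)
  list(aij = aij, bij = bij, a = a, b = b)
}

#' Mixture PR parameters under vdW2 mixing
#'
#' Quadratic mixing a_m = sum_ij x_i x_j a_ij, b_m = sum_ij x_i x_j b_ij
#' with a_ij = sqrt(a_i a_j)(1 - k_ij) and b_ij = (b_i + b_j)/2 (1 - l_ij).
#'
#' @param components list of `eos_component` (two for the binary system)
#' @param composition mole-fraction vector summing to 1
#' @param T_K temperature, K
#' @param k12,l12 binary interaction corrections (energy, covolume)
#' @return list with `a_m`, `b_m` and the pairwise matrices `aij`, `bij`
#' @export
pr_mixture_params <- function(components, composition, T_K, k12 = 0, l12 = 0) {
  x <- as.numeric(composition)
  if (length(x) != length(components))
    stop("composition length must match the number of components")
  if (abs(sum(x) - 1) > 1e-10) stop("composition must sum to 1")
  pm <- pair_matrices(components, T_K, k12, l12)
  list(a_m = drop(x %*% pm$aij %*% x), b_m = drop(x %*% pm$bij %*% x),
       aij = pm$aij, bij = pm$bij)
}

#' Compressibility roots of the PR equation
#'
#' Solves the PR cubic in Z at given T, P and mixture parameters, returning
#' the physically admissible real roots (v = ZRT/P > b_m). When several
#' roots exist the stable fluid root is the one minimising the residual
#' Gibbs energy.
#'
#' @param T_K temperature, K
#' @param P_Pa pressure, Pa
#' @param a_m,b_m mixture parameters (Pa m^6/mol^2, m^3/mol)
#' @return list with `roots` (all admissible real Z) and `Z` (the selected
#'   root)
#' @export
pr_solve_z <- function(T_K, P_Pa, a_m, b_m) {
  if (P_Pa <= 0) stop("pressure must be positive")
  A <- a_m * P_Pa / (.R_GAS * T_K)^2
  B <- b_m * P_Pa / (.R_GAS * T_K)
  # Z^3 - (1-B) Z^2 + (A - 3B^2 - 2B) Z - (AB - B^2 - B^3) = 0
  cf <- c(-(A * B - B^2 - B^3), A - 3 * B^2 - 2 * B, -(1 - B), 1)
  z <- polyroot(cf)
  re <- Re(z[abs(Im(z)) < 1e-9 * pmax(abs(z), 1)])
  re <- sort(unique(re[re > B]))
  if (!length(re)) stop("no compressibility root with v > b_m (unphysical state)")
  Zsel <- if (length(re) == 1) re else re[which.min(vapply(re, gibbs_residual,
                                                           0, A = A, B = B))]
  list(roots = re, Z = Zsel, A = A, B = B)
}

# Dimensionless residual molar Gibbs energy at a root; used for root selection.
gibbs_residual <- function(Z, A, B) {
  Z - 1 - log(Z - B) -
    A / (2 * .SQRT2 * B) * log((Z + (1 + .SQRT2) * B) / (Z + (1 - .SQRT2) * B))
}

#' Fugacity coefficients in a PR/vdW2 mixture
#'
#' Analytic expression including the covolume-interaction (l12) contribution
#' through the partial molar covolume bbar_i = 2 sum_j x_j b_ij - b_m.
#'
#' @param components list of `eos_component`
#' @param composition mole-fraction vector
#' @param T_K temperature, K
#' @param P_Pa pressure, Pa
#' @param k12,l12 interaction parameters
#' @return numeric vector of fugacity coefficients phi_i
#' @export
pr_fugacity <- function(components, composition, T_K, P_Pa, k12 = 0, l12 = 0) {
  x <- as.numeric(composition)
  mp <- pr_mixture_params(components, x, T_K, k12, l12)
  sol <- pr_solve_z(T_K, P_Pa, mp$a_m, mp$b_m)
  Z <- sol$Z; A <- sol$A; B <- sol$B
  abar <- 2 * drop(mp$aij %*% x)            # partial d(n^2 a_m)/dn_i / n
  bbar <- 2 * drop(mp$bij %*% x) - mp$b_m   # partial d(n b_m)/dn_i
  lnphi <- bbar / mp$b_m * (Z - 1) - log(Z - B) -
    A / (2 * .SQRT2 * B) * (abar / mp$a_m - bbar / mp$b_m) *
    log((Z + (1 + .SQRT2) * B) / (Z + (1 - .SQRT2) * B))
  exp(lnphi)
}

# Residual Helmholtz energy over RT at fixed T, V (m^3) for mole numbers n;
# the numerical-differentiation oracle for the analytic fugacity expression.
helmholtz_residual <- function(components, n_moles, T_K, V_m3, k12, l12) {
  n <- sum(n_moles)
  x <- n_moles / n
  mp <- pr_mixture_params(components, x, T_K, k12, l12)
  nb <- n * mp$b_m
  -n * log((V_m3 - nb) / V_m3) -
    n * mp$a_m / (2 * .SQRT2 * mp$b_m * .R_GAS * T_K) *
    log((V_m3 + (1 + .SQRT2) * nb) / (V_m3 + (1 - .SQRT2) * nb))
}

#' Numerical fugacity coefficients (finite-difference oracle)
#'
#' Evaluates ln phi_i = d(A_res/RT)/dn_i |_(T,V) - ln Z by central
#' differences of the residual Helmholtz energy, independent of the analytic
#' expression in [pr_fugacity()].
#'
#' @inheritParams pr_fugacity
#' @param h mole perturbation for the central difference
#' @return numeric vector of fugacity coefficients
#' @export
pr_fugacity_numeric <- function(components, composition, T_K, P_Pa,
                                k12 = 0, l12 = 0, h = 1e-6) {
  x <- as.numeric(composition)
  mp <- pr_mixture_params(components, x, T_K, k12, l12)
  sol <- pr_solve_z(T_K, P_Pa, mp$a_m, mp$b_m)
  V <- sol$Z * .R_GAS * T_K / P_Pa  # molar volume for 1 mol total
  vapply(seq_along(x), function(i) {
    np <- x; np[i] <- np[i] + h
    nm <- x; nm[i] <- nm[i] - h
    dF <- (helmholtz_residual(components, np, T_K, V, k12, l12) -
             helmholtz_residual(components, nm, T_K, V, k12, l12)) / (2 * h)
    exp(dF - log(sol$Z))
  }, 0)
}

#' Sublimation pressure from the normal boiling point
#'
#' Boiling-point-only vapor-pressure correlation for solids (modified Grain
#' estimate): with Tpt = T/Tb and m = 0.4133 - 0.2575 Tpt,
#' ln(P/Patm) = (dSb/R) * (1 - (3 - 2 Tpt)^m / Tpt
#'                          - 2 m (3 - 2 Tpt)^(m-1) ln(Tpt)),
#' dSb = 86.9 J/(mol K). At T = Tb it returns exactly one atmosphere.
#'
#' @param T_K temperature, K; must be below `Tb_K`
#' @param Tb_K normal boiling temperature, K
#' @param dSb_J_molK boiling entropy, J/(mol K)
#' @return sublimation pressure in Pa
#' @export
#' @examples
#' sublimation_pressure(308, 844.5)
sublimation_pressure <- function(T_K, Tb_K, dSb_J_molK = 86.9) {
  if (any(T_K <= 0) || any(T_K > Tb_K))
    stop("temperature must lie in (0, Tb]")
  tpt <- T_K / Tb_K
  m <- 0.4133 - 0.2575 * tpt
  bracket <- 1 - (3 - 2 * tpt)^m / tpt - 2 * m * (3 - 2 * tpt)^(m - 1) * log(tpt)
  .P_ATM * exp(dSb_J_molK / .R_GAS * bracket)
}

solute_psub <- function(props, T_K) {
  if (!is.null(props$sublimation_pressure_override))
    props$sublimation_pressure_override(T_K)
  else sublimation_pressure(T_K, props$boiling_temperature)
}

#' Solid solubility from the PR equation of state
#'
#' Solves the solid-fluid equilibrium
#' y2 = Psub/P * (phi_sat / phi2(T,P,y)) * exp(v2s (P - Psub) / RT)
#' by fixed-point iteration on y2, with PR/vdW2 fugacity coefficients for
#' the solute in the fluid phase and phi_sat = 1 (the solid's saturation
#' pressure is far below 1 Pa).
#'
#' @param T_K temperature, K
#' @param P_MPa pressure, MPa
#' @param props a `solute_props`
#' @param k12,l12 binary interaction parameters
#' @param y_init starting mole fraction
#' @param tol relative convergence tolerance
#' @param max_iter iteration cap
#' @return list with `y2`, `iterations`, `phi2`, `psub_Pa`
#' @export
solubility_eos <- function(T_K, P_MPa, props = methyldopa_props(),
                           k12 = 0, l12 = 0, y_init = 1e-5, tol = 1e-10,
                           max_iter = 200L) {
  P <- P_MPa * 1e6
  psub <- solute_psub(props, T_K)
  if (P <= psub) stop("system pressure must exceed the sublimation pressure")
  comps <- list(co2_component(), solute_component(props))
  v2s <- props$solid_molar_volume * 1e-6  # m^3/mol
  poynting <- exp(v2s * (P - psub) / (.R_GAS * T_K))
  ideal <- psub / P * poynting
  y <- y_init
  phi2 <- NA_real_
  for (it in seq_len(max_iter)) {
    phi2 <- pr_fugacity(comps, c(1 - y, y), T_K, P, k12, l12)[2]
    y_new <- ideal / phi2
    if (y_new >= 1) stop("equilibrium mole fraction >= 1 (unphysical state)")
    if (abs(y_new - y) <= tol * max(y, 1e-300)) {
      return(list(y2 = y_new, iterations = it, phi2 = phi2, psub_Pa = psub))
    }
    y <- y_new
  }
  stop(sprintf(
    "solubility iteration did not converge in %d steps (last y2 = %.3e, step %.1e)",
    max_iter, y, abs(y_new - y) / max(y, 1e-300)))
}

#' Predicted EoS solubilities over a table of conditions
#'
#' @param collection a `solubility_table` (only T and P are used)
#' @param props a `solute_props`
#' @param k12,l12 interaction parameters
#' @return numeric vector of predicted y2
#' @export
solubility_eos_grid <- function(collection, props = methyldopa_props(),
                                k12 = 0, l12 = 0) {
  d <- as_conditions(collection)
  y <- 1e-5
  out <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    # warm-start each point from the previous solution
    res <- solubility_eos(d$T_K[i], d$P_MPa[i], props, k12, l12,
                          y_init = max(min(y, 0.5), 1e-12))
    out[i] <- y <- res$y2
  }
  out
}

#' Fit PR/vdW2 interaction parameters to binary solubility data
#'
#' Regresses (k12, l12) against a binary table by seeded simulated annealing
#' minimising the AARD between measured and EoS-predicted mole fractions,
#' either globally (one pair for all records) or per isotherm.
#'
#' @param collection binary `solubility_table`
#' @param props a `solute_props`
#' @param config an [optimizer_config()]; interaction parameters are bounded
#'   in (-1, 1) x (-1, 1) unless `config$bounds` overrides
#' @param scope `"global"` or `"per_isotherm"`
#' @return for `"global"`: list with `k12`, `l12`, `metrics`
#'   (`fit_metrics`), `predicted`, `trace`; for `"per_isotherm"`: list with
#'   `by_isotherm` (data frame of per-temperature k12, l12, AARD) and pooled
#'   `metrics`
#' @export
fit_interaction_params <- function(collection, props = methyldopa_props(),
                                   config = optimizer_config(n_restarts = 4L,
                                                             iters_per_temp = 40L,
                                                             t_min = 0.05),
                                   scope = c("global", "per_isotherm")) {
  scope <- match.arg(scope)
  d <- as_conditions(collection)
  fit_one <- function(sub) {
    obj <- function(p) {
      pred <- tryCatch(solubility_eos_grid(sub, props, p[1], p[2]),
                       error = function(e) NULL)
      if (is.null(pred)) return(Inf)
      aard(sub$y2, pred)
    }
    # The AARD surface is a narrow ridge: slightly too little repulsion and
    # the equilibrium diverges, slightly too much and predictions collapse
    # to ~zero (AARD plateaus at 100 %). Locate the ridge first with a
    # coarse grid on a log-space proxy, which stays informative on the
    # plateau, then anneal the AARD inside a box around it.
    proxy <- function(p) {
      pred <- tryCatch(solubility_eos_grid(sub, props, p[1], p[2]),
                       error = function(e) NULL)
      if (is.null(pred)) return(Inf)
      mean(abs(log(pred / sub$y2)))
    }
    grid <- expand.grid(k = seq(-0.5, 0.9, by = 0.1),
                        l = seq(-0.9, 0.9, by = 0.2))
    gv <- apply(grid, 1, proxy)
    if (all(!is.finite(gv)))
      stop("no feasible interaction parameters on the search grid")
    best <- as.numeric(grid[which.min(gv), ])
    cfg <- config
    if (is.null(cfg$bounds))
      cfg$bounds <- rbind(pmax(best - c(0.15, 0.3), -0.99),
                          pmin(best + c(0.15, 0.3), 0.99))
    res <- run_optimizer(obj, start = best, config = cfg,
                         widen_on_boundary = FALSE)
    res$par <- pmin(pmax(res$par, -0.99), 0.99)
    res
  }
  if (scope == "global") {
    res <- fit_one(d)
    pred <- solubility_eos_grid(d, props, res$par[1], res$par[2])
    list(k12 = res$par[1], l12 = res$par[2],
         metrics = compute_metrics(d$y2, pred, 2), predicted = pred,
         trace = list(seed = config$seed, restart = res$restart,
                      restart_values = res$restart_values,
                      best_objective = res$value))
  } else {
    temps <- sort(unique(d$T_K))
    rows <- lapply(temps, function(tt) {
      sub <- d[d$T_K == tt, ]
      res <- fit_one(sub)
      pred <- solubility_eos_grid(sub, props, res$par[1], res$par[2])
      list(row = data.frame(T_K = tt, k12 = res$par[1], l12 = res$par[2],
                            aard_percent = aard(sub$y2, pred)),
           pred = pred, obs = sub$y2)
    })
    obs <- unlist(lapply(rows, `[[`, "obs"))
    pred <- unlist(lapply(rows, `[[`, "pred"))
    list(by_isotherm = do.call(rbind, lapply(rows, `[[`, "row")),
         metrics = compute_metrics(obs, pred, 2 * length(temps)))
  }
}
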