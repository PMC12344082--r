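# Post-fit thermodynamics: enthalpy decomposition from the van 't Hoff-type
# 1/T coefficients, Eq.-4-style mass solubility, cosolvent enhancement
# factors and crossover-pressure detection.

#' Mass solubility from mole fraction
#'
#' Converts the solute mole fraction to mass solubility in g per litre of
#' solvent, S = rho * M_solute * y2 / (M_CO2 * (1 - y2)), with the density
#' in kg/m^3.
#'
#' @param y2 solute mole fraction, in (0, 1)
#' @param co2_density solvent density, kg/m^3
#' @param solute_molar_mass g/mol (default methyldopa)
#' @param co2_molar_mass g/mol
#' @return solubility in g/L
#' @export
#' @examples
#' mass_solubility(0.238e-4, 768.4)  # 0.088 g/L
mass_solubility <- function(y2, co2_density,
                            solute_molar_mass = methyldopa_props()$molar_mass,
                            co2_molar_mass = .M_CO2) {
  if (any(y2 >= 1) || any(y2 <= 0)) stop("mole fraction must lie in (0, 1)")
  co2_density * solute_molar_mass * y2 / (co2_molar_mass * (1 - y2))
}

# Inverse of mass_solubility (used when a g/L-response model is refit or
# simulated in mole-fraction space).
mass_to_mole_fraction <- function(S, co2_density,
                                  solute_molar_mass = methyldopa_props()$molar_mass,
                                  co2_molar_mass = .M_CO2) {
  r <- S * co2_molar_mass / (co2_density * solute_molar_mass)
  r / (1 + r)
}

#' Total dissolution enthalpy from a Chrastil fit
#'
#' The Chrastil 1/T coefficient a1 (in K) carries the total enthalpy of
#' dissolution: deltaH_total = -a1 * R.
#'
#' @param fit a `fitted_model` with `model_id == "chrastil"` (see
#'   [fit_model()]), or a bare numeric Chrastil parameter vector
#' @return enthalpy in kJ/mol
#' @export
total_enthalpy_from_chrastil <- function(fit) {
  -chrastil_like_a1(fit, "chrastil") * .R_GAS / 1000
}

#' Vaporization enthalpy from a Bartle fit
#'
#' The Bartle 1/T coefficient a1 (in K) carries the solute vaporization
#' enthalpy: deltaH_vap = -a1 * R.
#'
#' @param fit a `fitted_model` with `model_id == "bartle"`, or a bare numeric
#'   Bartle parameter vector
#' @return enthalpy in kJ/mol
#' @export
vaporization_enthalpy_from_bartle <- function(fit) {
  -chrastil_like_a1(fit, "bartle") * .R_GAS / 1000
}

chrastil_like_a1 <- function(fit, expect_id) {
  if (inherits(fit, "fitted_model")) {
    if (fit$spec$model_id != expect_id)
      stop("expected a fitted '", expect_id, "' model, got '",
           fit$spec$model_id, "'")
    params <- fit$params
  } else params <- as.numeric(fit)
  if (length(params) != 3) stop("expected 3 parameters for ", expect_id)
  # both forms put the 1/T coefficient second: chrastil (log_rho, inv_T,
  # const) and bartle (const, inv_T, drho)
  unname(params[2])
}

#' Solvation enthalpy
#'
#' The exact identity deltaH_sol = deltaH_total - deltaH_vap.
#'
#' @param total_kj_mol total dissolution enthalpy, kJ/mol
#' @param vaporization_kj_mol vaporization enthalpy, kJ/mol
#' @return list of class `enthalpy_report` with fields `total_kj_mol`,
#'   `vaporization_kj_mol`, `solvation_kj_mol`
#' @export
#' @examples
#' solvation_enthalpy(34.12, 57.19)$solvation_kj_mol  # -23.07
solvation_enthalpy <- function(total_kj_mol, vaporization_kj_mol) {
  stopifnot(is.finite(total_kj_mol), is.finite(vaporization_kj_mol))
  structure(list(total_kj_mol = total_kj_mol,
                 vaporization_kj_mol = vaporization_kj_mol,
                 solvation_kj_mol = total_kj_mol - vaporization_kj_mol),
            class = "enthalpy_report")
}

#' Enthalpy decomposition from a binary solubility table
#'
#' Fits Chrastil and Bartle to the binary data and decomposes the total
#' dissolution enthalpy into vaporization and solvation contributions.
#'
#' @param collection binary `solubility_table`
#' @param config an [optimizer_config()]
#' @return an `enthalpy_report`
#' @export
enthalpy_decomposition <- function(collection, config = optimizer_config()) {
  ch <- fit_model("chrastil", collection, config)
  ba <- fit_model("bartle", collection, config)
  solvation_enthalpy(total_enthalpy_from_chrastil(ch),
                     vaporization_enthalpy_from_bartle(ba))
}

#' @export
print.enthalpy_report <- function(x, ...) {
  cat(sprintf(paste0("<enthalpy_report> total %.2f kJ/mol, vaporization %.2f",
                     " kJ/mol, solvation %.2f kJ/mol\n"),
              x$total_kj_mol, x$vaporization_kj_mol, x$solvation_kj_mol))
  invisible(x)
}

#' Cosolvent enhancement factors
#'
#' Matches every ternary (T, P) record to its binary counterpart and returns
#' the enhancement factor e = y2'/y2 (the plain solubility ratio; the
#' equivalent percentage reading is e * 100).
#'
#' @param binary binary `solubility_table`
#' @param ternary ternary `solubility_table` (one or more cosolvent levels)
#' @return data frame with columns `T_K`, `P_MPa`, `y3`, `enhancement`
#' @export
#' @examples
#' e <- enhancement_factors(builtin_dataset("binary"), builtin_dataset("ethanol-3%"))
#' subset(e, T_K == 338 & P_MPa == 12)  # e = 15.70
enhancement_factors <- function(binary, ternary) {
  b <- as.data.frame(binary); t <- as.data.frame(ternary)
  key_b <- paste(b$T_K, b$P_MPa)
  key_t <- paste(t$T_K, t$P_MPa)
  unmatched <- setdiff(unique(key_t), key_b)
  if (length(unmatched))
    stop("ternary conditions without a binary match: ",
         paste(unmatched, collapse = "; "))
  idx <- match(key_t, key_b)
  out <- data.frame(T_K = t$T_K, P_MPa = t$P_MPa, y3 = t$y3,
                    enhancement = t$y2 / b$y2[idx])
  out[order(out$y3, out$T_K, out$P_MPa), , drop = FALSE]
}

#' Crossover pressure of solubility isotherms
#'
#' Estimates, for every pair of isotherms, the pressure at which they
#' intersect in (P, ln y2) space using piecewise-linear interpolants; below
#' this pressure solubility is retrograde (decreases on heating). The
#' aggregate estimate is the median over intersecting pairs.
#'
#' @param collection a `solubility_table` with at least two isotherms on a
#'   shared pressure grid
#' @return list with `pairs` (data frame: `T_low`, `T_high`, `crossover_MPa`,
#'   `bracket_lo`, `bracket_hi`; NA where a pair does not intersect) and
#'   `aggregate_MPa` (median crossover)
#' @export
crossover_pressure <- function(collection) {
  d <- as.data.frame(collection)
  temps <- sort(unique(d$T_K))
  if (length(temps) < 2) stop("need at least two isotherms")
  iso <- lapply(temps, function(tt) {
    s <- d[d$T_K == tt, ]; s[order(s$P_MPa), ]
  })
  names(iso) <- temps
  rows <- list()
  for (i in seq_len(length(temps) - 1)) for (j in (i + 1):length(temps)) {
    a <- iso[[i]]; b <- iso[[j]]
    P <- intersect(a$P_MPa, b$P_MPa)
    if (length(P) < 2) next
    P <- sort(P)
    fa <- log(a$y2[match(P, a$P_MPa)]); fb <- log(b$y2[match(P, b$P_MPa)])
    diff <- fa - fb
    cross <- NA_real_; lo <- NA_real_; hi <- NA_real_
    sgn <- sign(diff)
    k <- which(sgn[-length(sgn)] * sgn[-1] < 0)
    if (any(diff == 0)) {
      cross <- P[which(diff == 0)[1]]; lo <- hi <- cross
    } else if (length(k)) {
      k <- k[1]
      cross <- P[k] + (P[k + 1] - P[k]) * diff[k] / (diff[k] - diff[k + 1])
      lo <- P[k]; hi <- P[k + 1]
    }
    rows[[length(rows) + 1]] <- data.frame(
      T_low = temps[i], T_high = temps[j], crossover_MPa = cross,
      bracket_lo = lo, bracket_hi = hi)
  }
  pairs <- do.call(rbind, rows)
  list(pairs = pairs,
       aggregate_MPa = stats::median(pairs$crossover_MPa, na.rm = TRUE))
}
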