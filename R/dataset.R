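# Physical constants used across the package
.R_GAS <- 8.314462618   # J/(mol K)
.M_CO2 <- 44.01         # g/mol
.P_ATM <- 101325        # Pa

#' Physical property set for methyldopa
#'
#' Returns the solute property set used by the equation-of-state and
#' conversion routines: molar mass, normal boiling point, critical constants,
#' acentric factor (Ambrose-Walton estimate) and solid molar volume.
#'
#' @param sublimation_pressure_override optional function of temperature (K)
#'   returning the solid's sublimation pressure in Pa, replacing the built-in
#'   boiling-point correlation (see [sublimation_pressure()]).
#' @return an object of class `solute_props`: a list with fields
#'   `molar_mass` (g/mol), `boiling_temperature` (K), `critical_temperature`
#'   (K), `critical_pressure` (MPa), `acentric_factor`, `solid_molar_volume`
#'   (cm^3/mol) and `sublimation_pressure_override`.
#' @export
#' @examples
#' methyldopa_props()$molar_mass
methyldopa_props <- function(sublimation_pressure_override = NULL) {
  solute_props(
    molar_mass = 211.21,
    boiling_temperature = 844.5,
    critical_temperature = 1177.3,
    critical_pressure = 2.45,
    acentric_factor = 0.558,
    solid_molar_volume = 335.4,
    sublimation_pressure_override = sublimation_pressure_override)
}

#' Construct a validated solute property set
#'
#' @param molar_mass g/mol
#' @param boiling_temperature normal boiling point, K
#' @param critical_temperature K
#' @param critical_pressure MPa
#' @param acentric_factor dimensionless
#' @param solid_molar_volume cm^3/mol
#' @param sublimation_pressure_override optional `function(T_K) -> Pa`
#' @return a `solute_props` list
#' @export
solute_props <- function(molar_mass, boiling_temperature, critical_temperature,
                         critical_pressure, acentric_factor, solid_molar_volume,
                         sublimation_pressure_override = NULL) {
  vals <- c(molar_mass, boiling_temperature, critical_temperature,
            critical_pressure, acentric_factor, solid_molar_volume)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all solute properties must be positive and finite")
  if (critical_temperature <= boiling_temperature)
    stop("critical temperature must exceed the boiling temperature")
  if (!is.null(sublimation_pressure_override) &&
      !is.function(sublimation_pressure_override))
    stop("sublimation_pressure_override must be a function of temperature")
  structure(list(
    molar_mass = molar_mass,
    boiling_temperature = boiling_temperature,
    critical_temperature = critical_temperature,
    critical_pressure = critical_pressure,
    acentric_factor = acentric_factor,
    solid_molar_volume = solid_molar_volume,
    sublimation_pressure_override = sublimation_pressure_override),
    class = "solute_props")
}

.required_cols <- c("T_K", "P_MPa", "rho_kg_m3", "y2", "y3", "sd")

#' Build a solubility table from per-record vectors
#'
#' The central data container: one row per equilibrium observation with
#' temperature (K), pressure (MPa), pure-CO2 density (kg/m^3), solute mole
#' fraction (y2 for binary, y2' for cosolvent-containing systems), cosolvent
#' mole fraction y3 (0 for binary) and the replicate standard deviation of
#' the mole fraction.
#'
#' @param T_K temperature in kelvin
#' @param P_MPa pressure in MPa
#' @param rho_kg_m3 solvent (CO2) density in kg/m^3
#' @param y2 solute mole fraction, in (0, 1)
#' @param y3 cosolvent mole fraction, in `[0, 1)`; default 0
#' @param sd replicate standard deviation of y2 (optional, default NA)
#' @param system a short label such as "binary" or "ethanol-3%"
#' @return a data frame of class `solubility_table`
#' @export
solubility_table <- function(T_K, P_MPa, rho_kg_m3, y2, y3 = 0, sd = NA_real_,
                             system = "unlabelled") {
  df <- data.frame(T_K = T_K, P_MPa = P_MPa, rho_kg_m3 = rho_kg_m3,
                   y2 = y2, y3 = y3, sd = sd)
  validate_solubility_table(df)
  structure(df, system = system,
            class = c("solubility_table", "data.frame"))
}

validate_solubility_table <- function(df) {
  core <- c("T_K", "P_MPa", "rho_kg_m3", "y2", "y3")
  bad <- !Reduce(`&`, lapply(df[core], function(v) is.finite(v)))
  if (any(bad))
    stop("non-finite fields in rows: ", paste(which(bad), collapse = ", "))
  chk <- function(ok, what) {
    if (any(!ok)) stop(what, " violated at rows: ",
                       paste(which(!ok), collapse = ", "))
  }
  chk(df$T_K > 0, "temperature > 0")
  chk(df$P_MPa > 0, "pressure > 0")
  chk(df$rho_kg_m3 > 0, "density > 0")
  chk(df$y2 > 0 & df$y2 < 1, "0 < mole fraction < 1")
  chk(df$y3 >= 0 & df$y3 < 1, "0 <= cosolvent fraction < 1")
  invisible(df)
}

#' Read a solubility table from CSV
#'
#' Expects the package CSV schema `system,T_K,P_MPa,rho_kg_m3,y2,y3,sd`
#' (comma-separated, header row, "." decimal mark). Column names can be
#' remapped through `schema`. Mole fractions are stored as plain
#' dimensionless values; if the file carries the common x10^4 table scaling,
#' pass `scale = 1e-4`.
#'
#' @param path CSV file path
#' @param schema named character vector mapping package column names to file
#'   column names, e.g. `c(y2 = "mole_frac")`; defaults to the identity
#' @param scale multiplier applied to `y2` and `sd` on read (default 1)
#' @return a `solubility_table`
#' @export
load_solubility_table <- function(path, schema = NULL, scale = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0) stop("empty table: ", path)
  names_map <- stats::setNames(.required_cols, .required_cols)
  if (!is.null(schema)) names_map[names(schema)] <- schema
  missing <- setdiff(unname(names_map[c("T_K", "P_MPa", "rho_kg_m3", "y2")]),
                     names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  out <- data.frame(
    T_K = as.numeric(df[[names_map["T_K"]]]),
    P_MPa = as.numeric(df[[names_map["P_MPa"]]]),
    rho_kg_m3 = as.numeric(df[[names_map["rho_kg_m3"]]]),
    y2 = as.numeric(df[[names_map["y2"]]]) * scale,
    y3 = if (names_map["y3"] %in% names(df))
      as.numeric(df[[names_map["y3"]]]) else 0,
    sd = if (names_map["sd"] %in% names(df))
      as.numeric(df[[names_map["sd"]]]) * scale else NA_real_)
  system <- if ("system" %in% names(df)) as.character(df$system[1]) else "unlabelled"
  solubility_table(out$T_K, out$P_MPa, out$rho_kg_m3, out$y2, out$y3, out$sd,
                   system = system)
}

#' Write a solubility table to CSV
#'
#' Inverse of [load_solubility_table()]; the round trip is lossless.
#'
#' @param x a `solubility_table`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_solubility_table <- function(x, path) {
  df <- as.data.frame(x)
  df <- cbind(system = attr(x, "system") %||% "unlabelled", df)
  df$y2 <- formatC(df$y2, format = "e", digits = 15)
  df$sd <- ifelse(is.na(df$sd), "", formatC(df$sd, format = "e", digits = 15))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.builtin_files <- c(
  "binary" = "methyldopa_binary.csv",
  "ethanol-1%" = "methyldopa_ethanol1.csv",
  "ethanol-3%" = "methyldopa_ethanol3.csv")

#' Packaged methyldopa solubility tables
#'
#' The isothermal solubility measurements for methyldopa in supercritical
#' CO2: the binary system (28 records over 308-338 K and 12-30 MPa) and the
#' two ethanol-cosolvent systems at 1 and 3 mol% (28 records each).
#' Cosolvent records carry the pure-CO2 density at the matching (T, P),
#' since all density models correlate against the solvent density.
#'
#' @param system one of `"binary"`, `"ethanol-1%"`, `"ethanol-3%"`, or
#'   `"ternary"` (both ethanol levels pooled, 56 records)
#' @return a `solubility_table`
#' @export
#' @examples
#' nrow(builtin_dataset("binary"))
builtin_dataset <- function(system = c("binary", "ethanol-1%", "ethanol-3%",
                                       "ternary")) {
  if (!is.character(system) || !system[1] %in% c(names(.builtin_files), "ternary"))
    stop("unknown system '", system[1], "'; valid labels: ",
         paste(c(names(.builtin_files), "ternary"), collapse = ", "))
  system <- system[1]
  if (system == "ternary") {
    a <- builtin_dataset("ethanol-1%")
    b <- builtin_dataset("ethanol-3%")
    out <- rbind(as.data.frame(a), as.data.frame(b))
    return(structure(out, system = "ternary",
                     class = c("solubility_table", "data.frame")))
  }
  path <- system.file("extdata", .builtin_files[[system]],
                      package = utils::packageName())
  load_solubility_table(path)
}

#' Pure-CO2 density on the experimental grid
#'
#' Looks up the tabulated CO2 density (NIST values shipped with the binary
#' table) at a grid point of the 4 x 7 experimental design, optionally
#' interpolating bilinearly off-grid.
#'
#' @param T_K temperature in K
#' @param P_MPa pressure in MPa
#' @param table density source, default the packaged binary table
#' @param interpolate allow bilinear interpolation off the grid
#' @return density in kg/m^3
#' @export
#' @examples
#' density_lookup(308, 12)
density_lookup <- function(T_K, P_MPa, table = builtin_dataset("binary"),
                           interpolate = FALSE) {
  hit <- which(table$T_K == T_K & table$P_MPa == P_MPa)
  if (length(hit) >= 1) return(table$rho_kg_m3[hit[1]])
  if (!interpolate) {
    Ts <- sort(unique(table$T_K)); Ps <- sort(unique(table$P_MPa))
    stop(sprintf(
      "(%g K, %g MPa) is off the grid; nearest grid T: %s; nearest grid P: %s (set interpolate = TRUE)",
      T_K, P_MPa,
      paste(Ts[order(abs(Ts - T_K))][1:2], collapse = ", "),
      paste(Ps[order(abs(Ps - P_MPa))][1:2], collapse = ", ")))
  }
  Ts <- sort(unique(table$T_K)); Ps <- sort(unique(table$P_MPa))
  if (T_K < min(Ts) || T_K > max(Ts) || P_MPa < min(Ps) || P_MPa > max(Ps))
    stop("query outside the tabulated range; no extrapolation")
  tlo <- max(Ts[Ts <= T_K]); thi <- min(Ts[Ts >= T_K])
  plo <- max(Ps[Ps <= P_MPa]); phi <- min(Ps[Ps >= P_MPa])
  g <- function(tt, pp) table$rho_kg_m3[table$T_K == tt & table$P_MPa == pp][1]
  wt <- if (thi > tlo) (T_K - tlo) / (thi - tlo) else 0
  wp <- if (phi > plo) (P_MPa - plo) / (phi - plo) else 0
  (1 - wt) * ((1 - wp) * g(tlo, plo) + wp * g(tlo, phi)) +
    wt * ((1 - wp) * g(thi, plo) + wp * g(thi, phi))
}

#' Mole fraction from gravimetric masses
#'
#' Converts the dissolved mass (initial minus final tablet mass) into the
#' solute mole fraction in the fluid phase.
#'
#' @param initial_mass g, tablet mass before exposure
#' @param final_mass g, tablet mass after exposure
#' @param moles_co2 mol of CO2 in the cell
#' @param molar_mass solute molar mass, g/mol
#' @return dimensionless mole fraction
#' @export
#' @examples
#' mole_fraction_from_masses(0.10, 0.09, 1, 211.21)
mole_fraction_from_masses <- function(initial_mass, final_mass, moles_co2,
                                      molar_mass = methyldopa_props()$molar_mass) {
  if (any(final_mass > initial_mass))
    stop("final mass exceeds initial mass: dissolved mass cannot be negative")
  if (any(final_mass < 0) || any(moles_co2 <= 0))
    stop("masses must be non-negative and moles_co2 positive")
  n_drug <- (initial_mass - final_mass) / molar_mass
  n_drug / (n_drug + moles_co2)
}

#' @export
print.solubility_table <- function(x, ...) {
  cat(sprintf("<solubility_table> system = %s, %d records, %d isotherm(s)\n",
              attr(x, "system") %||% "unlabelled", nrow(x),
              length(unique(x$T_K))))
  print(as.data.frame(x), ...)
  invisible(x)
}
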