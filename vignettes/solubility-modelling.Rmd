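---
title: "Modelling drug solubility in supercritical CO2: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling drug solubility in supercritical CO2: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Methyldopa, a polar antihypertensive, dissolves only sparingly in pure
supercritical CO2 (mole fractions of order 1e-5 to 1e-4 between 308 and
338 K and 12 and 30 MPa). Adding 1-3 mol % ethanol as a cosolvent raises
the solubility up to ~16-fold. `scco2sol` packages the isothermal
solubility tables for the binary (CO2 + drug) and ternary (CO2 + ethanol +
drug) systems and implements the two standard correlation routes for such
data:

1. **semi-empirical density models** — log-linear correlations of the
   solubility against the solvent density, temperature, pressure and
   cosolvent fraction, fitted per model to the data;
2. **a cubic equation of state** — Peng-Robinson (PR) with two-parameter
   van der Waals (vdW2) mixing rules, solving the solid-fluid equilibrium
   from pure-component constants plus two regressed binary interaction
   parameters.

Everything downstream of the fits — enthalpy decomposition, enhancement
factors, crossover pressures — is computed from these two routes.

## The density-model family

Ten models are registered, four binary and six ternary. All of them are
*linear in their adjustable parameters* after a log (or T-times-log)
transform of the response:

| id | form (transformed response = linear predictor) | k |
|----|-----------------------------------------------|---|
| `chrastil` | ln S = a0 ln rho + a1/T + a2 | 3 |
| `kumar_johnston` | ln y2 = a0 + a1 rho + a2/T | 3 |
| `bartle` | ln(y2 P/Pref) = a0 + a1/T + a2 (rho - rho_ref) | 3 |
| `mst_binary` | T ln(y2 P/Pref) = a0 + a1 rho + a2 T | 3 |
| `mst_ternary` | T ln(y2' P/Pref) = a0 + a1 rho + a2 T + a3 y3 | 4 |
| `sodeifian_sajadian` | ln y2' = (a0 + a1 rho/T) ln rho + a2 rho + a3 ln(y3 P) | 4 |
| `gonzalez` | ln y2' = a0 ln rho + a1 ln y3 + a2/T + a3 | 4 |
| `soltani_mazloumi` | ln y2' = a0 + a1/T + a2 rho/T - a3 ln P + a4 ln(y3 rho T) | 5 |
| `jouyban` | ln y2' = a0 + a1 y3 + a2 rho + a3 P^2 + a4 P T + a5 T/P + a6 ln rho | 7 |
| `garlapati_madras` | ln y2' = a0 + a1 ln rho + a2 rho + a3/T + a4 ln T + a5 ln y3 + a6 ln(y3 rho T) | 7 |

Here y2 (y2' with cosolvent) is the solute mole fraction, rho the pure-CO2
density and y3 the cosolvent mole fraction. Chrastil correlates the mass
solubility S in g/L, computed from the mole fraction via
S = rho M_drug y2 / (M_CO2 (1 - y2)); all other models correlate the mole
fraction itself.

**Unit conventions matter because fitted parameter values depend on
them.** Throughout: T in K, rho in kg/m^3; P in bar with Pref = 1 bar for
the reference-pressure-bearing forms (Bartle and both MST variants,
following the literature standard) and in MPa everywhere else, exactly as
the remaining forms are conventionally printed. The Bartle reference
density is rho_ref = 700 kg/m^3. The arguments of ln(y3 P) and
ln(y3 rho T) use those same units. Since every parameter set is refit from
data, any fixed convention is internally consistent — but parameters are
not transferable across conventions, so this one is stated prominently.

Two of the ten designs deserve a warning. `garlapati_madras` contains
ln(y3 rho T) alongside ln rho, ln T and ln y3, which makes its design
matrix *exactly* rank-deficient: one parameter direction is unidentified,
and only the fitted surface (not the individual parameters) is
reproducible. `jouyban` is full rank on the experimental grid but
ill-conditioned. The fitting layer pins unidentified least-squares
directions at zero and the tests check surface recovery, not parameter
recovery, for the degenerate case.

## Fitting

The default objective is the average absolute relative deviation,

AARD% = 100/N * sum |y_cal - y_exp| / y_exp,

minimised directly, because AARD is the statistic the field reports;
`sse_log` (least squares on the transformed scale) and raw `sse` are
available for sensitivity checks. Because every model is linear on the
transformed scale, an ordinary least-squares solve (`stats::lm.fit`)
yields the exact `sse_log` optimum in closed form. That solution seeds a
bounded simulated-annealing search (geometric cooling, factor 0.95 from a
relative temperature of 1 down to 1e-3, 200 proposals per level, 8
restarts, Gaussian proposals reflected into the box), whose best state is
polished with Nelder-Mead. Bounds default to the OLS start plus/minus
max(5|start|, 1) and are widened once (times 10) if the optimum lands on a
boundary. Ties across restarts resolve to the lowest restart index. The
whole fit is deterministic given `optimizer_config(seed = )`, and the
caller's RNG stream is restored afterwards.

Two consequences are worth spelling out. First, the annealed result can
never be worse than the OLS oracle under the `sse_log` objective — this is
asserted as a test invariant. Second, a *fully converged* AARD
minimisation typically lands 5-25 % below the AARD values quoted in the
solubility-correlation literature for comparable data, because published
fits are often stopped early; the package reports the converged optimum
and makes no attempt to emulate partial convergence.

Reported metrics per fit: AARD%, R^2 (1 - SSE/SStot), SSE, and a
small-sample corrected AIC, AICc = n ln(SSE/n) + 2k + 2k(k+1)/(n-k-1),
with k the nominal parameter count and SSE taken on the model's response
scale. The AICc convention (Gaussian likelihood, SSE-based) is a package
choice — other conventions shift all values by a constant, so only
differences are meaningful, and rankings are unaffected.

Ternary fits pool both ethanol levels (56 records, one parameter set per
model): every ternary equation carries y3 explicitly, so a single
parameter set is the natural scope.

## Peng-Robinson with vdW2 mixing

The solid-fluid equilibrium is

y2 = Psub(T)/P * (phi_sat / phi2(T, P, y)) * exp(v2s (P - Psub)/(R T)),

with the solute's fugacity coefficient phi2 in the fluid phase from PR:

- pure parameters a_i = 0.45724 R^2 Tc^2/Pc alpha(T),
  b_i = 0.07780 R Tc/Pc, alpha^(1/2) = 1 + kappa(1 - sqrt(T/Tc)),
  kappa = 0.37464 + 1.54226 w - 0.26992 w^2;
- quadratic mixing with a_ij = sqrt(a_i a_j)(1 - k12) and
  b_ij = (b_i + b_j)/2 (1 - l12) — note that the covolume is therefore
  composition-quadratic, so the fugacity expression uses the partial
  covolume bbar_i = 2 sum_j x_j b_ij - b_m where a linear-b formulation
  would just use b_i;
- component constants: CO2 Tc = 304.13 K, Pc = 7.377 MPa, w = 0.225;
  methyldopa Tc = 1177.3 K, Pc = 2.45 MPa, w = 0.558 (Ambrose-Walton),
  solid molar volume v2s = 335.4 cm^3/mol.

The analytic fugacity expression is verified in the tests against central
differences of the residual Helmholtz energy at fixed T and V to better
than six significant figures, including states with l12 != 0.

**Root selection.** When the cubic in Z has several admissible real roots
(v > b_m), the one minimising the residual Gibbs energy is taken; at the
dense supercritical conditions of the data this is the smallest-volume
root, and predictions are continuous in pressure along each isotherm.

**Sublimation pressure.** The solid's vapor pressure (sub-mPa here) comes
from a boiling-point-only correlation (modified Grain): with Tpt = T/Tb
and m = 0.4133 - 0.2575 Tpt,
ln(P/Patm) = (dSb/R)(1 - (3 - 2 Tpt)^m / Tpt - 2 m (3 - 2 Tpt)^(m-1) ln Tpt),
dSb = 86.9 J/(mol K), anchored so P(Tb) = 1 atm exactly. Because
Grain/Watson-type estimates vary by variant and dominate the predicted
solubility scale, `methyldopa_props()` accepts a
`sublimation_pressure_override` function so alternative estimates can be
injected without touching the equilibrium solver. phi_sat is fixed at 1:
at sub-pascal saturation pressures the solid's saturation fugacity
coefficient is indistinguishable from unity.

**Equilibrium solve.** Equation and fugacity are coupled through y2, so
the solver iterates y -> (Psub/P) Poynting / phi2(y) from y = 1e-5 to a
relative tolerance of 1e-10 (cap 200 iterations); across a table of
conditions each point warm-starts from the previous solution.

**Interaction-parameter regression.** The AARD surface over (k12, l12) is
a narrow curved ridge: slightly too little repulsion and the equilibrium
diverges, slightly too much and predictions collapse toward zero, where
AARD plateaus at 100 % and carries no gradient. The fitter therefore first
scans a coarse grid using mean |ln(pred/obs)| — which stays informative on
the plateau — and then anneals the AARD objective inside a box around the
best grid node, with a simplex polish. Both a global scope (one pair for
all records; k = 2 in AICc) and a per-isotherm scope (one pair per
temperature) are provided: on the packaged binary data the global optimum
sits near AARD 15 % while per-isotherm pairs reach ~8.5 % pooled, because
the effective solute-CO2 interaction weakens substantially with
temperature (k12 falls from ~0.26 at 308 K to ~0.14 at 338 K) and a single
pair cannot express that.

## Post-fit thermodynamics

- **Enthalpies.** The 1/T coefficient a1 (in K) of the Chrastil fit
  carries the total dissolution enthalpy, dH_total = -a1 R; the Bartle 1/T
  coefficient likewise gives the vaporization enthalpy. The solvation
  enthalpy is the exact identity dH_sol = dH_total - dH_vap. Note these
  values inherit the objective sensitivity of the parent fits: the AARD
  objective constrains a1 more loosely than least squares does, so
  enthalpies can shift by ~10-15 % between objectives.
- **Enhancement factors.** e = y2'/y2 at matched (T, P). The plain-ratio
  convention is used (an equivalent definition multiplies by 100) because
  the values carried in the packaged tables are plain ratios.
- **Crossover pressure.** No standard estimator exists; the package
  interpolates each isotherm piecewise-linearly in (P, ln y2), intersects
  isotherm pairs, reports each intersection with its bracketing grid
  interval, and aggregates by the median — a deterministic choice that
  needs no smoothing parameters. Non-intersecting pairs are reported as
  missing, not as errors.

## The synthetic-data generator

`generate_dataset()` emulates the structure of the measurements: the
4 x 7 (T, P) grid with the tabulated densities, mole fractions generated
from any registered model at chosen parameters, and *multiplicative*
lognormal replicate noise — y = mean over n_replicates of
y_model exp(eps), eps ~ N(0, sigma) — with sigma defaulting to 0.04, the
reported replicate-precision bound, and triplicate replicates as in the
measurement protocol. Multiplicative noise is the right shape here because
the stated precision is relative and the data span two orders of
magnitude; additive Gaussian noise would make small mole fractions go
negative. The generating truth travels with the dataset, so recovery
experiments are self-contained.

What the generator does *not* emulate: correlated errors along an
isotherm, density errors (densities are taken as exact), drift between
replicate runs, and any misspecification — synthetic data are exactly
on-model. Passing recovery tests therefore demonstrate that the optimizer
finds generating parameters under honest noise, not that any model is
"true" for real measurements.

## Problem sizes and runtime

The analysis scripts (`analysis/01...05`) run the full annealing schedule
on all 28/56-record tables (a few minutes in total). The test suite uses
a reduced schedule (2 restarts, 50 proposals per level) — sufficient
because the OLS seed already sits at the transformed-scale optimum — and
small recovery designs, keeping the suite to a few minutes. The
acceptance script uses the full schedule for the density models and the
ridge-scan configuration for the EoS regression.

## Known limitations

- PR underestimates the dense-CO2 density by ~6 % at the coldest, densest
  state point — the familiar cubic-EoS liquid-density bias; the EoS route
  absorbs this through the regressed interaction parameters.
- The ternary tables carry the pure-CO2 density at each (T, P); the small
  density increase from 1-3 % ethanol is not resolved by the data and is
  deliberately not modelled.
- Enthalpy extraction assumes the van 't Hoff-type interpretation of the
  1/T coefficients holds across the fitted range; no uncertainty is
  attached to the fitted parameters.
- The EoS route is implemented for the binary system only; ternary
  equation-of-state modelling (CO2 + ethanol + drug) is out of scope.
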