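co2 <- co2_component()
drug <- solute_component()
comps <- list(co2, drug)

test_that("pure PR parameters follow the critical-point constraints", {
  # alpha(Tc) = 1, so a reduces to 0.45724 R^2 Tc^2 / Pc exactly
  R <- 8.314462618
  p <- pr_pure_params(co2, co2$critical_temperature)
  expect_equal(p$a, 0.45724 * R^2 * 304.13^2 / 7.377e6, tolerance = 1e-12)
  expect_equal(pr_pure_params(co2, 308)$b, 2.66e-5, tolerance = 5e-3)
  # kappa(omega) increases on [0, 1]
  kappa <- function(w) 0.37464 + 1.54226 * w - 0.26992 * w^2
  w <- seq(0, 1, by = 0.05)
  expect_true(all(diff(kappa(w)) > 0))
})

test_that("vdW2 mixing reduces correctly in the pure and symmetric limits", {
  p1 <- pr_pure_params(co2, 320)
  # pure limit: x = (1, 0) gives component 1's constants for any k, l
  m <- pr_mixture_params(comps, c(1, 0), 320, k12 = 0.3, l12 = -0.2)
  expect_equal(m$a_m, p1$a, tolerance = 1e-12)
  expect_equal(m$b_m, p1$b, tolerance = 1e-12)
  # identical components with zero corrections: a_m = a1 at any composition
  twin <- list(co2, co2)
  m2 <- pr_mixture_params(twin, c(0.3, 0.7), 320)
  expect_equal(m2$a_m, p1$a, tolerance = 1e-12)
  expect_equal(m2$b_m, p1$b, tolerance = 1e-12)
  # equimolar mixture against direct summation of the a_ij table
  p2 <- pr_pure_params(drug, 320)
  a12 <- sqrt(p1$a * p2$a) * (1 - 0.1)
  m3 <- pr_mixture_params(comps, c(0.5, 0.5), 320, k12 = 0.1)
  expect_equal(m3$a_m, 0.25 * p1$a + 0.5 * a12 + 0.25 * p2$a,
               tolerance = 1e-12)
  expect_error(pr_mixture_params(comps, c(0.6, 0.6), 320), "sum to 1")
})

test_that("compressibility roots honour the ideal and dense limits", {
  expect_equal(pr_solve_z(308, 1e5, 0, 0)$Z, 1, tolerance = 1e-12)
  p <- pr_pure_params(co2, 308)
  expect_equal(pr_solve_z(308, 1, p$a, p$b)$Z, 1, tolerance = 1e-4)
  # dense CO2: single root whose density approximates the NIST value
  s <- pr_solve_z(308, 12e6, p$a, p$b)
  rho <- 12e6 * 44.01e-3 / (s$Z * 8.314462618 * 308)
  expect_equal(rho, 768.4, tolerance = 0.075)
  expect_true(all(s$roots * 8.314462618 * 308 / 12e6 > p$b))
})

test_that("analytic fugacity matches the Helmholtz finite-difference oracle", {
  set.seed(11)
  for (rep in 1:8) {
    T <- runif(1, 305, 340); P <- runif(1, 8e6, 3e7)
    y <- 10^runif(1, -6, -2)
    k <- runif(1, -0.4, 0.6); l <- runif(1, -0.4, 0.4)
    fa <- pr_fugacity(comps, c(1 - y, y), T, P, k, l)
    fn <- pr_fugacity_numeric(comps, c(1 - y, y), T, P, k, l)
    expect_equal(fa, fn, tolerance = 1e-6)
  }
})

test_that("fugacity limits: pure reduction and ideal gas", {
  p <- pr_pure_params(co2, 318)
  phi_mix <- pr_fugacity(comps, c(1, 0), 318, 15e6, k12 = 0.2, l12 = 0.1)[1]
  # pure-component PR fugacity from the single-component routine
  phi_pure <- pr_fugacity(list(co2), 1, 318, 15e6)[1]
  expect_equal(phi_mix, phi_pure, tolerance = 1e-10)
  expect_equal(pr_fugacity(comps, c(0.9999, 1e-4), 318, 10, 0.1, 0.05),
               c(1, 1), tolerance = 1e-4)
})

test_that("Gibbs-Duhem holds along a composition perturbation", {
  T <- 318; P <- 15e6; k <- 0.2; l <- -0.05
  y <- 1e-4; h <- 1e-7
  lnphi <- function(y) log(pr_fugacity(comps, c(1 - y, y), T, P, k, l))
  dlnphi <- (lnphi(y + h) - lnphi(y - h)) / (2 * h)
  resid <- sum(c(1 - y, y) * dlnphi)
  expect_lt(abs(resid), 1e-4)
})

test_that("sublimation pressure correlation is anchored and monotone", {
  expect_equal(sublimation_pressure(844.5, 844.5), 101325, tolerance = 1e-10)
  Ts <- seq(250, 844, by = 25)
  expect_true(all(diff(sublimation_pressure(Ts, 844.5)) > 0))
  p308 <- sublimation_pressure(308, 844.5)
  expect_gt(p308, 0)
  expect_lt(p308, 1)
  expect_error(sublimation_pressure(900, 844.5), "Tb")
  # override hook replaces the correlation
  props <- methyldopa_props(sublimation_pressure_override = function(T) 5e-4)
  r <- solubility_eos(318, 15, props, k12 = 0.3, l12 = 0)
  expect_equal(r$psub_Pa, 5e-4)
})

test_that("the equilibrium solution satisfies the solid-fluid fixed point", {
  r <- solubility_eos(318, 15, k12 = 0.25, l12 = 0)
  props <- methyldopa_props()
  psub <- sublimation_pressure(318, props$boiling_temperature)
  poynting <- exp(props$solid_molar_volume * 1e-6 * (15e6 - psub) /
                    (8.314462618 * 318))
  # y2 * phi2 = (Psub/P) * poynting, and at P = Psub the Poynting factor is 1
  expect_equal(r$y2 * r$phi2, psub / 15e6 * poynting, tolerance = 1e-8)
  expect_equal(exp(props$solid_molar_volume * 1e-6 * 0 /
                     (8.314462618 * 318)), 1)
  # with the fugacity correction stripped the closed form is recovered
  expect_equal(r$y2, psub / 15e6 * poynting / r$phi2, tolerance = 1e-8)
})

test_that("EoS predictions vary continuously along each isotherm", {
  bin <- binary_table()
  pred <- solubility_eos_grid(bin, k12 = 0.22, l12 = 0)
  for (tt in unique(bin$T_K)) {
    p <- pred[bin$T_K == tt]
    expect_true(all(abs(diff(log(p))) < 2), info = tt)
  }
})

test_that("known interaction parameters are recovered from noise-free EoS data", {
  k_true <- 0.19; l_true <- -0.07
  bin <- binary_table()
  y <- solubility_eos_grid(bin, k12 = k_true, l12 = l_true)
  synth <- solubility_table(bin$T_K, bin$P_MPa, bin$rho_kg_m3, y,
                            system = "synthetic:eos")
  fit <- fit_interaction_params(synth,
                                config = optimizer_config(seed = 3,
                                                          n_restarts = 2L,
                                                          iters_per_temp = 30L,
                                                          t_min = 0.05))
  expect_lt(abs(fit$k12 - k_true), 1e-3)
  expect_lt(abs(fit$l12 - l_true), 1e-3)
  expect_lt(fit$metrics$aard_percent, 0.1)
})

test_that("per-isotherm regression returns one parameter pair per temperature", {
  one <- binary_table()
  one <- one[one$T_K == 318, ]
  fit <- fit_interaction_params(one, scope = "per_isotherm",
                                config = optimizer_config(seed = 2,
                                                          n_restarts = 2L,
                                                          iters_per_temp = 30L,
                                                          t_min = 0.05))
  expect_equal(nrow(fit$by_isotherm), 1)
  expect_equal(fit$by_isotherm$T_K, 318)
})
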