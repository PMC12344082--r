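cond1 <- data.frame(T_K = 308, P_MPa = 12, rho_kg_m3 = 700, y3 = 0.03)

test_that("registry exposes the ten models with their parameter counts", {
  counts <- c(chrastil = 3, kumar_johnston = 3, bartle = 3, mst_binary = 3,
              mst_ternary = 4, sodeifian_sajadian = 4, gonzalez = 4,
              soltani_mazloumi = 5, jouyban = 7, garlapati_madras = 7)
  expect_setequal(model_ids(), names(counts))
  for (id in names(counts)) {
    sp <- model_spec(id)
    expect_equal(sp$n_params, unname(counts[id]), info = id)
  }
  expect_equal(model_spec("chrastil")$response, "mass_solubility")
  expect_true(model_spec("gonzalez")$requires_cosolvent)
  expect_false(model_spec("bartle")$requires_cosolvent)
  expect_error(model_spec("nosuch"), "unknown model")
})

test_that("hand-evaluated forms match evaluate_model", {
  # gonzalez: ln y = a0 ln(rho) + a1 ln(y3) + a2/T + a3
  lhs <- log(700) + 0.5 * log(0.03) - 1000 / 308 - 10
  expect_equal(lhs, -8.449, tolerance = 1e-4)
  expect_equal(evaluate_model("gonzalez", c(1, 0.5, -1000, -10), cond1),
               exp(lhs), tolerance = 1e-12)
  # degenerate parameter sets
  expect_equal(evaluate_model("gonzalez", c(0, 0, 0, -5), cond1), exp(-5))
  expect_equal(evaluate_model("kumar_johnston", c(-9, 0, 0), cond1), exp(-9))
  # kumar_johnston full form
  expect_equal(evaluate_model("kumar_johnston", c(-12, 0.004, -800), cond1),
               exp(-12 + 0.004 * 700 - 800 / 308), tolerance = 1e-12)
  # bartle and MST use P in bar with P_ref = 1 bar and rho_ref = 700
  expect_equal(evaluate_model("bartle", c(5, -6000, 0.01),
                              transform(cond1, rho_kg_m3 = 750)),
               exp(5 - 6000 / 308 + 0.01 * 50) / 120, tolerance = 1e-12)
  expect_equal(evaluate_model("mst_binary", c(-8000, 2, 20), cond1),
               exp((-8000 + 2 * 700 + 20 * 308) / 308) / 120,
               tolerance = 1e-12)
  # soltani_mazloumi subtracts its a3 ln(P) term
  p <- c(-2, -500, 1.5, 0.2, 0.9)
  expect_equal(evaluate_model("soltani_mazloumi", p, cond1),
               exp(-2 - 500 / 308 + 1.5 * 700 / 308 - 0.2 * log(12) +
                     0.9 * log(0.03 * 700 * 308)), tolerance = 1e-12)
})

test_that("parameter arity and cosolvent preconditions are enforced", {
  expect_error(evaluate_model("gonzalez", c(1, 2, 3), cond1), "4 parameters")
  expect_error(evaluate_model("chrastil", 1:4, cond1), "3 parameters")
  bincond <- transform(cond1, y3 = 0)
  expect_error(evaluate_model("gonzalez", c(1, 0.5, -1000, -10), bincond),
               "y3 = 0")
  # binary models ignore y3 entirely
  expect_equal(evaluate_model("kumar_johnston", c(-9, 0, 0), bincond),
               exp(-9))
})

test_that("predictions increase with density when the density coefficient is positive", {
  grid <- data.frame(T_K = 318, P_MPa = 18,
                     rho_kg_m3 = seq(400, 900, by = 50), y3 = 0.03)
  for (id in model_ids()) {
    sp <- model_spec(id)
    params <- switch(id,
      chrastil = c(2, -4000, -8), kumar_johnston = c(-14, 0.005, -1000),
      bartle = c(10, -6000, 0.01), mst_binary = c(-9000, 2.5, 15),
      mst_ternary = c(-9000, 2.5, 15, 5000),
      sodeifian_sajadian = c(1.5, 0.2, 0.001, 0.5),
      gonzalez = c(3, 1, -4500, -12),
      soltani_mazloumi = c(-1, -5000, 1.2, 0.2, 0.9),
      jouyban = c(-60, 50, 0.005, -0.001, 4e-4, -0.005, 9),
      garlapati_madras = c(3, 1.3, 0.003, -4900, 0.4, 1.4, -0.5))
    y <- evaluate_model(id, params, grid)
    expect_true(all(diff(y) > 0), info = id)
  }
})

test_that("self-consistency coordinates are exactly linear on noise-free data", {
  for (id in c("mst_binary", "gonzalez", "garlapati_madras")) {
    sp <- model_spec(id)
    params <- switch(id, mst_binary = c(-9000, 2.5, 15),
                     gonzalez = c(3, 1, -4500, -12),
                     garlapati_madras = c(3, 1.3, 0.003, -4900, 0.4, 1.4, -0.5))
    cfg <- synthetic_config(id, params, noise_rsd = 0,
                            cosolvent_levels = if (sp$requires_cosolvent)
                              c(0.01, 0.03) else 0)
    dat <- generate_dataset(cfg)
    lc <- linearized_coordinates(id, params, dat)
    expect_equal(lc$r_squared, 1, tolerance = 1e-9, info = id)
    # the coordinates invert back through evaluate_model
    pred <- evaluate_model(id, params, dat)
    obs <- if (sp$response == "mass_solubility")
      mass_solubility(dat$y2, dat$rho_kg_m3) else dat$y2
    expect_equal(pred, obs, tolerance = 1e-8, info = id)
  }
  one <- builtin_dataset("binary")[1, ]
  expect_error(linearized_coordinates("mst_binary", c(-9000, 2.5, 15), one),
               "two records")
})

test_that("fitted ternary models stay internally consistent on the measured data", {
  fit <- fit_model("mst_ternary", ternary_table(), fast_config())
  lc <- linearized_coordinates("mst_ternary", fit$params, ternary_table())
  expect_gt(lc$r_squared, 0.9)
})

test_that("Chrastil's g/L response and mole fractions interconvert through the density relation", {
  bin <- binary_table()
  S <- mass_solubility(bin$y2, bin$rho_kg_m3)
  y_back <- scco2sol:::mass_to_mole_fraction(S, bin$rho_kg_m3)
  expect_equal(y_back, bin$y2, tolerance = 1e-12)
})
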