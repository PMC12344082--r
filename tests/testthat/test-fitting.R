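test_that("AARD matches hand evaluation and validates inputs", {
  expect_equal(aard(c(1, 2), c(1, 2)), 0)
  expect_equal(aard(c(1, 2), c(1.1, 1.8)), 10)
  expect_error(aard(1:3, 1:2), "lengths differ")
  expect_error(aard(c(0, 1), c(1, 1)), "zero")
})

test_that("R^2 matches hand evaluation and validates inputs", {
  expect_equal(r_squared(1:3, 1:3), 1)
  obs <- c(1, 2, 3)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2), c(1, 2)), "constant")
})

test_that("AICc follows the small-sample Gaussian form", {
  expect_equal(aicc(28, 28, 3), 6 + 24 / 24)
  expect_equal(aicc(2 * 28, 28, 3) - aicc(28, 28, 3), 28 * log(2))
  expect_error(aicc(1, 4, 3), "n_points")
  expect_error(aicc(-1, 28, 3), "sse")
})

test_that("fits are deterministic given the seed", {
  f1 <- fit_model("kumar_johnston", binary_table(), fast_config(7))
  f2 <- fit_model("kumar_johnston", binary_table(), fast_config(7))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$metrics$aard_percent, f2$metrics$aard_percent)
  f3 <- fit_model("kumar_johnston", binary_table(), fast_config(8))
  expect_false(identical(f3$trace$restart_values, f1$trace$restart_values))
})

test_that("fitting does not disturb the caller's RNG stream", {
  set.seed(42); before <- rnorm(1)
  set.seed(42)
  invisible(fit_model("kumar_johnston", binary_table(), fast_config()))
  expect_identical(rnorm(1), before)
})

test_that("the returned objective dominates every restart's final state", {
  f <- fit_model("chrastil", binary_table(), fast_config())
  expect_true(all(f$trace$best_objective <= f$trace$restart_values + 1e-12))
  expect_equal(f$trace$best_objective, f$metrics$aard_percent,
               tolerance = 1e-10)
})

test_that("annealed log-SSE never exceeds the linearised least-squares oracle", {
  for (id in c("chrastil", "kumar_johnston", "bartle", "mst_binary")) {
    bin <- binary_table()
    f <- fit_model(id, bin, fast_config(), objective = "sse_log")
    # independent oracle: ordinary least squares on the linearised form
    m <- scco2sol:::.model_registry[[id]]
    d <- scco2sol:::as_conditions(bin)
    obs <- scco2sol:::observed_response(id, d)
    X <- m$design(d)
    ols <- stats::lm.fit(X, m$lhs(d, obs))
    sse_ols <- sum(ols$residuals^2)
    expect_lte(f$trace$best_objective, sse_ols * (1 + 1e-8) + 1e-8)
  }
})

test_that("noise-free generating parameters are recovered exactly", {
  true <- list(
    chrastil = c(2, -4000, -8), kumar_johnston = c(-14, 0.005, -1000),
    bartle = c(10, -6000, 0.01), mst_binary = c(-9000, 2.5, 15),
    mst_ternary = c(-9000, 2.5, 15, 5000),
    sodeifian_sajadian = c(-1.77, -0.58, 0.0177, 0.94),
    gonzalez = c(3, 1, -4500, -12),
    soltani_mazloumi = c(-1, -5000, 1.2, 0.2, 0.9),
    jouyban = c(-63.57, 53.19, -0.0144, -0.00195, 4.79e-4, -0.00599, 9.51))
  for (id in names(true)) {
    sp <- model_spec(id)
    cfg <- synthetic_config(id, true[[id]], noise_rsd = 0,
                            cosolvent_levels = if (sp$requires_cosolvent)
                              c(0.01, 0.03) else 0)
    dat <- generate_dataset(cfg)
    fit <- fit_model(id, dat, fast_config())
    expect_lt(max(abs(fit$params - true[[id]]) / abs(true[[id]])), 1e-3)
    expect_lt(fit$metrics$aard_percent, 1e-4)
  }
})

test_that("a rank-deficient model recovers the generating surface if not the parameters", {
  # garlapati_madras contains ln(y3 rho T) alongside its own summands, so
  # parameter directions are unidentified; the fitted surface must still
  # reproduce noise-free data.
  truth <- c(3, 1.3, 0.003, -4900, 0.4, 1.4, -0.5)
  cfg <- synthetic_config("garlapati_madras", truth, noise_rsd = 0,
                          cosolvent_levels = c(0.01, 0.03))
  dat <- generate_dataset(cfg)
  fit <- fit_model("garlapati_madras", dat, fast_config())
  expect_lt(fit$metrics$aard_percent, 1e-4)
})

test_that("fit_model enforces preconditions", {
  expect_error(fit_model("gonzalez", binary_table(), fast_config()), "y3")
  small <- binary_table()[1:3, ]
  expect_error(fit_model("chrastil", small, fast_config()), "n_params \\+ 2")
  expect_error(optimizer_config(n_restarts = 0), "n_restarts")
  expect_error(optimizer_config(bounds = rbind(1, 0)), "lower < upper")
})

test_that("fit_all ranks models by AICc and tolerates per-model failures", {
  res <- fit_all(ternary_table(), c("gonzalez", "mst_ternary"), fast_config())
  expect_named(res$fits, c("gonzalez", "mst_ternary"))
  ok <- res$summary[res$summary$error == "", ]
  expect_equal(ok$aicc, sort(ok$aicc))
  # a model whose preconditions fail yields an error entry, not an abort
  mixed <- fit_all(binary_table(), c("kumar_johnston", "gonzalez"),
                   fast_config())
  expect_s3_class(mixed$fits$kumar_johnston, "fitted_model")
  expect_match(mixed$summary$error[mixed$summary$model == "gonzalez"], "y3")
  empty <- fit_all(ternary_table(), character(0), fast_config())
  expect_equal(nrow(empty$summary), 0)
})
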