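# Shared fixtures and reduced optimizer settings so the suite stays fast;
# the analysis scripts use the full default schedule.

fast_config <- function(seed = 1L)
  optimizer_config(seed = seed, n_restarts = 2L, iters_per_temp = 50L)

acc_config <- function(seed = 1L)
  optimizer_config(seed = seed, n_restarts = 4L, iters_per_temp = 100L)

binary_table <- function() builtin_dataset("binary")
ternary_table <- function() builtin_dataset("ternary")

# A tiny two-isotherm table whose log-solubility isotherms cross at an
# exactly constructed pressure.
crossing_isotherms <- function(p_star = 16) {
  P <- c(12, 15, 18, 21)
  # line A: ln y = -10 + 0.05 (P - p_star); line B: ln y = -10 - 0.08 (P - p_star)
  ya <- exp(-10 + 0.05 * (P - p_star))
  yb <- exp(-10 - 0.08 * (P - p_star))
  solubility_table(T_K = rep(c(308, 338), each = 4), P_MPa = rep(P, 2),
                   rho_kg_m3 = rep(700, 8), y2 = c(ya, yb),
                   system = "constructed")
}
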