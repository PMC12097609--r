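sl_long <- solver_config(t_end = 2000, n_report = 2001)

test_that("a trajectory resting at a stable equilibrium is a stable point", {
  p <- model_params(beta0 = 0.58)
  eqs <- find_equilibria(p, x = 0, n_grid = 6)
  co <- eqs[eqs$kind == "coexistence", ]
  traj <- simulate_model(p, initial_state(co$S, co$I, co$P, 0),
                         solver_config(t_end = 500))
  att <- classify_attractor(traj)
  expect_identical(att$regime, "stable_point")
  expect_false(att$oscillatory)
})

test_that("the oscillatory ladder scenario classifies as a cycle", {
  traj <- simulate_model(model_params(beta0 = 0.8), solver = sl_long)
  att <- classify_attractor(traj)
  expect_true(att$regime %in% c("limit_cycle", "period_doubled"))
  expect_true(att$oscillatory)
  expect_length(att$extinct, 0)
  # neutral direction along the cycle: |lambda| below the chaos threshold
  expect_lt(abs(att$lyapunov), 0.005)
})

test_that("Lyapunov exponent is negative near a stable focus", {
  p <- model_params(beta0 = 0.58)
  eqs <- find_equilibria(p, x = 0, n_grid = 6)
  co <- eqs[eqs$kind == "coexistence", ]
  lam <- largest_lyapunov(p, initial_state(co$S, co$I, co$P, 0),
                          solver_config(t_end = 1000, transient = 100))
  expect_lt(lam, 0)
})

test_that("Lyapunov estimate is flagged not-applicable under extinction", {
  lam <- largest_lyapunov(model_params(beta0 = 0.5),
                          solver = solver_config(t_end = 1500, transient = 500))
  expect_true(is.na(lam))
  expect_identical(attr(lam, "reason"), "extinction")
})

test_that("a single-point scan equals one simulate + classify call", {
  p <- model_params(beta0 = 0.8)
  sl <- solver_config(t_end = 600, n_report = 601)
  sc <- scan_1d(p, "beta0", 0.8, solver = sl, lyapunov = FALSE)
  expect_equal(nrow(sc), 1)
  att <- classify_attractor(simulate_model(p, initial_state(), sl),
                            lyapunov = FALSE)
  expect_identical(sc$regime, att$regime)
  expect_equal(sc$S_amp, att$extrema$amplitude[1])
})

test_that("the frozen-strategy scan flips from oscillatory to steady", {
  sc <- scan_1d(model_params(beta0 = 0.95), "x", seq(0.30, 0.50, by = 0.02),
                solver = sl_long, lyapunov = FALSE)
  expect_true(sc$oscillatory[1])
  expect_false(sc$oscillatory[nrow(sc)])
  flip <- scan_regime_flip(sc)
  expect_false(is.na(flip))
  # the flip tracks the coexistence-collapse (predator invasion) threshold
  thr <- invasion_threshold(model_params(beta0 = 0.95), "x", c(0.2, 0.8))
  expect_lt(abs(flip - as.numeric(thr)), 0.02 + 1e-9)  # one grid step
})

test_that("a stronger Allee effect raises the infected floor in the scan", {
  xs <- c(0, 0.1, 0.2)
  sl <- solver_config(t_end = 1200, n_report = 1201)
  sc0 <- scan_1d(model_params(beta0 = 0.95, theta = 0), "x", xs,
                 solver = sl, lyapunov = FALSE)
  sc3 <- scan_1d(model_params(beta0 = 0.95, theta = 0.3), "x", xs,
                 solver = sl, lyapunov = FALSE)
  expect_true(all(sc3$I_min > sc0$I_min))
})

test_that("fixed and continuation policies agree off any bistable window", {
  xs <- seq(0.30, 0.50, by = 0.04)
  a <- scan_1d(model_params(beta0 = 0.95), "x", xs, solver = sl_long,
               lyapunov = FALSE)
  b <- scan_1d(model_params(beta0 = 0.95), "x", xs, solver = sl_long,
               policy = "continuation", lyapunov = FALSE)
  expect_identical(a$oscillatory, b$oscillatory)
})

test_that("eigenvalue bisection lands on the linear Hopf point", {
  p <- model_params(beta0 = 0.95)
  thr_x <- hopf_threshold(p, "x", c(0.2, 0.40))
  expect_equal(as.numeric(thr_x), 0.362376, tolerance = 1e-3)
  expect_lt(abs(attr(thr_x, "max_re")), 1e-6)

  thr_b <- hopf_threshold(model_params(), "beta0", c(0.58, 0.65), x = 0)
  expect_equal(as.numeric(thr_b), 0.605743, tolerance = 1e-3)
})

test_that("threshold bisection raises the contracted errors", {
  p <- model_params(beta0 = 0.95)
  # both endpoints unstable: no sign change
  expect_error(hopf_threshold(p, "x", c(0.05, 0.2)),
               class = "ecoepi_no_sign_change")
  # the coexistence branch terminates inside (0.2, 0.6)
  expect_error(hopf_threshold(p, "x", c(0.2, 0.6)),
               class = "ecoepi_equilibrium_lost")
  # with a weak Allee effect the predator can never invade from rarity
  expect_error(invasion_threshold(model_params(beta0 = 0.95, theta = 0.1),
                                  "x", c(0.2, 0.8)),
               class = "ecoepi_no_sign_change")
})

test_that("the collapse threshold sits where the predator invasion fails", {
  thr <- invasion_threshold(model_params(beta0 = 0.95), "x", c(0.2, 0.8))
  expect_equal(as.numeric(thr), 0.418494, tolerance = 1e-3)
  eq <- attr(thr, "equilibrium")
  expect_identical(unname(eq[["P"]]), 0)
  expect_gt(eq[["I"]], 0)
})

test_that("a 1x1 two-parameter scan reduces to a single classified run", {
  p <- model_params(beta0 = 0.7, theta = 0.1, CP = 0.5, x_mode = "dynamic")
  sc <- scan_2d(p, c("CS", "e"), list(0.5, 0.5), solver = sl_long,
                lyapunov = FALSE)
  expect_equal(nrow(sc), 1)
  expect_true(startsWith(sc$regime, "extinct"))
})
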