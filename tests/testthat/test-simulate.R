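test_that("the extinction state is preserved exactly", {
  traj <- simulate_model(model_params(), initial_state(0, 0, 0, 0),
                         solver_config(t_end = 100, n_report = 101))
  expect_true(all(traj$S == 0 & traj$I == 0 & traj$P == 0 & traj$x == 0))
})

test_that("simulation is deterministic and the two engines agree", {
  p <- model_params(beta0 = 0.8)
  sl <- solver_config(t_end = 150, n_report = 301)
  a <- simulate_model(p, initial_state(), sl)
  b <- simulate_model(p, initial_state(), sl)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))

  r <- simulate_model(p, initial_state(),
                      solver_config(t_end = 150, n_report = 301, engine = "R"))
  expect_lt(rel_diff(as.matrix(a[, 2:5]), as.matrix(r[, 2:5])), 1e-8)
})

test_that("adaptive and fixed-step integrators agree on the oscillatory run", {
  p <- model_params(beta0 = 0.8)  # transmission-ladder scenario, x = 0
  sl_a <- solver_config(t_end = 200, n_report = 201)
  sl_f <- solver_config(method = "rk4", dt_fixed = 1e-3, t_end = 200,
                        n_report = 201)
  a <- simulate_model(p, initial_state(), sl_a)
  f <- simulate_model(p, initial_state(), sl_f)
  expect_lt(rel_diff(as.numeric(a[201, 2:4]), as.numeric(f[201, 2:4])), 1e-5)
})

test_that("halving the tolerances barely moves the solution", {
  p <- model_params(beta0 = 0.8)
  a <- simulate_model(p, initial_state(), solver_config(t_end = 100))
  b <- simulate_model(p, initial_state(),
                      solver_config(t_end = 100, rel_tol = 5e-9, abs_tol = 5e-11))
  expect_lt(rel_diff(as.numeric(a[nrow(a), 2:4]), as.numeric(b[nrow(b), 2:4])),
            1e-6)
})

test_that("reported states always satisfy the state invariants", {
  for (b0 in c(0.5, 0.95)) {
    traj <- simulate_model(model_params(beta0 = b0, CS = 0.3, CP = 0.5,
                                        x_mode = "dynamic"),
                           initial_state(x = 0.5),
                           solver_config(t_end = 400, n_report = 401))
    expect_true(all(traj$S >= 0 & traj$I >= 0 & traj$P >= 0))
    expect_true(all(traj$x >= 0 & traj$x <= 1))
  }
})

test_that("a low transmission rate extinguishes the infection, not the host", {
  # below the invasion threshold beta*K/(a+K) = mu the infection dies out
  traj <- simulate_model(model_params(beta0 = 0.5),
                         solver = solver_config(t_end = 1500, n_report = 1501))
  ext <- detect_extinction(traj)
  expect_true(ext$extinct[ext$compartment == "I"])
  expect_false(ext$extinct[ext$compartment == "S"])
  expect_equal(traj$S[nrow(traj)], 1, tolerance = 1e-4)
})

test_that("a strong Allee effect starves the predator out", {
  traj <- simulate_model(model_params(beta0 = 0.95, theta = 0.3),
                         solver = solver_config(t_end = 2500, n_report = 2001))
  ext <- detect_extinction(traj)
  expect_true(ext$extinct[ext$compartment == "P"])
  expect_false(ext$extinct[ext$compartment == "I"])
  expect_false(ext$extinct[ext$compartment == "S"])
})

test_that("extinction detection flags a constant-zero trajectory at t = 0", {
  traj <- simulate_model(model_params(), initial_state(0, 0, 0, 0),
                         solver_config(t_end = 50, n_report = 51))
  ext <- detect_extinction(traj, eps = 1e-8)
  expect_true(all(ext$extinct))
  expect_true(all(ext$first_below == 0))
})

test_that("underflow absorption keeps a collapsing run integrable", {
  # the ratio payoff reading can push the infection to sub-denormal
  # densities; absorption to exact zero keeps lsoda healthy
  p <- model_params(beta0 = 0.95, CS = 0.05, CP = 0.5, e = 0.5,
                    x_mode = "dynamic", g_mode = "ratio")
  traj <- simulate_model(p, initial_state(x = 0.5),
                         solver_config(t_end = 5000, n_report = 1001))
  ev <- trajectory_events(traj)
  expect_true(any(ev$event == "absorbed"))
  ext <- detect_extinction(traj)
  expect_true(ext$extinct[ext$compartment == "I"])
})

test_that("a trajectory started at a stable equilibrium stays there", {
  p <- model_params(beta0 = 0.58)  # below the oscillatory threshold
  eqs <- find_equilibria(p, x = 0, n_grid = 6)
  co <- eqs[eqs$kind == "coexistence", ]
  expect_equal(nrow(co), 1)
  expect_match(co$label, "stable")
  st <- initial_state(co$S, co$I, co$P, 0)
  traj <- simulate_model(p, st, solver_config(t_end = 100, n_report = 201))
  drift <- max(abs(as.matrix(traj[, 2:4]) -
                     matrix(unname(st[1:3]), nrow(traj), 3, byrow = TRUE)))
  expect_lt(drift, 1e-6)
})

test_that("integration failures carry the failure time", {
  err <- tryCatch(ecoepidyn:::integration_error(12.5, "boom"),
                  error = function(e) e)
  expect_s3_class(
    tryCatch(stop(err), ecoepi_integration_error = function(e) e),
    "ecoepi_integration_error")
  expect_match(conditionMessage(err), "t = 12.5")
})
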