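test_that("transmission rate is linear in x and floored at zero", {
  p <- model_params(beta0 = 0.95, e = 1)
  expect_equal(transmission_rate(0, p), 0.95)
  expect_equal(transmission_rate(1, p), 0)
  expect_equal(transmission_rate(0.3, p), 0.665)
  # e = 0 or x = 0 leaves the baseline rate exactly
  expect_identical(transmission_rate(0.7, model_params(beta0 = 0.8, e = 0)), 0.8)
  expect_identical(transmission_rate(0, model_params(beta0 = 0.8)), 0.8)
  # e > 1 allows e*x > 1; the floor activates with a warning
  p2 <- suppressWarnings(model_params(beta0 = 0.95, e = 2))
  expect_warning(b <- transmission_rate(0.9, p2), "clamped")
  expect_identical(b, 0)
})

test_that("Allee factor satisfies the three mating-probability conditions", {
  expect_equal(allee_factor(0.5, 0.5), 0.5)     # P = theta gives 1/2
  expect_identical(allee_factor(3, 0), 1)       # Allee-free limit is exact
  expect_identical(allee_factor(0, 0.1), 0)     # no mating at zero density
  expect_identical(allee_factor(0, 0), 1)       # 0/0 convention (see docs)

  # monotone non-decreasing in P, non-increasing in theta, approaches 1
  P <- seq(0, 50, length.out = 200)
  for (theta in c(0.01, 0.1, 1, 5)) {
    f <- allee_factor(P, theta)
    expect_true(all(diff(f) >= 0))
    expect_true(all(f >= 0 & f <= 1))
    expect_gt(f[length(f)], 0.9)
  }
  for (Pv in c(0.05, 0.5, 2)) {
    f <- vapply(c(0.01, 0.1, 1, 5), function(th) allee_factor(Pv, th), 1)
    expect_true(all(diff(f) <= 0))
  }
})

test_that("replicator dynamics pin the boundary strategies", {
  p <- model_params(CS = 0.5, CP = 0.5, x_mode = "dynamic")
  for (i in 1:20) {
    st <- rand_state()
    st[["x"]] <- sample(c(0, 1), 1)
    expect_identical(strategy_rhs(st, p), 0)
  }
  # direct substitution into the literal payoff reading
  st <- initial_state(S = 1, I = 0, P = 0, x = 0.5)
  expect_equal(strategy_rhs(st, p), -0.125)
})

test_that("the three payoff readings are as documented", {
  st <- initial_state(S = 0.8, I = 0.2, P = 1.5, x = 0.5)
  g1 <- strategy_gain(st, model_params(CS = 0.3, CP = 0.6, x_mode = "dynamic"))
  expect_equal(g1, -0.3 * 0.8 + 0.2 + 0.6 * 1.5)
  g2 <- strategy_gain(st, model_params(CS = 0.3, CP = 0.6, g_mode = "pooled"))
  expect_equal(g2, -0.3 * 1.0 + 0.6 * 1.5)
  g3 <- strategy_gain(st, model_params(CS = 0.3, CP = 0.6, g_mode = "ratio"))
  expect_equal(g3, -0.3 / 1.0 + 0.6 * 1.5)
})

test_that("RHS vanishes at extinction and at the logistic carrying capacity", {
  p <- model_params(r = 1, b = 1)
  expect_equal(unname(ode_rhs(initial_state(0, 0, 0, 0), p)), rep(0, 4))
  d <- ode_rhs(initial_state(S = 1, I = 0, P = 0, x = 0), p)
  expect_equal(unname(d), rep(0, 4))
})

test_that("RHS matches the independently evaluated fixture", {
  # each bracket evaluated separately by hand and frozen
  p <- model_params(beta0 = 0.5, theta = 0)
  d <- ode_rhs(initial_state(0.99, 0.01, 0.01, 0), p)
  expect_equal(d[["S"]], 0.0061378937367769842, tolerance = 1e-14)
  expect_equal(d[["I"]], -0.00035288902795160615, tolerance = 1e-14)
  expect_equal(d[["P"]], -7.7813339219365049e-05, tolerance = 1e-14)
  expect_identical(d[["x"]], 0)
})

test_that("RHS rejects non-finite input, naming the component", {
  p <- model_params()
  st <- c(S = 0.5, I = NaN, P = 0.1, x = 0)
  expect_error(ode_rhs(st, p), "I")
})

test_that("coordinate faces are invariant under the flow", {
  set.seed(101)
  for (i in 1:50) {
    p <- rand_params(x_mode = sample(c("fixed", "dynamic"), 1))
    st <- rand_state()
    st0 <- st; st0[["S"]] <- 0
    expect_identical(ode_rhs(st0, p)[["S"]], 0)
    st0 <- st; st0[["I"]] <- 0
    expect_identical(ode_rhs(st0, p)[["I"]], 0)
    st0 <- st; st0[["P"]] <- 0
    expect_identical(ode_rhs(st0, p)[["P"]], 0)
    st0 <- st; st0[["x"]] <- 1
    expect_identical(ode_rhs(st0, p)[["x"]], 0)
  }
})

test_that("theta = 0 reduces the predator equation to the classical form", {
  set.seed(102)
  for (i in 1:20) {
    p <- rand_params()
    st <- rand_state()
    dP <- ode_rhs(st, p)[["P"]]
    classical <- with(p, (c1 * alpha1 * st[["S"]] / (sigma + st[["S"]]) +
                            c2 * alpha2 * st[["I"]] / (d + st[["I"]]) - m)) *
      st[["P"]]
    expect_identical(dP, unname(classical))
  }
})

test_that("RHS agrees with an independent re-derivation on random states", {
  set.seed(103)
  for (i in 1:1000) {
    p <- rand_params(x_mode = if (i %% 2) "fixed" else "dynamic")
    st <- rand_state()
    expect_lt(rel_diff(ode_rhs(st, p), rhs_indep(st, p)), 1e-12)
  }
})
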