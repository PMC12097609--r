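test_that("eigenvalue classification follows the labelling contract", {
  expect_identical(classify_equilibrium(c(-1, -2, -3)), "stable_node")
  expect_identical(classify_equilibrium(c(-0.1 + 2i, -0.1 - 2i, -1)),
                   "stable_focus")
  expect_identical(classify_equilibrium(c(0.05 + 1i, 0.05 - 1i, -1)), "saddle")
  expect_identical(classify_equilibrium(c(0.2, 0.3, 0.1)), "unstable")
  expect_identical(classify_equilibrium(c(1e-9, -1, -2)), "non_hyperbolic")
})

test_that("the closed-form equilibria are always found", {
  eqs <- find_equilibria(model_params(beta0 = 0.8), x = 0, n_grid = 6)
  expect_true(any(eqs$S == 0 & eqs$I == 0 & eqs$P == 0))
  expect_true(any(abs(eqs$S - 1) < 1e-8 & eqs$I == 0 & eqs$P == 0))
  expect_true(all(eqs$residual <= 1e-10))
})

test_that("coexistence stability flips with the transmission rate", {
  # high transmission: unstable coexistence (oscillatory regime)
  hi <- find_equilibria(model_params(beta0 = 0.95), x = 0, n_grid = 6)
  co_hi <- hi[hi$kind == "coexistence", ]
  expect_equal(nrow(co_hi), 1)
  expect_gt(co_hi$max_re, 0)

  # just below the linear threshold: a (weakly) stable focus
  lo <- find_equilibria(model_params(beta0 = 0.58), x = 0, n_grid = 6)
  co_lo <- lo[lo$kind == "coexistence", ]
  expect_equal(nrow(co_lo), 1)
  expect_identical(co_lo$label, "stable_focus")

  # below the infection invasion threshold no coexistence exists
  none <- find_equilibria(model_params(beta0 = 0.5), x = 0, n_grid = 6)
  expect_identical(sum(none$kind == "coexistence"), 0L)
})

test_that("the equilibrium set is stable under grid refinement", {
  p <- model_params(beta0 = 0.95)
  a <- find_equilibria(p, x = 0, n_grid = 6)
  b <- find_equilibria(p, x = 0, n_grid = 12)
  key <- function(e) {
    m <- round(as.matrix(e[, c("S", "I", "P")]), 6)
    sort(apply(m, 1, paste, collapse = ","))
  }
  expect_identical(key(a), key(b))
})

test_that("full-mode search returns the strategy boundary equilibria", {
  p <- model_params(beta0 = 0.95, CS = 0.5, CP = 0.5, x_mode = "dynamic")
  eqs <- find_equilibria(p, mode = "full", n_grid = 5)
  expect_true(all(eqs$x >= 0 & eqs$x <= 1))
  expect_true(any(eqs$x == 0) && any(eqs$x == 1))
  expect_true(all(eqs$residual <= 1e-10))
  expect_true(all(vapply(eqs$eigenvalues, length, 1L) == 4))
})

test_that("stability labels agree with perturbed simulations", {
  set.seed(107)
  p <- model_params(beta0 = 0.95)
  n_ok <- 0
  for (i in 1:8) {
    pj <- rand_params(jitter = 0.05)
    eqs <- find_equilibria(pj, x = 0, n_grid = 6)
    co <- eqs[eqs$kind == "coexistence" & abs(eqs$max_re) > 1e-3, ]
    if (nrow(co) == 0) next
    st <- initial_state(co$S[1], co$I[1], co$P[1], 0)
    st[1:3] <- st[1:3] + 1e-3
    traj <- simulate_model(pj, st, solver_config(t_end = 500, n_report = 501))
    dev <- max(abs(as.numeric(traj[nrow(traj), 2:4]) -
                     as.numeric(co[1, c("S", "I", "P")])))
    if (grepl("stable", co$label[1])) {
      expect_lt(dev, 1.8e-3)  # contraction of the perturbation
    } else {
      expect_gt(dev, 1e-2)    # divergence from the unstable equilibrium
    }
    n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 4)
})
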