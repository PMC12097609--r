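# Shared fixtures: random draws and an independently re-derived RHS.

# Random feasible state (densities up to ~carrying capacity scale).
rand_state <- function() {
  initial_state(S = runif(1, 0, 1.2), I = runif(1, 0, 1.2),
                P = runif(1, 0, 4), x = runif(1))
}

# Multiplicative jitter around the caption base parameter set.
rand_params <- function(jitter = 0.1, x_mode = "fixed") {
  j <- function(v) v * runif(1, 1 - jitter, 1 + jitter)
  model_params(r = j(1), b = j(1), c = j(0.01), beta0 = j(0.95), e = 1,
               a = j(0.3636), alpha1 = j(0.01), alpha2 = j(0.05),
               sigma = j(15), d = j(0.5), c1 = j(2), c2 = j(1),
               mu = j(0.4), m = j(0.01), theta = 0,
               CS = runif(1), CP = runif(1), x_mode = x_mode)
}

# Independent re-derivation of the RHS with a different algebraic
# arrangement (terms over common denominators), used as an oracle.
rhs_indep <- function(state, pars) {
  S <- state[["S"]]; I <- state[["I"]]; P <- state[["P"]]; x <- state[["x"]]
  with(pars, {
    bx <- max(beta0 * (1 - e * x), 0)
    phi <- if (theta == 0) 1 else P / (theta + P)
    dS <- S * ((r - b * S - c * I) * (a + S) * (sigma + S) -
                 bx * I * (sigma + S) - alpha1 * P * (a + S)) /
      ((a + S) * (sigma + S))
    dI <- I * ((bx * S - mu * (a + S)) * (d + I) -
                 alpha2 * P * (a + S)) / ((a + S) * (d + I))
    dP <- P * ((c1 * alpha1 * S * (d + I) + c2 * alpha2 * I * (sigma + S)) *
                 phi - m * (sigma + S) * (d + I)) /
      ((sigma + S) * (d + I))
    G <- switch(g_mode,
                literal = -CS * S + I + CP * P,
                pooled = -CS * (S + I) + CP * P,
                ratio = if (S + I > 1e-12) -CS / (S + I) + CP * P else CP * P)
    dx <- if (x_mode == "dynamic") x * (1 - x) * G else 0
    c(S = dS, I = dI, P = dP, x = dx)
  })
}

rel_diff <- function(a, b) {
  max(abs(a - b) / pmax(abs(a), abs(b), 1e-8))
}
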