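# Analytic Jacobian of the model right-hand side.

#' Analytic Jacobian of the model RHS
#'
#' Exact partial derivatives of [ode_rhs()] with respect to the state.
#' Returns a 3x3 matrix over `(S, I, P)` when the strategy is fixed and a
#' 4x4 matrix including `x` when it is dynamic (overridable via `mode`).
#' The transmission-rate floor is handled piecewise: where
#' `beta0 (1 - e x) <= 0` the derivative of `beta` with respect to `x`
#' is 0.
#'
#' @param state State vector from [initial_state()].
#' @param pars An [model_params()] object.
#' @param mode `"auto"` (follow `pars$x_mode`), `"fixed"` (3x3) or
#'   `"dynamic"` (4x4).
#' @return A numeric matrix with dimnames over the state components.
#' @export
jacobian_matrix <- function(state, pars, mode = c("auto", "fixed", "dynamic")) {
  stopifnot(inherits(pars, "ecoepi_params"))
  mode <- match.arg(mode)
  if (mode == "auto") mode <- pars$x_mode
  if (is.null(names(state))) names(state) <- c("S", "I", "P", "x")
  S <- state[["S"]]; I <- state[["I"]]; P <- state[["P"]]; x <- state[["x"]]

  aS <- pars$a + S; sS <- pars$sigma + S; dI <- pars$d + I
  if (aS == 0 || sS == 0 || dI == 0 || (pars$theta + P) == 0 && pars$theta > 0) {
    stop("vanishing denominator in Jacobian evaluation", call. = FALSE)
  }
  beta_raw <- pars$beta0 * (1 - pars$e * x)
  beta <- max(beta_raw, 0)
  dbeta_dx <- if (beta_raw > 0) -pars$beta0 * pars$e else 0

  theta <- pars$theta
  phi <- if (theta == 0) 1 else P / (theta + P)
  dphi_dP <- if (theta == 0) 0 else theta / (theta + P)^2

  A <- pars$r - pars$b * S - pars$c * I - beta * I / aS - pars$alpha1 * P / sS
  B <- beta * S / aS - pars$alpha2 * P / dI - pars$mu
  W <- pars$c1 * pars$alpha1 * S / sS + pars$c2 * pars$alpha2 * I / dI
  Cc <- W * phi - pars$m

  J <- matrix(0, 4, 4, dimnames = list(c("S", "I", "P", "x"),
                                       c("S", "I", "P", "x")))
  # dS/dt = A * S
  J["S", "S"] <- A + S * (-pars$b + beta * I / aS^2 + pars$alpha1 * P / sS^2)
  J["S", "I"] <- S * (-pars$c - beta / aS)
  J["S", "P"] <- S * (-pars$alpha1 / sS)
  J["S", "x"] <- S * (-dbeta_dx * I / aS)
  # dI/dt = B * I
  J["I", "S"] <- I * beta * pars$a / aS^2
  J["I", "I"] <- B + I * (pars$alpha2 * P / dI^2)
  J["I", "P"] <- I * (-pars$alpha2 / dI)
  J["I", "x"] <- I * S / aS * dbeta_dx
  # dP/dt = (W * phi - m) * P
  J["P", "S"] <- P * phi * pars$c1 * pars$alpha1 * pars$sigma / sS^2
  J["P", "I"] <- P * phi * pars$c2 * pars$alpha2 * pars$d / dI^2
  J["P", "P"] <- Cc + P * W * dphi_dP

  if (mode == "dynamic") {
    G <- strategy_gain(state, pars)
    xf <- x * (1 - x)
    dG <- switch(pars$g_mode,
      literal = c(-pars$CS, 1, pars$CP),
      pooled  = c(-pars$CS, -pars$CS, pars$CP),
      ratio   = if (S + I > 1e-12) {
        c(pars$CS / (S + I)^2, pars$CS / (S + I)^2, pars$CP)
      } else c(0, 0, pars$CP)
    )
    J["x", c("S", "I", "P")] <- xf * dG
    J["x", "x"] <- (1 - 2 * x) * G
    J
  } else {
    J[1:3, 1:3]
  }
}
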