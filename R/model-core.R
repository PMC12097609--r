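# The model right-hand side and its building blocks (pure functions).

#' Strategy-dependent transmission rate
#'
#' `beta(x) = beta0 (1 - e x)`, floored at 0: a negative transmission rate
#' is biologically meaningless and can only arise for `e * x > 1`, which
#' the recommended range `e` in `[0,1]` excludes. A warning is emitted
#' whenever the floor activates.
#'
#' @param x Cooperation level in `[0, 1]` (vectorised).
#' @param pars An [model_params()] object (fields `beta0`, `e` are used).
#' @return Non-negative transmission rate(s).
#' @examples
#' p <- model_params(beta0 = 0.95, e = 1)
#' transmission_rate(c(0, 0.3, 1), p)
#' @export
transmission_rate <- function(x, pars) {
  stopifnot(inherits(pars, "ecoepi_params"))
  beta <- pars$beta0 * (1 - pars$e * x)
  if (any(beta < 0)) {
    warning("beta(x) clamped at 0 (e * x > 1)", call. = FALSE)
    beta <- pmax(beta, 0)
  }
  beta
}

#' Weak Allee (mate-finding) factor
#'
#' `P/(theta + P)`: the probability that a predator finds a mate at density
#' `P`. It is 0 at zero density, increases with `P`, and approaches 1 at
#' large densities. `theta = 0` returns exactly 1 (the Allee-free limit)
#' for any `P > 0`; the joint degenerate case `P = 0, theta = 0` also
#' returns 1 by convention -- the factor only ever multiplies a term that
#' already carries a factor of `P`, so any finite convention yields the
#' correct product 0, and 1 preserves continuity of the `theta -> 0` limit.
#'
#' @param P Predator density, `>= 0` (vectorised).
#' @param theta Allee parameter, `>= 0`.
#' @return Factor(s) in `[0, 1]`.
#' @examples
#' allee_factor(0.5, 0.5)  # P = theta gives 1/2
#' allee_factor(3, 0)      # Allee-free limit
#' @export
allee_factor <- function(P, theta) {
  stopifnot(all(P >= 0), length(theta) == 1, theta >= 0)
  if (theta == 0) return(rep(1, length(P)))
  P / (theta + P)
}

#' Replicator payoff gain G(S, I, P)
#'
#' The net payoff gain of cooperating, entering the replicator equation
#' `dx/dt = x (1 - x) G`. The printed form of the source model is
#' ambiguous, so the reading is isolated here and switched by
#' `pars$g_mode`:
#' * `"literal"` (default): `G = -CS*S + I + CP*P` -- cooperation is
#'   discouraged in proportion to the susceptible pool (its cost scales
#'   with `CS*S`) and encouraged by infection pressure `I` and predation
#'   pressure `CP*P`;
#' * `"pooled"`: `G = -CS*(S+I) + CP*P`;
#' * `"ratio"`: `G = -CS/(S+I) + CP*P` (guarded near `S + I = 0`).
#'
#' @param state State vector from [initial_state()].
#' @param pars An [model_params()] object.
#' @return Scalar payoff gain.
#' @export
strategy_gain <- function(state, pars) {
  S <- state[["S"]]; I <- state[["I"]]; P <- state[["P"]]
  switch(pars$g_mode,
    literal = -pars$CS * S + I + pars$CP * P,
    pooled  = -pars$CS * (S + I) + pars$CP * P,
    ratio   = if (S + I > 1e-12) -pars$CS / (S + I) + pars$CP * P
              else pars$CP * P
  )
}

#' Replicator dynamics of the cooperation level
#'
#' `dx/dt = x (1 - x) G(S, I, P)`. The factor `x (1 - x)` pins both
#' boundary strategies: the derivative is exactly 0 at `x = 0` and
#' `x = 1`, so `[0, 1]` is invariant.
#'
#' @inheritParams strategy_gain
#' @return Scalar `dx/dt`.
#' @export
strategy_rhs <- function(state, pars) {
  x <- state[["x"]]
  x * (1 - x) * strategy_gain(state, pars)
}

#' Model right-hand side
#'
#' Time derivatives of the full system:
#' \deqn{dS/dt = [r - bS - cI - \beta(x) I/(a+S) - \alpha_1 P/(\sigma+S)]\,S}
#' \deqn{dI/dt = [\beta(x) S/(a+S) - \alpha_2 P/(d+I) - \mu]\,I}
#' \deqn{dP/dt = [(c_1\alpha_1 S/(\sigma+S) + c_2\alpha_2 I/(d+I))\,
#'   P/(\theta+P) - m]\,P}
#' with `dx/dt` given by [strategy_rhs()] when `x_mode = "dynamic"` and 0
#' otherwise. Every bracket carries its own population factor, so each
#' coordinate face (`S = 0`, `I = 0`, `P = 0`, `x` in `{0, 1}`) is
#' invariant under the flow.
#'
#' This R implementation is the reference; [simulate_model()] uses an
#' identical compiled version by default, and the two are tested to agree
#' to machine precision.
#'
#' @param state State vector from [initial_state()] (finite; non-finite
#'   components raise an error naming the offending component).
#' @param pars An [model_params()] object.
#' @return Named derivative vector `c(S=, I=, P=, x=)`.
#' @examples
#' p <- model_params(beta0 = 0.5)
#' ode_rhs(initial_state(), p)
#' @export
ode_rhs <- function(state, pars) {
  stopifnot(inherits(pars, "ecoepi_params"))
  if (is.null(names(state))) names(state) <- c("S", "I", "P", "x")
  bad <- !is.finite(state)
  if (any(bad)) {
    stop("non-finite state component: ",
         paste(names(state)[bad], collapse = ", "), call. = FALSE)
  }
  S <- state[["S"]]; I <- state[["I"]]; P <- state[["P"]]; x <- state[["x"]]
  beta <- max(pars$beta0 * (1 - pars$e * x), 0)
  phi <- if (pars$theta == 0) 1 else P / (pars$theta + P)
  dS <- (pars$r - pars$b * S - pars$c * I - beta * I / (pars$a + S) -
           pars$alpha1 * P / (pars$sigma + S)) * S
  dI <- (beta * S / (pars$a + S) - pars$alpha2 * P / (pars$d + I) -
           pars$mu) * I
  dP <- ((pars$c1 * pars$alpha1 * S / (pars$sigma + S) +
            pars$c2 * pars$alpha2 * I / (pars$d + I)) * phi - pars$m) * P
  dx <- if (pars$x_mode == "dynamic") strategy_rhs(state, pars) else 0
  c(S = dS, I = dI, P = dP, x = dx)
}
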