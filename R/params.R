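# Parameter container and validation.

# Order of the numeric parameters passed to the compiled RHS; must match
# the #define block in src/ecoepidyn.c.
.ecoepi_par_order <- c(
  "r", "b", "c", "beta0", "e", "a", "alpha1", "alpha2", "sigma", "d",
  "c1", "c2", "mu", "m", "theta", "CS", "CP"
)

.g_modes <- c(literal = 1, pooled = 2, ratio = 3)

#' Model parameters
#'
#' Construct the full parameter set of the eco-epidemiological model:
#' susceptible prey `S` with logistic growth, infected prey `I` recruited by
#' saturated-incidence transmission, a predator `P` taking both prey classes
#' through Holling type-II responses and subject to a weak Allee
#' (mate-finding) factor `P/(theta+P)`, and a cooperation level `x` in
#' `[0,1]` that scales transmission down via `beta(x) = beta0 (1 - e x)`.
#'
#' Defaults are the caption parameter set used by every scenario preset
#' (see [list_presets()]), with `beta0 = 0.95` and the behavioural-cost
#' coefficients at `0.5`.
#'
#' @param r Susceptible prey intrinsic growth rate (per unit time).
#' @param b Intra-class competition coefficient of susceptible prey.
#' @param c Inter-class effect of infected on susceptible prey.
#' @param beta0 Baseline disease transmission rate.
#' @param e Cooperator proportionality constant in `[0,1]`; values above 1
#'   are accepted with a warning (the transmission rate is floored at 0).
#' @param a Half-saturation constant of the saturated incidence term.
#' @param alpha1,alpha2 Predator attack rates on susceptible and infected
#'   prey.
#' @param sigma,d Predator half-saturation constants for susceptible and
#'   infected prey (strictly positive; they appear in denominators).
#' @param c1,c2 Transfer efficacies (conversion of consumed susceptible and
#'   infected prey into predator growth).
#' @param mu Infected prey death rate.
#' @param m Predator natural death rate.
#' @param theta Allee parameter (`>= 0`); `theta = 0` recovers the
#'   Allee-free model exactly.
#' @param CS,CP Controlling costs of susceptible prey and predator in
#'   `[0,1]`, entering the replicator payoff gain.
#' @param x_mode `"fixed"` holds the strategy constant at its initial value
#'   (`dx/dt = 0`); `"dynamic"` evolves it by replicator dynamics.
#' @param g_mode Reading of the replicator payoff gain `G(S,I,P)`:
#'   `"literal"` (default) is `-CS*S + I + CP*P`; `"pooled"` is
#'   `-CS*(S+I) + CP*P`; `"ratio"` is `-CS/(S+I) + CP*P`. See
#'   [strategy_gain()].
#'
#' @return An object of class `ecoepi_params` (a validated named list).
#' @examples
#' pars <- model_params(beta0 = 0.5)
#' update_params(pars, theta = 0.3)
#' @export
model_params <- function(r = 1.0, b = 1.0, c = 0.01, beta0 = 0.95, e = 1.0,
                         a = 0.3636, alpha1 = 0.01, alpha2 = 0.05,
                         sigma = 15, d = 0.5, c1 = 2, c2 = 1.0,
                         mu = 0.4, m = 0.01, theta = 0,
                         CS = 0.5, CP = 0.5,
                         x_mode = c("fixed", "dynamic"),
                         g_mode = c("literal", "pooled", "ratio")) {
  x_mode <- match.arg(x_mode)
  g_mode <- match.arg(g_mode)
  pars <- list(
    r = r, b = b, c = c, beta0 = beta0, e = e, a = a,
    alpha1 = alpha1, alpha2 = alpha2, sigma = sigma, d = d,
    c1 = c1, c2 = c2, mu = mu, m = m, theta = theta, CS = CS, CP = CP,
    x_mode = x_mode, g_mode = g_mode
  )
  class(pars) <- "ecoepi_params"
  validate_params(pars)
}

#' Modify an existing parameter set
#'
#' @param pars An `ecoepi_params` object.
#' @param ... Named fields to replace (any argument of [model_params()]).
#' @return A new, re-validated `ecoepi_params` object.
#' @export
update_params <- function(pars, ...) {
  stopifnot(inherits(pars, "ecoepi_params"))
  new <- list(...)
  if (length(new) == 0) return(pars)
  bad <- setdiff(names(new), names(pars))
  if (length(bad) > 0) {
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pars[names(new)] <- new
  validate_params(pars)
}

validate_params <- function(pars) {
  num <- .ecoepi_par_order
  for (nm in num) {
    v <- pars[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  for (nm in c("a", "sigma", "d")) {
    if (pars[[nm]] <= 0) {
      stop("half-saturation constant '", nm,
           "' must be strictly positive (it appears in a denominator)",
           call. = FALSE)
    }
  }
  for (nm in setdiff(num, c("a", "sigma", "d"))) {
    if (pars[[nm]] < 0) {
      stop("parameter '", nm, "' must be non-negative", call. = FALSE)
    }
  }
  if (pars$e > 1) {
    warning("e > 1: beta(x) can reach its floor at 0 for large x",
            call. = FALSE)
  }
  for (nm in c("CS", "CP")) {
    if (pars[[nm]] > 1) {
      warning("'", nm, "' exceeds 1; the model treats controlling costs as ",
              "scaled to [0,1]", call. = FALSE)
    }
  }
  if (!pars$x_mode %in% c("fixed", "dynamic")) {
    stop("x_mode must be 'fixed' or 'dynamic'", call. = FALSE)
  }
  if (!pars$g_mode %in% names(.g_modes)) {
    stop("g_mode must be one of ", paste(names(.g_modes), collapse = ", "),
         call. = FALSE)
  }
  pars
}

# Numeric vector handed to the compiled RHS.
params_vector <- function(pars) {
  stopifnot(inherits(pars, "ecoepi_params"))
  c(unlist(pars[.ecoepi_par_order]),
    xdyn = as.numeric(pars$x_mode == "dynamic"),
    gmode = as.numeric(.g_modes[[pars$g_mode]]))
}

#' @export
print.ecoepi_params <- function(x, ...) {
  cat("<ecoepi_params>  x_mode:", x$x_mode, " g_mode:", x$g_mode, "\n")
  v <- unlist(x[.ecoepi_par_order])
  print(v)
  invisible(x)
}

#' @export
as_tibble.ecoepi_params <- function(x, ...) {
  tibble::as_tibble(c(x[.ecoepi_par_order],
                      list(x_mode = x$x_mode, g_mode = x$g_mode)))
}

#' System state vector
#'
#' Build the instantaneous state `(S, I, P, x)`: susceptible prey, infected
#' prey, predator (all non-negative densities) and the cooperation level
#' `x` in `[0,1]`. The default is the initial condition used by every
#' scenario preset, `(0.99, 0.01, 0.01)`, with `x = 0` (no cooperation);
#' dynamic-strategy presets start from the uninformative interior point
#' `x = 0.5`.
#'
#' @param S,I,P Population densities, `>= 0`.
#' @param x Cooperation level in `[0, 1]`.
#' @return A named numeric vector `c(S=, I=, P=, x=)`.
#' @export
initial_state <- function(S = 0.99, I = 0.01, P = 0.01, x = 0) {
  st <- c(S = S, I = I, P = P, x = x)
  validate_state(st)
}

validate_state <- function(state) {
  if (!is.numeric(state) || length(state) != 4) {
    stop("state must be a numeric vector (S, I, P, x)", call. = FALSE)
  }
  if (is.null(names(state)) || !identical(names(state), c("S", "I", "P", "x"))) {
    names(state) <- c("S", "I", "P", "x")
  }
  bad <- !is.finite(state)
  if (any(bad)) {
    stop("non-finite state component: ", paste(names(state)[bad], collapse = ", "),
         call. = FALSE)
  }
  if (any(state[c("S", "I", "P")] < 0)) {
    stop("population densities S, I, P must be non-negative", call. = FALSE)
  }
  if (state[["x"]] < 0 || state[["x"]] > 1) {
    stop("cooperation level x must lie in [0, 1]", call. = FALSE)
  }
  state
}
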