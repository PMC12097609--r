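# Equilibria of the (S, I, P) subsystem and the full 4-D system:
# closed forms, damped-Newton multi-start, eigenvalue classification.

#' Classify an equilibrium from its eigenvalues
#'
#' Standard linear (hyperbolic) classification with a hyperbolicity band:
#' eigenvalues whose real part lies within `tol` of 0 make the equilibrium
#' `non_hyperbolic` rather than forcing a guess -- bifurcation scans probe
#' exactly these boundaries.
#'
#' * all `Re < -tol`: `stable_node` (all real) or `stable_focus`
#'   (a complex pair);
#' * all `Re > tol`: `unstable`;
#' * mixed signs: `saddle`.
#'
#' @param eigenvalues Complex (or numeric) eigenvalue vector.
#' @param tol Hyperbolicity band (default `1e-7`).
#' @return A single string label.
#' @examples
#' classify_equilibrium(c(-1, -2, -3))
#' classify_equilibrium(c(-0.1 + 2i, -0.1 - 2i, -1))
#' classify_equilibrium(c(0.05 + 1i, 0.05 - 1i, -1))
#' @export
classify_equilibrium <- function(eigenvalues, tol = 1e-7) {
  re <- Re(eigenvalues)
  if (any(abs(re) <= tol)) return("non_hyperbolic")
  if (all(re < 0)) {
    if (any(abs(Im(eigenvalues)) > 0)) "stable_focus" else "stable_node"
  } else if (all(re > 0)) {
    "unstable"
  } else {
    "saddle"
  }
}

# Damped Newton on f = ode_rhs (3-D with x frozen, or 4-D) from one seed.
# Returns the root or NULL.
.newton_root <- function(y0, pars, dim, x_fixed = 0,
                         max_iter = 80, f_tol = 1e-12) {
  fy <- function(y) {
    st <- if (dim == 3) c(y, x_fixed) else y
    names(st) <- c("S", "I", "P", "x")
    unname(ode_rhs(st, pars))[seq_len(dim)]
  }
  Jy <- function(y) {
    st <- if (dim == 3) c(y, x_fixed) else y
    names(st) <- c("S", "I", "P", "x")
    jacobian_matrix(st, pars, mode = if (dim == 3) "fixed" else "dynamic")
  }
  y <- y0
  f <- fy(y)
  for (i in seq_len(max_iter)) {
    if (max(abs(f)) < f_tol) break
    J <- Jy(y)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lam <- 1
    repeat {
      yn <- y + lam * step
      # keep Newton out of regions where the RHS is undefined
      if (dim == 4) yn[4] <- min(max(yn[4], -0.25), 1.25)
      fn <- tryCatch(fy(yn), error = function(e) NULL)
      if (!is.null(fn) && all(is.finite(fn)) &&
          (max(abs(fn)) < max(abs(f)) || lam < 1e-8)) break
      lam <- lam / 2
    }
    y <- yn; f <- fn
  }
  if (max(abs(f)) < 1e-10 && all(is.finite(y))) y else NULL
}

#' Locate equilibria
#'
#' Finds the equilibria of the `(S, I, P)` subsystem (strategy frozen at
#' `x`) or of the full 4-D system: the trivial equilibrium, the axial
#' closed forms (e.g. `(r/b, 0, 0)`), and any interior or face equilibria
#' reached by damped Newton iteration from a deterministic multi-start
#' grid over `[0, r/b]^3` (`r/b` is the disease-free, predator-free
#' carrying capacity -- a natural a-priori seed box, not a claimed
#' invariant of the flow). In full mode the grid is repeated on the
#' `x = 0` and `x = 1` faces and at interior strategy seeds.
#' Duplicates are merged at distance `1e-6`; equilibria with negative
#' components are discarded; every returned equilibrium satisfies
#' `max |ode_rhs| <= 1e-10`.
#'
#' @param pars An [model_params()] object.
#' @param mode `"fixed"` (3-D subsystem, default when `pars$x_mode` is
#'   `"fixed"`) or `"full"`.
#' @param x Frozen strategy value for `"fixed"` mode.
#' @param n_grid Seeds per axis of the multi-start grid.
#' @return A tibble of class `ecoepi_eq_set`: columns `S, I, P, x, kind`
#'   (`trivial`, `axial`, `coexistence`, `boundary-x`), `label` (from
#'   [classify_equilibrium()]), `max_re`, `residual`, and a list-column
#'   `eigenvalues`. An empty interior set is a valid result.
#' @examples
#' eqs <- find_equilibria(model_params(beta0 = 0.8), x = 0, n_grid = 6)
#' eqs[, c("S", "I", "P", "kind", "label")]
#' @export
find_equilibria <- function(pars,
                            mode = if (pars$x_mode == "dynamic") "full" else "fixed",
                            x = 0, n_grid = 10) {
  stopifnot(inherits(pars, "ecoepi_params"))
  mode <- match.arg(mode, c("fixed", "full"))
  K <- pars$r / pars$b
  ax <- seq(0, K, length.out = n_grid)
  seeds3 <- as.matrix(expand.grid(S = ax, I = ax, P = ax))
  # exact closed forms as seeds too
  seeds3 <- rbind(seeds3, c(0, 0, 0), c(K, 0, 0))

  roots <- list()
  add_root <- function(y, xv) {
    y[abs(y) < 1e-12] <- 0
    if (any(y[1:3] < -1e-9)) return(invisible())
    y[1:3] <- pmax(y[1:3], 0)
    key <- c(y[1:3], xv)
    for (r in roots) if (max(abs(r - key)) < 1e-6) return(invisible())
    roots[[length(roots) + 1L]] <<- key
  }

  if (mode == "fixed") {
    for (i in seq_len(nrow(seeds3))) {
      y <- .newton_root(seeds3[i, ], pars, dim = 3, x_fixed = x)
      if (!is.null(y)) add_root(y, x)
    }
  } else {
    for (xv in c(0, 1)) {
      for (i in seq_len(nrow(seeds3))) {
        y <- .newton_root(seeds3[i, ], pars, dim = 3, x_fixed = xv)
        if (!is.null(y)) add_root(y, xv)
      }
    }
    for (xv in c(0.25, 0.5, 0.75)) {
      for (i in seq_len(nrow(seeds3))) {
        y <- .newton_root(c(seeds3[i, ], xv), pars, dim = 4)
        if (!is.null(y) && y[4] > 1e-9 && y[4] < 1 - 1e-9) {
          add_root(y[1:3], y[4])
        }
      }
    }
  }

  rows <- purrr::map_dfr(roots, function(st) {
    names(st) <- c("S", "I", "P", "x")
    jmode <- if (mode == "fixed") "fixed" else "dynamic"
    ev <- eigen(jacobian_matrix(st, pars, mode = jmode),
                only.values = TRUE)$values
    res <- max(abs(unname(ode_rhs(st, update_params(
      pars, x_mode = if (mode == "fixed") "fixed" else "dynamic"
    )))[if (mode == "fixed") 1:3 else 1:4]))
    kind <- if (all(st[1:3] == 0)) {
      "trivial"
    } else if (all(st[1:3] > 0)) {
      if (mode == "full" && (st[["x"]] == 0 || st[["x"]] == 1)) {
        "boundary-x"
      } else "coexistence"
    } else "axial"
    tibble::tibble(S = st[["S"]], I = st[["I"]], P = st[["P"]],
                   x = st[["x"]], kind = kind,
                   label = classify_equilibrium(ev),
                   max_re = max(Re(ev)), residual = res,
                   eigenvalues = list(ev))
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(S = numeric(), I = numeric(), P = numeric(),
                           x = numeric(), kind = character(),
                           label = character(), max_re = numeric(),
                           residual = numeric(), eigenvalues = list())
  }
  rows <- dplyr::arrange(rows, dplyr::desc(.data$kind == "coexistence"),
                         .data$S, .data$I, .data$P)
  attr(rows, "params") <- pars
  attr(rows, "mode") <- mode
  class(rows) <- c("ecoepi_eq_set", class(rows))
  rows
}

# Closed-form predator-free endemic equilibrium (S*, I*, 0) of the 3-D
# subsystem at frozen strategy x, or the disease-free state (r/b, 0, 0)
# when the infection cannot invade. Used by invasion_threshold().
predator_free_equilibrium <- function(pars, x = 0) {
  beta <- max(pars$beta0 * (1 - pars$e * x), 0)
  K <- pars$r / pars$b
  if (beta > pars$mu) {
    S <- pars$mu * pars$a / (beta - pars$mu)   # beta S/(a+S) = mu
    if (S < K) {
      I <- (pars$r - pars$b * S) / (pars$c + beta / (pars$a + S))
      if (I > 0) return(c(S = S, I = I, P = 0, x = x))
    }
  }
  c(S = K, I = 0, P = 0, x = x)
}
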