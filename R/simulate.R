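# Time integration of the model, non-negativity enforcement, extinction
# detection.

#' Solver configuration
#'
#' Controls for [simulate_model()] and the downstream attractor analysis.
#' The report grid is always uniform (`n_report` points on `[0, t_end]`)
#' regardless of the solver's internal steps, because peak detection in the
#' bifurcation module needs even sampling.
#'
#' @param method `"adaptive"` (lsoda, the default) or `"rk4"` (classical
#'   fixed-step Runge-Kutta with internal step `dt_fixed`).
#' @param rel_tol,abs_tol Relative and absolute tolerances of the adaptive
#'   solver.
#' @param dt_fixed Internal step of the fixed-step method (time units).
#' @param t_end Final time (time units).
#' @param n_report Number of equally spaced output points (`>= 2`).
#' @param transient Time discarded before attractor analysis; defaults to
#'   `t_end / 2`.
#' @param extinction_eps Density below which a compartment is declared
#'   extinct by [detect_extinction()].
#' @param clamp_negative If `TRUE` (default), components that dip below 0
#'   between integration segments are clamped to 0 (an event is logged when
#'   the excursion exceeds `abs_tol`), `x` is clamped into `[0,1]`, and
#'   components that underflow below `absorb_floor` are absorbed to exactly
#'   0 so the solver is not dragged through meaningless sub-denormal decay.
#' @param absorb_floor Absorption threshold (see above); far below
#'   `extinction_eps`, so it cannot affect extinction calls.
#' @param chunk_t Length of the integration segments between which clamping
#'   is applied.
#' @param engine `"compiled"` (default) uses the C implementation of the
#'   RHS; `"R"` uses [ode_rhs()]. Both give the same trajectories to
#'   solver accuracy and are tested for exact RHS agreement.
#' @return An object of class `ecoepi_solver` (a validated list).
#' @export
solver_config <- function(method = c("adaptive", "rk4"),
                          rel_tol = 1e-8, abs_tol = 1e-10,
                          dt_fixed = 1e-3, t_end = 500, n_report = 1001,
                          transient = t_end / 2,
                          extinction_eps = 1e-8, clamp_negative = TRUE,
                          absorb_floor = 1e-30, chunk_t = 50,
                          engine = c("compiled", "R")) {
  method <- match.arg(method)
  engine <- match.arg(engine)
  rel_tol <- as.numeric(rel_tol); abs_tol <- as.numeric(abs_tol)
  dt_fixed <- as.numeric(dt_fixed); t_end <- as.numeric(t_end)
  n_report <- as.integer(n_report); transient <- as.numeric(transient)
  extinction_eps <- as.numeric(extinction_eps)
  absorb_floor <- as.numeric(absorb_floor); chunk_t <- as.numeric(chunk_t)
  clamp_negative <- isTRUE(as.logical(clamp_negative))
  stopifnot(rel_tol > 0, abs_tol > 0, dt_fixed > 0, t_end > 0,
            n_report >= 2, transient >= 0, transient < t_end,
            extinction_eps > 0, absorb_floor > 0, chunk_t > 0)
  structure(list(method = method, rel_tol = rel_tol, abs_tol = abs_tol,
                 dt_fixed = dt_fixed, t_end = t_end, n_report = n_report,
                 transient = transient, extinction_eps = extinction_eps,
                 clamp_negative = clamp_negative, absorb_floor = absorb_floor,
                 chunk_t = chunk_t, engine = engine),
            class = "ecoepi_solver")
}

# One deSolve call over a times grid; returns the raw matrix or signals
# an ecoepi_integration_error.
.integrate_segment <- function(y, times, pars, solver) {
  pv <- params_vector(pars)
  res <- tryCatch({
    if (solver$engine == "compiled") {
      if (solver$method == "adaptive") {
        deSolve::ode(y = y, times = times, func = "ecoepi_derivs",
                     parms = pv, dllname = "ecoepidyn",
                     initfunc = "ecoepi_initmod", method = "lsoda",
                     rtol = solver$rel_tol, atol = solver$abs_tol,
                     maxsteps = 100000)
      } else {
        deSolve::ode(y = y, times = times, func = "ecoepi_derivs",
                     parms = pv, dllname = "ecoepidyn",
                     initfunc = "ecoepi_initmod", method = "rk4",
                     hini = solver$dt_fixed)
      }
    } else {
      fr <- function(t, y, parms) {
        st <- y[seq_len(4)]
        names(st) <- c("S", "I", "P", "x")
        d <- unname(ode_rhs(st, pars))
        if (length(y) == 8) {
          st2 <- y[5:8]; names(st2) <- c("S", "I", "P", "x")
          d <- c(d, unname(ode_rhs(st2, pars)))
        }
        list(d)
      }
      if (solver$method == "adaptive") {
        deSolve::ode(y = y, times = times, func = fr, parms = NULL,
                     method = "lsoda", rtol = solver$rel_tol,
                     atol = solver$abs_tol, maxsteps = 100000)
      } else {
        deSolve::ode(y = y, times = times, func = fr, parms = NULL,
                     method = "rk4", hini = solver$dt_fixed)
      }
    }
  }, error = function(e) e, warning = function(w) w)
  if (inherits(res, "condition")) {
    stop(integration_error(times[1], conditionMessage(res)))
  }
  m <- unclass(res)
  if (nrow(m) < length(times) || any(!is.finite(m[nrow(m), -1]))) {
    t_fail <- if (nrow(m) >= 1) m[nrow(m), 1] else times[1]
    stop(integration_error(t_fail, "non-finite state or premature stop"))
  }
  m
}

integration_error <- function(time, msg) {
  structure(class = c("ecoepi_integration_error", "error", "condition"),
            list(message = sprintf("integration failed at t = %.6g: %s",
                                   time, msg),
                 call = NULL, time = time))
}

#' Simulate the model
#'
#' Integrates the system from `t = 0` to `solver$t_end` and reports the
#' state on a uniform grid. Integration proceeds in segments of
#' `solver$chunk_t` time units; between segments, negativity clamping and
#' underflow absorption are applied to the state (see [solver_config()])
#' and logged as events. The result is deterministic given
#' `(pars, state0, solver)`.
#'
#' @param pars An [model_params()] object.
#' @param state0 Initial state from [initial_state()].
#' @param solver A [solver_config()].
#' @return A trajectory: a tibble with columns `t, S, I, P, x` of class
#'   `ecoepi_traj`, carrying attributes `params`, `solver` and `events`
#'   (a tibble `time, compartment, event`). Access events with
#'   [trajectory_events()].
#' @examples
#' traj <- simulate_model(model_params(beta0 = 0.8),
#'                        solver = solver_config(t_end = 100, n_report = 201))
#' dplyr::slice_tail(traj, n = 3)
#' @export
simulate_model <- function(pars, state0 = initial_state(),
                           solver = solver_config()) {
  stopifnot(inherits(pars, "ecoepi_params"), inherits(solver, "ecoepi_solver"))
  state0 <- validate_state(state0)
  times <- seq(0, solver$t_end, length.out = solver$n_report)

  # segment boundaries: report indices grouped into spans <= chunk_t
  n_chunks <- max(1L, ceiling(solver$t_end / solver$chunk_t))
  breaks <- unique(round(seq(1L, length(times), length.out = n_chunks + 1L)))

  out <- matrix(NA_real_, nrow = length(times), ncol = 4)
  out[1, ] <- unname(state0)
  events <- list()
  y <- unname(state0)
  comp <- c("S", "I", "P", "x")

  clamp <- function(y, t) {
    if (!solver$clamp_negative) return(y)
    for (j in 1:3) {
      if (y[j] < 0) {
        if (y[j] < -solver$abs_tol) {
          events[[length(events) + 1L]] <<-
            list(time = t, compartment = comp[j], event = "clamped_negative")
        }
        y[j] <- 0
      } else if (y[j] > 0 && y[j] < solver$absorb_floor) {
        events[[length(events) + 1L]] <<-
          list(time = t, compartment = comp[j], event = "absorbed")
        y[j] <- 0
      }
    }
    if (y[4] < 0) { y[4] <- 0 } else if (y[4] > 1) { y[4] <- 1 }
    y
  }

  for (k in seq_len(length(breaks) - 1L)) {
    idx <- breaks[k]:breaks[k + 1L]
    m <- .integrate_segment(y, times[idx], pars, solver)
    seg <- m[, 2:5, drop = FALSE]
    # clamp reported rows (display contract: reported states satisfy the
    # invariants even when the integrator wanders below 0 by < abs_tol)
    seg[, 1:3][seg[, 1:3] < 0] <- 0
    seg[, 4] <- pmin(pmax(seg[, 4], 0), 1)
    out[idx, ] <- seg
    y <- clamp(m[nrow(m), 2:5], times[breaks[k + 1L]])
    out[breaks[k + 1L], ] <- y
  }

  ev <- if (length(events) == 0) {
    tibble::tibble(time = numeric(), compartment = character(),
                   event = character())
  } else {
    dplyr::bind_rows(lapply(events, tibble::as_tibble))
  }
  traj <- tibble::tibble(t = times, S = out[, 1], I = out[, 2],
                         P = out[, 3], x = out[, 4])
  attr(traj, "params") <- pars
  attr(traj, "solver") <- solver
  attr(traj, "events") <- ev
  attr(traj, "state0") <- state0
  class(traj) <- c("ecoepi_traj", class(traj))
  traj
}

#' Clamping/absorption events of a trajectory
#'
#' @param traj A trajectory from [simulate_model()].
#' @return A tibble `time, compartment, event`.
#' @export
trajectory_events <- function(traj) {
  ev <- attr(traj, "events")
  if (is.null(ev)) {
    tibble::tibble(time = numeric(), compartment = character(),
                   event = character())
  } else ev
}

#' Detect extinction of the population compartments
#'
#' For each of `S`, `I`, `P`: the first report time the density falls below
#' `eps`, and whether it remains below `eps` until the end of the
#' trajectory. A compartment is considered extinct when both hold
#' (`extinct = !is.na(time) & stayed_below`).
#'
#' @param traj A trajectory from [simulate_model()].
#' @param eps Extinction threshold; defaults to the solver's
#'   `extinction_eps`.
#' @return A tibble with one row per compartment: `compartment`,
#'   `first_below` (time of the first dip below `eps`, `NA` if never),
#'   `stayed_below` (whether it stayed below from that first dip on),
#'   `extinct` (whether the density is below `eps` from some time through
#'   the end of the trajectory, with that terminal stretch covering at
#'   least 5% of the horizon -- a cycle can dip through `eps` at a
#'   trough, rebound, and only later die for good, and a trough that
#'   happens to sit at the very end must not be called extinction), and
#'   `extinct_from` (start of the terminal below-`eps` stretch).
#' @examples
#' traj <- simulate_model(model_params(beta0 = 0.5),
#'                        solver = solver_config(t_end = 200, n_report = 401))
#' detect_extinction(traj)
#' @export
detect_extinction <- function(traj, eps = NULL) {
  stopifnot(inherits(traj, "ecoepi_traj") || all(c("t", "S", "I", "P") %in% names(traj)))
  if (is.null(eps)) {
    sl <- attr(traj, "solver")
    eps <- if (!is.null(sl)) sl$extinction_eps else 1e-8
  }
  purrr::map_dfr(c("S", "I", "P"), function(cc) {
    v <- traj[[cc]]
    n <- length(v)
    below <- which(v < eps)
    if (length(below) == 0) {
      return(tibble::tibble(compartment = cc, first_below = NA_real_,
                            stayed_below = FALSE, extinct = FALSE,
                            extinct_from = NA_real_))
    }
    stayed <- all(v[below[1]:n] < eps)
    from <- if (v[n] < eps) {
      above <- which(v >= eps)
      if (length(above) == 0) traj$t[1] else traj$t[max(above) + 1L]
    } else NA_real_
    # require the terminal below-eps stretch to cover at least 5% of the
    # horizon, so a single cycle trough at the end is not called extinct
    extinct <- !is.na(from) &&
      (traj$t[n] - from) >= 0.05 * (traj$t[n] - traj$t[1])
    tibble::tibble(compartment = cc, first_below = traj$t[below[1]],
                   stayed_below = stayed, extinct = extinct,
                   extinct_from = from)
  })
}
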