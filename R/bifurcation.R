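# Attractor classification, Lyapunov exponents, one- and two-parameter
# scans, and eigenvalue-bisection stability thresholds.

# Local maxima of an evenly sampled series, refined by quadratic
# interpolation through the three points around each maximum.
.find_peaks <- function(y) {
  n <- length(y)
  if (n < 3) return(numeric())
  i <- which(y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
  if (length(i) == 0) return(numeric())
  ym <- y[i - 1]; y0 <- y[i]; yp <- y[i + 1]
  den <- ym - 2 * y0 + yp
  adj <- ifelse(abs(den) > 0, (ym - yp)^2 / (8 * abs(den)), 0)
  y0 + adj
}

# Cluster peak values at a relative tolerance; returns the cluster count.
.count_peak_clusters <- function(peaks, rel_tol = 1e-3) {
  if (length(peaks) == 0) return(0L)
  scale <- max(abs(peaks), 1e-12)
  v <- sort(peaks)
  sum(c(TRUE, diff(v) > rel_tol * scale))
}

#' Largest Lyapunov exponent (two-trajectory Benettin estimate)
#'
#' Average exponential separation rate of a companion trajectory started a
#' distance `d0` from the reference, renormalised back to `d0` every
#' `renorm_dt` time units over the post-transient window. Positive values
#' indicate chaos; a neutral direction along a limit cycle gives values
#' near 0; contraction toward a stable equilibrium gives negative values.
#' Deterministic given its arguments.
#'
#' When the strategy is fixed, the perturbation and the separation metric
#' live in the `(S, I, P)` subspace (a fixed `x` would contribute a
#' spurious neutral direction).
#'
#' @param pars An [model_params()] object.
#' @param state0 Initial state.
#' @param solver A [solver_config()]; its `transient` is discarded first.
#' @param d0 Initial separation.
#' @param renorm_dt Renormalisation interval (time units).
#' @param horizon Averaging window length after the transient.
#' @return The exponent (1/time units). If the reference trajectory hits
#'   extinction during the probe, `NA` is returned with attribute
#'   `reason = "extinction"`.
#' @export
largest_lyapunov <- function(pars, state0 = initial_state(),
                             solver = solver_config(), d0 = 1e-8,
                             renorm_dt = 1,
                             horizon = min(500, solver$t_end - solver$transient)) {
  stopifnot(inherits(pars, "ecoepi_params"))
  state0 <- validate_state(state0)
  dims <- if (pars$x_mode == "dynamic") 1:4 else 1:3

  # run in the reference trajectory through the transient
  y <- unname(state0)
  if (solver$transient > 0) {
    tt <- seq(0, solver$transient,
              length.out = max(2L, ceiling(solver$transient / solver$chunk_t) + 1L))
    m <- .integrate_segment(y, tt, pars, solver)
    y <- pmax(m[nrow(m), 2:5], 0); y[4] <- min(max(m[nrow(m), 5], 0), 1)
  }

  u <- rep(0, 4); u[dims] <- 1 / sqrt(length(dims))
  y8 <- c(y, y + d0 * u)
  n_steps <- max(1L, round(horizon / renorm_dt))
  log_sum <- 0
  for (k in seq_len(n_steps)) {
    m <- .integrate_segment(y8, c(0, renorm_dt), pars, solver)
    y8 <- m[nrow(m), 2:9]
    if (any(y8[1:3] < solver$extinction_eps & unname(state0[1:3]) > 0)) {
      # reference orbit collapsed onto an extinction face: not applicable
      out <- NA_real_
      attr(out, "reason") <- "extinction"
      return(out)
    }
    diff <- y8[5:8] - y8[1:4]
    d <- sqrt(sum(diff[dims]^2))
    if (!is.finite(d) || d == 0) {
      out <- NA_real_
      attr(out, "reason") <- "degenerate_separation"
      return(out)
    }
    log_sum <- log_sum + log(d / d0)
    y8[5:8] <- y8[1:4] + (d0 / d) * diff
  }
  log_sum / (n_steps * renorm_dt)
}

#' Classify the attractor of a trajectory
#'
#' Post-transient characterisation, in this order of precedence:
#' 1. extinction labels (a compartment that falls below `eps` and stays
#'    below until the end) give `extinct_I`, `extinct_P` or
#'    `extinct_I_and_P`;
#' 2. if every surviving compartment's post-transient amplitude is below
#'    `point_tol`, the regime is `stable_point`;
#' 3. otherwise, if the largest Lyapunov exponent exceeds `chaos_tol`,
#'    `chaotic`;
#' 4. otherwise the number of distinct peak values (clustered at relative
#'    tolerance `peak_rel_tol`) decides: 1 is `limit_cycle`, 2 or more is
#'    `period_doubled`; a windowed series with amplitude above `point_tol`
#'    but no local maxima at all is a monotone transient and is labelled
#'    `stable_point` with a `transient_not_settled` warning.
#'
#' A `transient_not_settled` warning is also recorded (non-fatally) when
#' the amplitude over the second half of the window differs from the
#' first half by more than 20%.
#'
#' @param traj A trajectory from [simulate_model()] covering at least
#'   twice the transient.
#' @param transient Time to discard; defaults to the solver's value.
#' @param eps Extinction threshold (defaults to the solver's).
#' @param point_tol Amplitude below which a compartment is steady.
#' @param chaos_tol Lyapunov threshold separating chaos from neutral cycle
#'   directions at desk-scale horizons.
#' @param peak_rel_tol Relative tolerance for clustering peak values;
#'   chosen to resolve period doubling without overcounting solver jitter.
#' @param lyapunov `TRUE` to estimate the exponent when (and only when)
#'   the classification needs it, `FALSE` to skip (regime then never
#'   `chaotic`), or a number to use directly.
#' @return An object of class `ecoepi_attractor`: a list with `regime`,
#'   `extrema` (tibble: compartment, min, max, amplitude, n_peaks, peaks),
#'   `lyapunov`, `extinct`, `warnings`, `window`. Use [generics::tidy()]
#'   for a one-row summary.
#' @export
classify_attractor <- function(traj, transient = NULL, eps = NULL,
                               point_tol = 1e-4, chaos_tol = 0.005,
                               peak_rel_tol = 1e-3, lyapunov = TRUE) {
  stopifnot(inherits(traj, "ecoepi_traj"))
  solver <- attr(traj, "solver")
  pars <- attr(traj, "params")
  if (is.null(transient)) transient <- solver$transient
  if (is.null(eps)) eps <- solver$extinction_eps
  t_end <- max(traj$t)
  if (t_end < 2 * transient) {
    stop("trajectory must be at least twice the transient cut", call. = FALSE)
  }
  w <- traj$t > transient
  warnings <- character()

  ext <- detect_extinction(traj, eps = eps)
  extinct <- ext$compartment[ext$extinct]

  extrema <- purrr::map_dfr(c("S", "I", "P"), function(cc) {
    y <- traj[[cc]][w]
    pk <- .find_peaks(y)
    tibble::tibble(compartment = cc, min = min(y), max = max(y),
                   amplitude = max(y) - min(y),
                   n_peaks = .count_peak_clusters(pk, peak_rel_tol),
                   peaks = list(pk))
  })

  # settledness: amplitude over the two halves of the post-transient
  # window must agree within 20% (halves rather than 10% tails so that
  # the long-period relaxation cycles of this model fit inside a window)
  surv <- setdiff(c("S", "I", "P"), extinct)
  t_half <- (transient + t_end) / 2
  for (cc in surv) {
    a_last <- diff(range(traj[[cc]][traj$t > t_half]))
    a_prev <- diff(range(traj[[cc]][w & traj$t <= t_half]))
    if (abs(a_last - a_prev) > 0.2 * max(a_prev, point_tol)) {
      warnings <- union(warnings, "transient_not_settled")
    }
  }

  surv_amp <- extrema$amplitude[extrema$compartment %in% surv]
  oscillatory <- length(surv) > 0 && any(surv_amp > point_tol)
  lyap <- NA_real_

  if (length(extinct) > 0 && "S" %in% extinct) {
    regime <- "extinct_S"
  } else if (all(c("I", "P") %in% extinct)) {
    regime <- "extinct_I_and_P"
  } else if ("I" %in% extinct) {
    regime <- "extinct_I"
  } else if ("P" %in% extinct) {
    regime <- "extinct_P"
  } else if (!oscillatory) {
    regime <- "stable_point"
  } else {
    if (isTRUE(lyapunov)) {
      lyap <- largest_lyapunov(pars, attr(traj, "state0"), solver)
    } else if (is.numeric(lyapunov)) {
      lyap <- lyapunov
    }
    npk <- max(extrema$n_peaks[extrema$compartment %in% surv &
                                 extrema$amplitude > point_tol])
    if (!is.na(lyap) && lyap > chaos_tol) {
      regime <- "chaotic"
    } else if (npk == 0) {
      regime <- "stable_point"
      warnings <- union(warnings, "transient_not_settled")
    } else if (npk == 1) {
      regime <- "limit_cycle"
    } else {
      regime <- "period_doubled"
    }
  }

  structure(list(regime = regime, extrema = extrema, lyapunov = lyap,
                 extinct = extinct, oscillatory = oscillatory,
                 warnings = warnings, window = c(transient, t_end)),
            class = "ecoepi_attractor")
}

#' @export
print.ecoepi_attractor <- function(x, ...) {
  cat("<ecoepi_attractor> regime:", x$regime,
      if (!is.na(x$lyapunov)) sprintf(" lyapunov: %.4g", x$lyapunov), "\n")
  print(x$extrema[, c("compartment", "min", "max", "amplitude", "n_peaks")])
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = ", "), "\n")
  invisible(x)
}

# shared engine for 1-D and 2-D scans
.scan_engine <- function(pars, grid, state0, solver, policy, lyapunov,
                         point_tol, chaos_tol, peak_rel_tol) {
  param_names <- names(grid)
  state <- state0
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p_i <- pars
    s_i <- if (policy == "continuation" && i > 1 && !is.null(state)) {
      state
    } else state0
    for (pn in param_names) {
      v <- grid[[pn]][i]
      if (pn == "x") {
        s_i[["x"]] <- v
      } else {
        p_i <- do.call(update_params, c(list(p_i), stats::setNames(list(v), pn)))
      }
    }
    res <- tryCatch({
      traj <- simulate_model(p_i, s_i, solver)
      att <- classify_attractor(traj, point_tol = point_tol,
                                chaos_tol = chaos_tol,
                                peak_rel_tol = peak_rel_tol,
                                lyapunov = lyapunov)
      state <- unname(traj[nrow(traj), c("S", "I", "P", "x")])
      state <- validate_state(pmin(pmax(as.numeric(state), 0),
                                   c(Inf, Inf, Inf, 1)))
      list(att = att, error = NA_character_)
    }, ecoepi_integration_error = function(e) {
      list(att = NULL, error = conditionMessage(e))
    })
    row <- tibble::as_tibble(grid[i, , drop = FALSE])
    if (!is.null(res$att)) {
      a <- res$att
      ex <- a$extrema
      wide <- stats::setNames(
        as.list(c(ex$min, ex$max, ex$amplitude, ex$n_peaks)),
        c(paste0(ex$compartment, "_min"), paste0(ex$compartment, "_max"),
          paste0(ex$compartment, "_amp"), paste0(ex$compartment, "_n_peaks")))
      row <- dplyr::bind_cols(row, tibble::as_tibble(wide))
      row$regime <- a$regime
      row$oscillatory <- a$oscillatory
      row$lyapunov <- a$lyapunov
      row$warnings <- paste(a$warnings, collapse = ";")
      row$S_peaks <- list(ex$peaks[[1]])
      row$I_peaks <- list(ex$peaks[[2]])
      row$P_peaks <- list(ex$peaks[[3]])
    } else {
      row$regime <- NA_character_
      row$oscillatory <- NA
      row$lyapunov <- NA_real_
      row$warnings <- ""
      row$S_peaks <- list(numeric()); row$I_peaks <- list(numeric())
      row$P_peaks <- list(numeric())
    }
    row$error <- res$error
    rows[[i]] <- row
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "params") <- pars
  attr(out, "solver") <- solver
  attr(out, "swept") <- param_names
  attr(out, "policy") <- policy
  attr(out, "state0") <- state0
  class(out) <- c("ecoepi_scan", class(out))
  out
}

#' One-parameter bifurcation scan
#'
#' For each value of the swept quantity: simulate, discard the transient,
#' and attach the attractor summary. The peak-value columns reproduce the
#' dots-per-parameter-value structure of a numerical bifurcation diagram
#' (local extrema of the post-transient trajectory). Sweeping `"x"` sets
#' the strategy component of the initial state (the frozen strategy level
#' when `x_mode = "fixed"`).
#'
#' @param pars Base [model_params()].
#' @param param Name of the swept quantity: a parameter field or `"x"`.
#' @param values Sorted numeric grid.
#' @param state0 Initial state (used at every grid point under the default
#'   `"fixed"` policy).
#' @param solver A [solver_config()].
#' @param policy `"fixed"` restarts every run from `state0`;
#'   `"continuation"` reuses the previous endpoint (useful to expose
#'   hysteresis; the two policies agree wherever there is no bistability).
#' @param lyapunov,point_tol,chaos_tol,peak_rel_tol Passed to
#'   [classify_attractor()].
#' @return A tibble of class `ecoepi_scan`: the swept column, `regime`,
#'   `oscillatory`, `lyapunov`, per-compartment `*_min`, `*_max`, `*_amp`,
#'   `*_n_peaks` and `*_peaks` list-columns, and `error` (per-point
#'   integration failures are recorded, not fatal).
#' @examples
#' \donttest{
#' sc <- scan_1d(model_params(), "x", seq(0.3, 0.5, by = 0.05),
#'               solver = solver_config(t_end = 400, n_report = 801))
#' sc[, c("x", "regime")]
#' }
#' @export
scan_1d <- function(pars, param, values, state0 = initial_state(),
                    solver = solver_config(),
                    policy = c("fixed", "continuation"),
                    lyapunov = TRUE, point_tol = 1e-4, chaos_tol = 0.005,
                    peak_rel_tol = 1e-3) {
  policy <- match.arg(policy)
  stopifnot(is.numeric(values), !is.unsorted(values))
  if (!param %in% c(.ecoepi_par_order, "x")) {
    stop("'", param, "' is not a model parameter or 'x'", call. = FALSE)
  }
  grid <- tibble::tibble(!!param := values)
  .scan_engine(pars, grid, state0, solver, policy, lyapunov, point_tol,
               chaos_tol, peak_rel_tol)
}

#' Two-parameter outcome scan
#'
#' Classifies the attractor on the Cartesian grid of two swept quantities
#' (typically the behavioural costs and the cooperation efficiency under
#' dynamic strategy), producing the cell structure of a two-parameter
#' outcome phase diagram.
#'
#' @inheritParams scan_1d
#' @param params Character vector of the two swept names.
#' @param values List of two sorted numeric grids, in the same order.
#' @return An `ecoepi_scan` tibble with one row per grid cell.
#' @export
scan_2d <- function(pars, params, values, state0 = initial_state(x = 0.5),
                    solver = solver_config(),
                    policy = c("fixed", "continuation"),
                    lyapunov = TRUE, point_tol = 1e-4, chaos_tol = 0.005,
                    peak_rel_tol = 1e-3) {
  policy <- match.arg(policy)
  stopifnot(length(params) == 2, length(values) == 2)
  for (k in 1:2) {
    stopifnot(is.numeric(values[[k]]), !is.unsorted(values[[k]]))
    if (!params[k] %in% c(.ecoepi_par_order, "x")) {
      stop("'", params[k], "' is not a model parameter or 'x'", call. = FALSE)
    }
  }
  grid <- tidyr::expand_grid(!!params[1] := values[[1]],
                             !!params[2] := values[[2]])
  .scan_engine(pars, grid, state0, solver, policy, lyapunov, point_tol,
               chaos_tol, peak_rel_tol)
}

#' Locate the oscillatory-to-steady flip of a 1-D scan
#'
#' Returns the midpoint between the last grid value whose attractor is
#' oscillatory (any surviving compartment's post-transient amplitude above
#' `point_tol`) and the first steady value that follows it.
#'
#' @param scan An `ecoepi_scan` from [scan_1d()].
#' @return The flip location (numeric), with attribute `bracket`; `NA` if
#'   the scan never flips.
#' @export
scan_regime_flip <- function(scan) {
  stopifnot(inherits(scan, "ecoepi_scan"))
  param <- attr(scan, "swept")[1]
  osc <- scan$oscillatory
  v <- scan[[param]]
  flip <- which(!osc[-1] & osc[-length(osc)])
  if (length(flip) == 0) return(NA_real_)
  i <- flip[1]
  out <- (v[i] + v[i + 1]) / 2
  attr(out, "bracket") <- c(v[i], v[i + 1])
  out
}

# --- eigenvalue-bisection thresholds -----------------------------------

.set_swept <- function(pars, param, v, x) {
  if (param == "x") {
    list(pars = pars, x = v)
  } else {
    list(pars = do.call(update_params,
                        c(list(pars), stats::setNames(list(v), param))),
         x = x)
  }
}

no_sign_change_error <- function(msg) {
  structure(class = c("ecoepi_no_sign_change", "error", "condition"),
            list(message = msg, call = NULL))
}
equilibrium_lost_error <- function(msg) {
  structure(class = c("ecoepi_equilibrium_lost", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Hopf threshold of the coexistence equilibrium
#'
#' Bisection on the maximum eigenvalue real part of the interior
#' coexistence equilibrium of the `(S, I, P)` subsystem, tracked across
#' the bracket by Newton continuation from the previous solution. The
#' bracket endpoints must straddle the crossing (otherwise a
#' `no-sign-change` error); if the tracked equilibrium leaves the positive
#' octant inside the bracket an `equilibrium-lost` error is raised.
#'
#' Note that for weakly damped foci the flip seen in a finite-horizon
#' bifurcation diagram can sit well away from this linear threshold; the
#' collapse of oscillatory coexistence through a boundary collision is
#' located by [invasion_threshold()] instead. See the methods vignette.
#'
#' @param pars Base [model_params()].
#' @param param Swept quantity (parameter name or `"x"`).
#' @param bracket Length-2 numeric bracket.
#' @param x Frozen strategy when `param` is not `"x"`.
#' @param eig_tol Stop when `|max Re lambda| <` this.
#' @param par_tol Stop when the bracket width `<` this.
#' @param n_grid Multi-start resolution used to find the equilibrium at
#'   the first endpoint.
#' @return The critical parameter value, with attributes `max_re`,
#'   `equilibrium` and `iterations`.
#' @export
hopf_threshold <- function(pars, param, bracket, x = 0,
                           eig_tol = 1e-8, par_tol = 1e-6, n_grid = 8) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])

  eq_eval <- function(v, seed) {
    sw <- .set_swept(pars, param, v, x)
    if (is.null(seed)) {
      eqs <- find_equilibria(sw$pars, mode = "fixed", x = sw$x,
                             n_grid = n_grid)
      cand <- dplyr::filter(eqs, .data$kind == "coexistence")
      if (nrow(cand) == 0) {
        stop(equilibrium_lost_error(sprintf(
          "no interior coexistence equilibrium at %s = %g", param, v)))
      }
      st <- as.numeric(cand[1, c("S", "I", "P")])
    } else {
      st <- .newton_root(seed, sw$pars, dim = 3, x_fixed = sw$x)
      if (is.null(st) || any(st < 1e-8)) {
        stop(equilibrium_lost_error(sprintf(
          "coexistence equilibrium lost while tracking at %s = %g", param, v)))
      }
    }
    stv <- c(st, sw$x); names(stv) <- c("S", "I", "P", "x")
    ev <- eigen(jacobian_matrix(stv, sw$pars, mode = "fixed"),
                only.values = TRUE)$values
    list(max_re = max(Re(ev)), eq = st)
  }

  lo <- bracket[1]; hi <- bracket[2]
  e_lo <- eq_eval(lo, NULL)
  e_hi <- eq_eval(hi, e_lo$eq)
  if (sign(e_lo$max_re) == sign(e_hi$max_re)) {
    stop(no_sign_change_error(sprintf(
      "max Re(lambda) has the same sign at both endpoints (%.3g, %.3g)",
      e_lo$max_re, e_hi$max_re)))
  }
  it <- 0L
  e_mid <- e_lo
  while (hi - lo > par_tol) {
    it <- it + 1L
    mid <- (lo + hi) / 2
    e_mid <- eq_eval(mid, e_lo$eq)
    if (abs(e_mid$max_re) < eig_tol) break
    if (sign(e_mid$max_re) == sign(e_lo$max_re)) {
      lo <- mid; e_lo <- e_mid
    } else {
      hi <- mid; e_hi <- e_mid
    }
  }
  out <- (lo + hi) / 2
  structure(out, max_re = e_mid$max_re, equilibrium = e_mid$eq,
            iterations = it)
}

#' Predator-invasion (coexistence collapse) threshold
#'
#' The parameter value at which the predator's invasion eigenvalue -- the
#' transversal eigenvalue of the predator-free attractor equilibrium on
#' the `P = 0` face -- crosses zero. On one side the predator can invade
#' and the three populations coexist (steadily or on cycles); on the
#' other the coexistence equilibrium has collided with the face
#' (its predator component reaching 0 with a zero leading eigenvalue,
#' a transcritical exchange of stability) and the attractor is the
#' predator-free state. This is the point where oscillatory coexistence
#' visibly collapses in a finite-horizon bifurcation diagram.
#'
#' The predator-free equilibrium is available in closed form: the endemic
#' state `(S*, I*, 0)` with `beta(x) S*/(a+S*) = mu` when the infection
#' can invade, else the disease-free state `(r/b, 0, 0)`. With a weak
#' Allee effect (`theta > 0`) the invasion eigenvalue is identically
#' `-m < 0` (the mate-finding factor vanishes at `P = 0`), so no crossing
#' exists and a `no-sign-change` error is raised -- which is exactly why
#' any positive `theta` dooms a rare predator in this model.
#'
#' @inheritParams hopf_threshold
#' @return The critical parameter value, with attributes `equilibrium`
#'   (the face equilibrium at the root) and `iterations`.
#' @export
invasion_threshold <- function(pars, param, bracket, x = 0, par_tol = 1e-6) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])
  lam <- function(v) {
    sw <- .set_swept(pars, param, v, x)
    fe <- predator_free_equilibrium(sw$pars, x = sw$x)
    J <- jacobian_matrix(fe, sw$pars, mode = "fixed")
    list(lam = J["P", "P"], eq = fe)
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- lam(lo); f_hi <- lam(hi)
  if (sign(f_lo$lam) == sign(f_hi$lam)) {
    stop(no_sign_change_error(sprintf(
      "predator-invasion eigenvalue has the same sign at both endpoints (%.3g, %.3g)",
      f_lo$lam, f_hi$lam)))
  }
  it <- 0L
  f_mid <- f_lo
  while (hi - lo > par_tol) {
    it <- it + 1L
    mid <- (lo + hi) / 2
    f_mid <- lam(mid)
    if (sign(f_mid$lam) == sign(f_lo$lam)) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid; f_hi <- f_mid
    }
  }
  structure((lo + hi) / 2, equilibrium = f_mid$eq, iterations = it)
}
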