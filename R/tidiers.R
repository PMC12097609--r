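# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an equilibrium set
#'
#' One row per equilibrium with its state, kind, stability label, leading
#' eigenvalue real part, spectral details and residual.
#'
#' @param x An `ecoepi_eq_set` from [find_equilibria()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ecoepi_eq_set <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$eigenvalues <- purrr::map(out$eigenvalues, identity)
  out
}

#' Glance at an equilibrium set
#'
#' @param x An `ecoepi_eq_set`.
#' @param ... Unused.
#' @return A one-row tibble: counts per kind, number stable, worst
#'   residual.
#' @export
glance.ecoepi_eq_set <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    n_coexistence = sum(x$kind == "coexistence"),
    n_axial = sum(x$kind %in% c("axial", "boundary-x")),
    n_stable = sum(x$label %in% c("stable_node", "stable_focus")),
    max_residual = if (nrow(x)) max(x$residual) else NA_real_
  )
}

#' Tidy an attractor summary
#'
#' @param x An `ecoepi_attractor` from [classify_attractor()].
#' @param ... Unused.
#' @return A one-row tibble: regime, Lyapunov exponent, per-compartment
#'   extrema and peak counts, warnings.
#' @export
tidy.ecoepi_attractor <- function(x, ...) {
  ex <- x$extrema
  wide <- stats::setNames(
    as.list(c(ex$min, ex$max, ex$amplitude, ex$n_peaks)),
    c(paste0(ex$compartment, "_min"), paste0(ex$compartment, "_max"),
      paste0(ex$compartment, "_amp"), paste0(ex$compartment, "_n_peaks")))
  dplyr::bind_cols(
    tibble::tibble(regime = x$regime, oscillatory = x$oscillatory,
                   lyapunov = x$lyapunov),
    tibble::as_tibble(wide),
    tibble::tibble(warnings = paste(x$warnings, collapse = ";"))
  )
}

#' Tidy a scan result
#'
#' Long format: one row per grid point, compartment and post-transient
#' peak value (the dots of a bifurcation diagram).
#'
#' @param x An `ecoepi_scan`.
#' @param ... Unused.
#' @return A tibble with the swept column(s), `compartment`, `peak`,
#'   `regime`.
#' @export
tidy.ecoepi_scan <- function(x, ...) {
  swept <- attr(x, "swept")
  tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(x), dplyr::all_of(swept), "regime",
                  dplyr::matches("^[SIP]_peaks$")),
    dplyr::matches("^[SIP]_peaks$"), names_to = "compartment",
    values_to = "peak") |>
    dplyr::mutate(compartment = sub("_peaks$", "", .data$compartment)) |>
    tidyr::unnest_longer("peak", indices_include = FALSE)
}

#' Glance at a scan result
#'
#' @param x An `ecoepi_scan`.
#' @param ... Unused.
#' @return A one-row tibble: grid size, regime counts, number of
#'   integration failures.
#' @export
glance.ecoepi_scan <- function(x, ...) {
  counts <- table(x$regime)
  out <- tibble::tibble(n_points = nrow(x),
                        n_failed = sum(!is.na(x$error)))
  for (nm in names(counts)) out[[paste0("n_", nm)]] <- as.integer(counts[[nm]])
  out
}

#' Glance at a trajectory
#'
#' @param x An `ecoepi_traj`.
#' @param ... Unused.
#' @return A one-row tibble: horizon, report points, final state, event
#'   count.
#' @export
glance.ecoepi_traj <- function(x, ...) {
  n <- nrow(x)
  tibble::tibble(t_end = x$t[n], n_report = n,
                 S_final = x$S[n], I_final = x$I[n], P_final = x$P[n],
                 x_final = x$x[n], n_events = nrow(trajectory_events(x)))
}
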