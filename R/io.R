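# Readers and writers: tidy CSV for trajectories and scans, JSON sidecars
# with full provenance. All floating point is serialised with 17
# significant digits so round-trips are bit-exact.

.fmt17 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

.params_to_list <- function(pars) {
  c(lapply(pars[.ecoepi_par_order], identity),
    list(x_mode = pars$x_mode, g_mode = pars$g_mode))
}

.params_from_list <- function(lst) {
  do.call(model_params, lst[intersect(names(lst),
                                      c(.ecoepi_par_order, "x_mode", "g_mode"))])
}

#' Write / read a trajectory
#'
#' `write_trajectory()` stores the report grid as a tidy CSV with columns
#' `t, S, I, P, x` (17 significant digits) plus a JSON sidecar
#' (`<path>.json`) holding the parameter set, solver configuration,
#' initial state and clamp/absorption events. `read_trajectory()`
#' reconstructs the `ecoepi_traj` object; the round-trip is bit-exact.
#'
#' @param traj A trajectory from [simulate_model()].
#' @param path CSV path; the sidecar is written next to it.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns the trajectory.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ecoepi_traj"))
  m <- vapply(c("t", "S", "I", "P", "x"), function(cc) .fmt17(traj[[cc]]),
              character(nrow(traj)))
  utils::write.table(m, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = c("t", "S", "I", "P", "x"))
  solver <- attr(traj, "solver")
  side <- list(
    params = .params_to_list(attr(traj, "params")),
    solver = unclass(solver),
    state0 = as.list(attr(traj, "state0")),
    events = attr(traj, "events")
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  traj <- tibble::as_tibble(df)
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    attr(traj, "params") <- .params_from_list(side$params)
    sl <- side$solver
    attr(traj, "solver") <- do.call(solver_config, sl[setdiff(names(sl), NULL)])
    attr(traj, "state0") <- validate_state(unlist(side$state0))
    ev <- side$events
    attr(traj, "events") <- if (is.null(ev) || length(ev) == 0 ||
                                (is.data.frame(ev) && nrow(ev) == 0)) {
      tibble::tibble(time = numeric(), compartment = character(),
                     event = character())
    } else tibble::as_tibble(ev)
  }
  class(traj) <- c("ecoepi_traj", class(traj))
  traj
}

#' Write / read a scan result
#'
#' `write_scan()` stores the long format of a scan (one row per grid
#' point, compartment and peak value -- the dots of a bifurcation
#' diagram) as CSV, and a JSON summary (`<path>.json`) with the per-point
#' regimes, Lyapunov map, swept grid and provenance. `read_scan()`
#' returns a list `long` (tibble) and `summary`.
#'
#' @param scan An `ecoepi_scan` from [scan_1d()] or [scan_2d()].
#' @param path CSV path.
#' @return `write_scan()`: `path`, invisibly. `read_scan()`: a list.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "ecoepi_scan"))
  swept <- attr(scan, "swept")
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(scan), dplyr::all_of(swept),
                  dplyr::matches("^[SIP]_peaks$")),
    dplyr::matches("^[SIP]_peaks$"), names_to = "compartment",
    values_to = "peak") |>
    dplyr::mutate(compartment = sub("_peaks$", "", .data$compartment)) |>
    tidyr::unnest_longer("peak", indices_include = FALSE)
  m <- vapply(names(long), function(cc) {
    v <- long[[cc]]
    if (is.numeric(v)) .fmt17(v) else as.character(v)
  }, character(nrow(long)))
  utils::write.table(m, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = names(long))
  summary <- list(
    swept = swept,
    policy = attr(scan, "policy"),
    params = .params_to_list(attr(scan, "params")),
    solver = unclass(attr(scan, "solver")),
    state0 = as.list(attr(scan, "state0")),
    points = dplyr::select(tibble::as_tibble(scan), dplyr::all_of(swept),
                           dplyr::any_of(c("regime", "oscillatory",
                                           "lyapunov", "warnings", "error")))
  )
  jsonlite::write_json(summary, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  long <- tibble::as_tibble(utils::read.csv(path))
  side_path <- paste0(path, ".json")
  summary <- if (file.exists(side_path)) {
    jsonlite::read_json(side_path, simplifyVector = TRUE)
  } else NULL
  list(long = long, summary = summary)
}
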