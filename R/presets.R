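# Named scenario presets: every parameter combination printed in the
# source figure captions, plus the figure-specific sweeps, so all
# experiments run self-contained.

# The caption base set shared by all scenarios. `notes` keeps the printed
# value of every caption-backed field as a string, so an integrity test can
# confirm the registry equals the captions character-for-character.
.caption_base <- c(a = "0.3636", b = "1.0", alpha1 = "0.01", sigma = "15",
                   c = "0.01", r = "1.0", alpha2 = "0.05", d = "0.5",
                   mu = "0.4", c1 = "2", c2 = "1.0", e = "1.0", m = "0.01")

.base_params <- function(...) {
  do.call(model_params, list(...))
}

.preset_registry <- local({
  reg <- list()

  add <- function(name, description, params, state0, sweep = NULL,
                  variants = NULL, notes = character()) {
    reg[[name]] <<- list(name = name, description = description,
                         params = params, state0 = state0, sweep = sweep,
                         variants = variants,
                         notes = c(.caption_base, notes))
  }

  add("fig1",
      "Transmission-rate ladder: x = 0, theta = 0, beta0 in {0.5, 0.6, 0.8, 0.95}",
      .base_params(beta0 = 0.5, theta = 0, x_mode = "fixed"),
      initial_state(x = 0),
      sweep = list(beta0 = c(0.5, 0.6, 0.8, 0.95)),
      notes = c(theta = "0", x = "0.0", beta0 = "0.5"))

  add("fig2",
      "Allee sweep at moderate transmission: beta0 = 0.7, theta in {0, 0.01, 0.3, 0.5}",
      .base_params(beta0 = 0.7, theta = 0, x_mode = "fixed"),
      initial_state(x = 0),
      sweep = list(theta = c(0, 0.01, 0.3, 0.5)),
      notes = c(beta0 = "0.7", x = "0.0"))

  add("fig3",
      "Allee sweep at high transmission: beta0 = 0.95, theta in {0, 0.01, 0.3, 0.5}",
      .base_params(beta0 = 0.95, theta = 0, x_mode = "fixed"),
      initial_state(x = 0),
      sweep = list(theta = c(0, 0.01, 0.3, 0.5)),
      notes = c(beta0 = "0.95", x = "0.0"))

  add("fig4",
      "Fixed-strategy ladder: beta0 = 0.95, theta = 0, x in {0, 0.01, 0.1, 0.3}",
      .base_params(beta0 = 0.95, theta = 0, x_mode = "fixed"),
      initial_state(x = 0),
      sweep = list(x = c(0, 0.01, 0.1, 0.3)),
      notes = c(beta0 = "0.95", theta = "0.0"))

  add("fig5",
      "1-D bifurcation along frozen x, theta = 0 (variants 0.01, 0.03); beta0 = 0.95 adopted",
      .base_params(beta0 = 0.95, theta = 0, x_mode = "fixed"),
      initial_state(x = 0),
      sweep = list(x = seq(0, 1, by = 0.02)),
      variants = list(theta = c(0, 0.01, 0.03)),
      notes = c(theta = "0.0"))

  add("fig5_text_variant",
      "1-D bifurcation along frozen x with theta = 0.3 (running-text variant)",
      .base_params(beta0 = 0.95, theta = 0.3, x_mode = "fixed"),
      initial_state(x = 0),
      sweep = list(x = seq(0, 1, by = 0.02)),
      notes = c(theta = "0.3"))

  add("fig6",
      "Dynamic strategy time series: CS, CP in {0.1, 0.5, 0.9}, theta = 0; beta0 = 0.95 adopted",
      .base_params(beta0 = 0.95, theta = 0, CS = 0.1, CP = 0.1,
                   x_mode = "dynamic"),
      initial_state(x = 0.5),
      sweep = list(CS = c(0.1, 0.5, 0.9), CP = c(0.1, 0.5, 0.9)),
      notes = c(theta = "0.0"))

  add("fig7",
      "1-D bifurcation along CS, CP variants {0.1, 0.5, 0.9}, theta = 0; beta0 = 0.95 adopted",
      .base_params(beta0 = 0.95, theta = 0, CP = 0.1, x_mode = "dynamic"),
      initial_state(x = 0.5),
      sweep = list(CS = seq(0, 1, by = 0.02)),
      variants = list(CP = c(0.1, 0.5, 0.9)),
      notes = c(theta = "0.0"))

  add("fig8",
      "1-D bifurcation along CS, theta variants {0, 0.1, 0.5}, CP = 0.5; beta0 = 0.95 adopted",
      .base_params(beta0 = 0.95, theta = 0, CP = 0.5, x_mode = "dynamic"),
      initial_state(x = 0.5),
      sweep = list(CS = seq(0, 1, by = 0.02)),
      variants = list(theta = c(0, 0.1, 0.5)),
      notes = c(CP = "0.5", theta = "0.0"))

  add("fig9",
      "2-D outcome diagram over (CS, e) at beta0 = 0.7, CP = 0.5, theta in {0, 0.1}",
      .base_params(beta0 = 0.7, theta = 0, CP = 0.5, x_mode = "dynamic"),
      initial_state(x = 0.5),
      sweep = list(CS = seq(0, 1, length.out = 11),
                   e = seq(0, 1, length.out = 11)),
      variants = list(theta = c(0, 0.1)),
      notes = c(beta0 = "0.7", CP = "0.5"))

  add("fig10",
      "2-D outcome diagram over (CS, e) at beta0 = 0.95, CP = 0.5, theta in {0, 0.1}",
      .base_params(beta0 = 0.95, theta = 0, CP = 0.5, x_mode = "dynamic"),
      initial_state(x = 0.5),
      sweep = list(CS = seq(0, 1, length.out = 11),
                   e = seq(0, 1, length.out = 11)),
      variants = list(theta = c(0, 0.1)),
      notes = c(beta0 = "0.95", CP = "0.5"))

  reg
})

#' Retrieve a scenario preset
#'
#' Returns a deep copy of a registered scenario: its parameter set,
#' initial state, the sweep that the corresponding experiment runs, any
#' registered variants, and the printed values backing each caption field
#' (in `notes`). Mutating the returned object cannot corrupt the
#' registry.
#'
#' @param name Preset name; see [list_presets()].
#' @return A list of class `ecoepi_preset` with fields `name`,
#'   `description`, `params`, `state0`, `sweep`, `variants`, `notes`.
#' @examples
#' pre <- get_preset("fig1")
#' pre$sweep
#' @export
get_preset <- function(name) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% names(.preset_registry)) {
    stop("unknown preset '", paste(name, collapse = ","),
         "'; available: ", paste(names(.preset_registry), collapse = ", "),
         call. = FALSE)
  }
  # R list copy semantics already give a deep copy
  p <- .preset_registry[[name]]
  class(p) <- "ecoepi_preset"
  p
}

#' Catalogue of scenario presets
#'
#' @return A tibble `name`, `description` in deterministic (registry)
#'   order.
#' @export
list_presets <- function() {
  tibble::tibble(
    name = names(.preset_registry),
    description = purrr::map_chr(.preset_registry, "description")
  )
}

#' Export a preset to a flat config list / YAML
#'
#' Serialises a preset's parameters, initial state and sweep to the flat
#' key-value layout used by the command line (`beta0`, `alpha1`, ...,
#' `S0`, `I0`, `P0`, `x0`).
#'
#' @param name Preset name.
#' @param file Optional path; when given, YAML is written there.
#' @return The flat config list, invisibly when `file` is given.
#' @export
preset_export <- function(name, file = NULL) {
  p <- get_preset(name)
  cfg <- c(p$params[.ecoepi_par_order],
           list(x_mode = p$params$x_mode, g_mode = p$params$g_mode,
                S0 = unname(p$state0[["S"]]), I0 = unname(p$state0[["I"]]),
                P0 = unname(p$state0[["P"]]), x0 = unname(p$state0[["x"]])))
  if (!is.null(p$sweep)) cfg$sweep <- p$sweep
  if (is.null(file)) return(cfg)
  yaml::write_yaml(cfg, file)
  invisible(cfg)
}

#' @export
print.ecoepi_preset <- function(x, ...) {
  cat("<ecoepi_preset>", x$name, "-", x$description, "\n")
  print(x$params)
  cat("state0:", paste(sprintf("%s=%g", names(x$state0), x$state0),
                       collapse = " "), "\n")
  if (!is.null(x$sweep)) {
    cat("sweep:", paste(names(x$sweep), collapse = ", "), "\n")
  }
  invisible(x)
}
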