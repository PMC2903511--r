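# ConfiguredSystem: the output contract of the chemical-specific model
# builders, and the machinery for combining several models over one shared
# body physiology into a joint multi-chemical system.

#' Create a configured chemical model
#'
#' Bundles everything a chemical-specific builder produces: the shared
#' body physiology, the species list, reaction network, transport
#' processes, default exposure hooks and parameter provenance. The object
#' is guaranteed to pass [assemble_system()] validation at construction.
#'
#' @param name Model name.
#' @param body Shared `body_physiology`.
#' @param chemicals List of [chemical_species()].
#' @param reactions Reaction list (`gamma`, `mm`).
#' @param transports List of [transport_process()].
#' @param exposures Default exposure hooks (may be empty).
#' @param volume_fns Named list of time-varying reporting volumes.
#' @param provenance List with `file` (the packaged parameter file every
#'   numeric parameter came from) and `note`.
#' @return A `configured_system`.
#' @export
configured_system <- function(name, body, chemicals, reactions = list(),
                              transports = list(), exposures = list(),
                              volume_fns = list(), provenance = list()) {
  cs <- structure(list(name = name, body = body, chemicals = chemicals,
                       reactions = reactions, transports = transports,
                       exposures = exposures, volume_fns = volume_fns,
                       provenance = provenance),
                  class = "configured_system")
  assemble_model(cs)  # fail fast if inconsistent
  cs
}

#' @export
print.configured_system <- function(x, ...) {
  cat(sprintf("configured_system '%s': %d species, %d first-order pathways, %d saturable reactions, %d transports\n",
              x$name, length(x$chemicals),
              length(x$reactions$gamma), length(x$reactions$mm),
              length(x$transports)))
  if (!is.null(x$provenance$file))
    cat("  parameters from:", x$provenance$file, "\n")
  invisible(x)
}

#' Assemble a configured model into an integrable system
#'
#' @param model A `configured_system` (or list of them, see
#'   [combine_models()]).
#' @param exposures Exposure profiles; defaults to the model's own hooks.
#' @param interactions Interaction specs.
#' @return A `pbtk_system`.
#' @export
assemble_model <- function(model, exposures = NULL, interactions = list()) {
  if (is.null(exposures)) exposures <- model$exposures
  assemble_system(model$body, model$chemicals, model$reactions,
                  model$transports, exposures, interactions,
                  model$volume_fns)
}

#' Combine chemical models over one shared physiology
#'
#' Merges several configured models into one joint `configured_system`.
#' All models must share the same body physiology (the central
#' harmonization requirement: one chemical-independent body for every
#' chemical).
#'
#' @param models List of `configured_system` objects.
#' @param name Name of the combined model.
#' @return A `configured_system` covering all species.
#' @export
combine_models <- function(models, name = "combined") {
  body <- models[[1L]]$body
  for (m in models[-1L]) {
    if (!isTRUE(all.equal(as.data.frame(body), as.data.frame(m$body))) ||
        abs(body$cardiac_output - m$body$cardiac_output) > 1e-12)
      stop(sprintf("model '%s' uses a different body physiology; all models must share one body", m$name))
  }
  configured_system(
    name = name, body = body,
    chemicals = do.call(c, lapply(models, `[[`, "chemicals")),
    reactions = list(gamma = do.call(c, lapply(models, function(m) m$reactions$gamma)),
                     mm = do.call(c, lapply(models, function(m) m$reactions$mm))),
    transports = do.call(c, lapply(models, `[[`, "transports")),
    exposures = do.call(c, lapply(models, `[[`, "exposures")),
    volume_fns = do.call(c, lapply(models, `[[`, "volume_fns")),
    provenance = list(file = unlist(lapply(models, function(m) m$provenance$file)),
                      note = "combined model")
  )
}

#' Combine models and keep their dose hooks
#'
#' Like [combine_models()] but also merges the per-chemical dose hooks so
#' [dietary_profile()] and friends keep working on the joint model.
#'
#' @inheritParams combine_models
#' @return A `configured_system`.
#' @export
combine_models_with_hooks <- function(models, name = "combined") {
  cs <- combine_models(models, name)
  cs$dose_hooks <- do.call(c, unname(lapply(models, `[[`, "dose_hooks")))
  for (m in models) if (!is.null(m$bone_states)) cs$bone_states <- m$bone_states
  cs
}

# read a packaged parameter file, allowing user overrides (shallow merge)
load_model_params <- function(file, params = NULL) {
  path <- system.file("extdata", file, package = "pbtkmix")
  if (!nzchar(path)) stop(sprintf("packaged parameter file '%s' not found", file))
  defaults <- yaml::read_yaml(path)
  if (!is.null(params)) defaults <- utils::modifyList(defaults, params)
  attr(defaults, "file") <- file
  defaults
}

# expand a transfers table (list of {from, to, k} / {from, route, k}) into
# transport_process objects for one chemical
transfers_to_transports <- function(chemical, transfers) {
  lapply(transfers, function(tr) {
    if (!is.null(tr$route)) {
      kind <- switch(tr$route,
                     urine = "urinary_excretion", feces = "fecal_excretion",
                     hair = "hair_excretion", milk = "milk_excretion",
                     stop(sprintf("unknown excretion route '%s'", tr$route)))
      transport_process(kind, chemical, source = tr$from, rate = tr$k)
    } else {
      transport_process("first_order_transfer", chemical, source = tr$from,
                        destination = tr$to, rate = tr$k)
    }
  })
}
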