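# Chemical-specific model builders for cadmium, lead and chromium.
# Builders contain structure only; every numeric parameter comes from the
# packaged per-model configuration file (overridable via `params`).

pool_states <- function(pools) {
  lapply(pools, function(p) list(compartment = p$name, scheme = "pool", volume = p$volume))
}

#' Build the cadmium biokinetic model
#'
#' A linear first-order transfer network in the classical human cadmium
#' biokinetic structure: sex-dependent fractional GI absorption into a
#' blood pool, accumulation in liver and kidney (metallothionein-bound)
#' and an aggregated other-tissue pool, slow urinary elimination from the
#' kidney plus a small filtered fraction from blood, and biliary/fecal
#' loss from the liver. All transfers are first-order, so the model is
#' linear: steady-state tissue concentrations scale proportionally with
#' intake.
#'
#' @param params Optional overrides of the packaged parameter file.
#' @param sex `"male"` or `"female"` (selects the absorbed fraction).
#' @param body Shared body physiology (default [reference_adult()]).
#' @return A `configured_system` with a `dose_hooks` entry for dietary
#'   dosing.
#' @export
build_cadmium_model <- function(params = NULL, sex = c("male", "female"),
                                body = reference_adult()) {
  sex <- match.arg(sex)
  p <- load_model_params("params_cadmium.yaml", params)
  for (req in c("molecular_mass", "absorption", "pools", "transfers"))
    if (is.null(p[[req]])) stop(sprintf("cadmium parameters: missing '%s'", req))
  F_abs <- if (sex == "male") p$absorption$F_abs_male else p$absorption$F_abs_female
  if (is.null(F_abs)) stop("cadmium parameters: missing absorbed fraction for ", sex)
  chem <- chemical_species("cadmium", p$molecular_mass, pool_states(p$pools))
  cs <- configured_system(
    name = "cadmium", body = body, chemicals = list(chem),
    transports = transfers_to_transports("cadmium", p$transfers),
    provenance = list(file = attr(p, "file"), note = p$provenance)
  )
  cs$dose_hooks <- list(cadmium = list(route = "oral_continuous", target = "blood",
                                       F_abs = F_abs, molecular_mass = p$molecular_mass))
  cs$cortex_kidney_ratio <- p$cortex_kidney_ratio
  cs
}

#' Build the lead biokinetic model
#'
#' Plasma/red-cell binding, liver, kidney and lumped soft tissues with
#' urinary elimination from plasma, plus the two-part skeleton that
#' dominates chronic lead kinetics: a trabecular bone pool with
#' formation/resorption exchange, and mature cortical bone discretized
#' into `n_shells` concentric cylindrical shell states exchanging by
#' radial diffusion, with the innermost shell in contact with blood.
#' Shells have equal thickness, so shell volumes grow as the odd numbers
#' `2k - 1` and the interface conductances scale with the interface
#' radius index.
#'
#' @param params Optional overrides of the packaged parameter file.
#' @param include_age_growth If `TRUE`, applies the simplified
#'   age-scaling of body mass and bone turnover for `age_years` (a
#'   piecewise-linear reduction of body size and acceleration of bone
#'   turnover for children).
#' @param age_years Age used when `include_age_growth` is `TRUE`.
#' @param body Shared body physiology.
#' @return A `configured_system` with a dietary dose hook.
#' @export
build_lead_model <- function(params = NULL, include_age_growth = FALSE,
                             age_years = 30, body = reference_adult()) {
  p <- load_model_params("params_lead.yaml", params)
  b <- p$bone
  if (is.null(b$n_shells) || b$n_shells < 1) stop("lead parameters: shell count must be >= 1")
  if (is.null(b$shell_conductance)) stop("lead parameters: missing diffusion (shell) conductance")
  if (include_age_growth) {
    # simplified growth hooks: children have smaller pools and faster bone
    # turnover; piecewise-linear ramp to adult values at age 18
    f_mass <- min(1, 0.1 + 0.9 * age_years / 18)
    f_turn <- if (age_years >= 18) 1 else 4 - 3 * age_years / 18
    p$pools <- lapply(p$pools, function(q) { q$volume <- q$volume * f_mass; q })
    b$cortical_volume <- b$cortical_volume * f_mass
    b$trabecular_return_k <- b$trabecular_return_k * f_turn
    b$cortical_return_k <- b$cortical_return_k * f_turn
  }
  n <- b$n_shells
  shell_names <- paste0("bone_cort_s", seq_len(n))
  wts <- 2 * seq_len(n) - 1                       # annulus volumes, equal thickness
  shell_vols <- b$cortical_volume * wts / sum(wts)
  shells <- Map(function(nm, v) list(compartment = nm, scheme = "pool", volume = v),
                shell_names, shell_vols)
  chem <- chemical_species("lead", p$molecular_mass, c(pool_states(p$pools), unname(shells)))

  tr <- transfers_to_transports("lead", p$transfers)
  tr <- c(tr, list(
    transport_process("bone_exchange", "lead", source = "plasma",
                      destination = "bone_trab", rate = b$trabecular_uptake_k),
    transport_process("bone_exchange", "lead", source = "bone_trab",
                      destination = "plasma", rate = b$trabecular_return_k),
    transport_process("bone_exchange", "lead", source = "plasma",
                      destination = shell_names[1], rate = b$cortical_uptake_k),
    transport_process("bone_exchange", "lead", source = shell_names[1],
                      destination = "plasma", rate = b$cortical_return_k)
  ))
  # radial diffusion between adjacent shells: conductance g_k = g0 * k
  # (interface area at radius index k), expressed as paired first-order
  # exchanges g_k * (C_k - C_k+1)
  if (n > 1) {
    for (k in seq_len(n - 1)) {
      g <- b$shell_conductance * k
      tr <- c(tr, list(
        transport_process("bone_exchange", "lead", source = shell_names[k],
                          destination = shell_names[k + 1], clearance = g),
        transport_process("bone_exchange", "lead", source = shell_names[k + 1],
                          destination = shell_names[k], clearance = g)
      ))
    }
  }
  cs <- configured_system(
    name = "lead", body = body, chemicals = list(chem), transports = tr,
    provenance = list(file = attr(p, "file"), note = p$provenance)
  )
  cs$dose_hooks <- list(lead = list(route = "oral_continuous", target = "plasma",
                                    F_abs = p$absorption$F_abs,
                                    molecular_mass = p$molecular_mass))
  cs$bone_states <- c("bone_trab", shell_names)
  cs
}

#' Add a tracer isotope sharing all lead parameters
#'
#' Clones the lead species, transports and dose hook under a new name
#' (e.g. `"lead204"`), so a tracer dose can be followed independently of
#' the stable-lead background while obeying identical kinetics.
#'
#' @param model A lead `configured_system` from [build_lead_model()].
#' @param tracer_name Name of the tracer chemical.
#' @return A `configured_system` containing both chemicals.
#' @export
add_lead_tracer <- function(model, tracer_name = "lead204") {
  src <- model$chemicals[[1]]
  tracer <- chemical_species(tracer_name, src$molecular_mass, src$states)
  tr_tracer <- lapply(model$transports, function(tp) { tp$chemical <- tracer_name; tp })
  cs <- configured_system(
    name = model$name, body = model$body,
    chemicals = c(model$chemicals, list(tracer)),
    reactions = model$reactions,
    transports = c(model$transports, tr_tracer),
    exposures = model$exposures, provenance = model$provenance
  )
  cs$dose_hooks <- model$dose_hooks
  cs$dose_hooks[[tracer_name]] <- model$dose_hooks$lead
  cs$bone_states <- model$bone_states
  cs
}

#' Build the chromium model
#'
#' Two tracked species: hexavalent chromium is absorbed and then rapidly
#' reduced to trivalent chromium in blood (a fast first-order reaction
#' edge), so Cr(VI) disappears from blood on the minutes scale; Cr(III)
#' distributes over a simplified lead-like skeleton (liver, kidney, bone,
#' soft tissue) with urinary elimination of both species.
#'
#' @param params Optional overrides of the packaged parameter file.
#' @param body Shared body physiology.
#' @return A `configured_system` with oral dose hooks for both species.
#' @export
build_chromium_model <- function(params = NULL, body = reference_adult()) {
  p <- load_model_params("params_chromium.yaml", params)
  if (is.null(p$reduction_k)) stop("chromium parameters: missing 'reduction_k'")
  cr6 <- chemical_species("cr6", p$molecular_mass, pool_states(p$pools_cr6))
  cr3 <- chemical_species("cr3", p$molecular_mass, pool_states(p$pools_cr3))
  cs <- configured_system(
    name = "chromium", body = body, chemicals = list(cr6, cr3),
    reactions = list(gamma = list(
      list(tissue = "blood", parent = "cr6", product = "cr3", k = p$reduction_k))),
    transports = c(transfers_to_transports("cr6", p$transfers_cr6),
                   transfers_to_transports("cr3", p$transfers_cr3)),
    provenance = list(file = attr(p, "file"), note = p$provenance)
  )
  cs$dose_hooks <- list(
    cr6 = list(route = "oral_bolus", target = "blood",
               F_abs = p$absorption$F_abs_cr6, molecular_mass = p$molecular_mass),
    cr3 = list(route = "oral_bolus", target = "blood",
               F_abs = p$absorption$F_abs_cr3, molecular_mass = p$molecular_mass)
  )
  cs
}
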