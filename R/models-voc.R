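# Volatile-organics (benzene/toluene) inhalation model and dosing helpers
# shared by all builders.

#' Build the benzene/toluene inhalation model
#'
#' Whole-body perfusion-limited PBTK for the two volatile organics on the
#' shared physiology: continuous alveolar uptake and first-order
#' exhalation (gas exchange against the blood:air partition), tissue
#' distribution by tissue:blood partition coefficients, and hepatic
#' saturable oxidation with mutual competitive inhibition (each chemical
#' raises the other's apparent K_m through its inhibition constant).
#'
#' @param params Optional overrides of the packaged parameter file.
#' @param mutual_inhibition Wire the benzene/toluene competitive
#'   inhibition constants (`TRUE` by default; set `FALSE` for independent
#'   single-chemical kinetics).
#' @param body Shared body physiology.
#' @return A `configured_system` with inhalation dose hooks.
#' @export
build_voc_model <- function(params = NULL, mutual_inhibition = TRUE,
                            body = reference_adult()) {
  p <- load_model_params("params_voc.yaml", params)
  qalv <- p$alveolar_ventilation
  mk_species <- function(nm) {
    cp <- p[[nm]]
    if (is.null(cp$partition)) stop(sprintf("voc parameters: missing partition set for '%s'", nm))
    states <- c(list(list(compartment = "blood", scheme = "blood")),
                lapply(names(cp$partition), function(tis)
                  list(compartment = tis, scheme = "perfusion", P = cp$partition[[tis]])))
    chemical_species(nm, cp$molecular_mass, states)
  }
  benzene <- mk_species("benzene")
  toluene <- mk_species("toluene")
  comp_b <- if (mutual_inhibition) c(toluene = p$mutual_inhibition$I_toluene_on_benzene) else numeric()
  comp_t <- if (mutual_inhibition) c(benzene = p$mutual_inhibition$I_benzene_on_toluene) else numeric()
  mm <- list(
    mm_reaction("liver", "benzene", product = NA, V_max = p$benzene$V_max,
                K_m = p$benzene$K_m, competitive = comp_b, name = "benzene_oxidation"),
    mm_reaction("liver", "toluene", product = NA, V_max = p$toluene$V_max,
                K_m = p$toluene$K_m, competitive = comp_t, name = "toluene_oxidation")
  )
  tr <- list(
    transport_process("gas_exchange", "benzene", source = "blood",
                      clearance = qalv / p$benzene$blood_air_partition),
    transport_process("gas_exchange", "toluene", source = "blood",
                      clearance = qalv / p$toluene$blood_air_partition)
  )
  cs <- configured_system(
    name = "voc", body = body, chemicals = list(benzene, toluene),
    reactions = list(mm = mm), transports = tr,
    provenance = list(file = attr(p, "file"), note = p$provenance)
  )
  cs$dose_hooks <- list(
    benzene = list(route = "inhalation", target = "blood",
                   alveolar_ventilation = qalv,
                   molecular_mass = p$benzene$molecular_mass),
    toluene = list(route = "inhalation", target = "blood",
                   alveolar_ventilation = qalv,
                   molecular_mass = p$toluene$molecular_mass)
  )
  cs
}

# ---- dose hooks -----------------------------------------------------------

model_hook <- function(model, chemical) {
  hk <- model$dose_hooks[[chemical]]
  if (is.null(hk)) stop(sprintf("model '%s' has no dose hook for chemical '%s'",
                                model$name, chemical))
  hk
}

#' Continuous dietary exposure for a model chemical
#'
#' Builds an `oral_continuous` exposure profile using the model's dose
#' hook (absorbed fraction, target state, molecular mass).
#'
#' @param model A `configured_system` with dose hooks.
#' @param chemical Chemical name.
#' @param ug_per_day Intake rate (ug/day); or use `ug_per_kg_day`.
#' @param ug_per_kg_day Intake per kg body mass per day.
#' @param start,end Event window (h).
#' @return An [exposure_profile()].
#' @export
dietary_profile <- function(model, chemical, ug_per_day = NULL,
                            ug_per_kg_day = NULL, start = 0, end = Inf) {
  hk <- model_hook(model, chemical)
  rate <- if (!is.null(ug_per_day))
    convert_dose(ug_per_day, "ug/day", hk$molecular_mass)
  else convert_dose(ug_per_kg_day, "ug/kg/day", hk$molecular_mass,
                    body_mass = model$body$body_mass)
  exposure_profile(chemical, "oral_continuous",
                   events = list(list(start = start, end = end, magnitude = rate)),
                   F_abs = hk$F_abs, target = hk$target)
}

#' Oral bolus exposure for a model chemical
#'
#' @inheritParams dietary_profile
#' @param ug Dose (ug); or `mg` for milligram doses.
#' @param mg Dose (mg).
#' @param time Dosing time (h).
#' @return An [exposure_profile()].
#' @export
bolus_profile <- function(model, chemical, ug = NULL, mg = NULL, time = 0) {
  hk <- model_hook(model, chemical)
  amt <- if (!is.null(ug)) convert_dose(ug, "ug", hk$molecular_mass)
         else convert_dose(mg, "mg", hk$molecular_mass)
  exposure_profile(chemical, "oral_bolus",
                   events = list(list(time = time, amount = amt)),
                   F_abs = hk$F_abs, target = hk$target)
}

#' Inhalation exposure for a model chemical
#'
#' @inheritParams dietary_profile
#' @param ppm Air concentration (ppm v/v), converted via the ideal-gas
#'   molar volume at 25 degrees C.
#' @return An [exposure_profile()].
#' @export
inhalation_profile <- function(model, chemical, ppm, start = 0, end = Inf) {
  hk <- model_hook(model, chemical)
  exposure_profile(chemical, "inhalation",
                   events = list(list(start = start, end = end,
                                      magnitude = convert_dose(ppm, "ppm"))),
                   target = hk$target,
                   alveolar_ventilation = hk$alveolar_ventilation)
}
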