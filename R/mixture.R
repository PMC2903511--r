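# The metals + volatile-organics mixture case study: joint simulation of
# cadmium, methylmercury, lead, arsenic (and metabolites), toluene and
# benzene with competitive inhibition between the organics and a lagged
# metal -> metabolism interaction in the liver.

#' Default configuration of the mixture case study
#'
#' Continuous dietary metal intakes (15/40/70/100 ug/day of cadmium,
#' methylmercury, lead and inorganic arsenic), inhalation of 20 ppm
#' toluene and 10 ppm benzene, a 40% step increase of the metal intakes
#' (organics unchanged) at day 500, and a birth-to-age-30 cadmium pre-run
#' at 0.2 ug/kg/day whose tissue levels seed the short-term simulation.
#'
#' @param t_end_day Simulation length (days).
#' @param report_dt_h Reporting step (h).
#' @return Configuration list consumed by [run_mixture_scenario()].
#' @export
mixture_config <- function(t_end_day = 700, report_dt_h = 48) {
  list(
    cadmium_ug_day = 15, mehg_ug_day = 40, lead_ug_day = 70, arsenic_ug_day = 100,
    toluene_ppm = 20, benzene_ppm = 10,
    step_day = 500, step_factor = 1.4,
    prerun_cd_ug_kg_day = 0.2, prerun_years = 30,
    total_effect = 0.25,       # targeted baseline steady-state V_max decrease
    tau_h = 24,                # interaction lag time-constant
    t_end_day = t_end_day, report_dt_h = report_dt_h,
    rtol = 1e-8, atol = 1e-12
  )
}

mixture_models <- function(body = reference_adult()) {
  list(cadmium = build_cadmium_model(body = body),
       mehg = build_mehg_model(body = body),
       lead = build_lead_model(body = body),
       arsenic = build_arsenic_model(body = body),
       voc = build_voc_model(body = body))
}

#' Steady-state cadmium burden from a birth-to-age pre-run
#'
#' Runs the cadmium model alone for `years` at `ug_per_kg_day` and
#' returns the final tissue amounts keyed by state, for use as the
#' initial condition of short-term mixture simulations (the hepatic
#' cadmium half-life is far too long for a 500-day run to reach its own
#' steady state).
#'
#' @param ug_per_kg_day Chronic intake (ug per kg body mass per day).
#' @param years Pre-run length (years).
#' @param body Shared body physiology.
#' @return Named numeric vector of amounts (umol) keyed by state key.
#' @export
cadmium_prerun <- function(ug_per_kg_day = 0.2, years = 30,
                           body = reference_adult()) {
  cd <- build_cadmium_model(body = body)
  expo <- list(dietary_profile(cd, "cadmium", ug_per_kg_day = ug_per_kg_day))
  sys <- assemble_model(cd, exposures = expo)
  t_end <- years * 365.25 * 24
  res <- simulate_system(sys, t_end, report_grid = seq(0, t_end, length.out = 61))
  final <- res$amounts[nrow(res$amounts), ]
  final[final > 0]
}

# exposure set of the mixture study; the day-500 scaling switch applies to
# the metals only ("exposure to toluene and benzene remained constant")
mixture_exposures <- function(model, cfg) {
  profs <- list(
    dietary_profile(model, "cadmium", cfg$cadmium_ug_day),
    dietary_profile(model, "mehg", cfg$mehg_ug_day),
    dietary_profile(model, "lead", cfg$lead_ug_day),
    dietary_profile(model, "as5", cfg$arsenic_ug_day),
    inhalation_profile(model, "toluene", cfg$toluene_ppm),
    inhalation_profile(model, "benzene", cfg$benzene_ppm)
  )
  scale_intakes(profs, cfg$step_factor, cfg$step_day * 24,
                chemicals = c("cadmium", "mehg", "lead", "as5"))
}

# liver concentrations of the four metals (total arsenic summed over its
# six species) at a reference row of a mixture result
metal_liver_concentrations <- function(res, as_species) {
  i <- which.min(abs(res$time - max(res$time)))
  c(cadmium = concentration(res, "cadmium", "liver")[i],
    lead = concentration(res, "lead", "liver")[i],
    mehg = concentration(res, "mehg", "liver")[i],
    arsenic_total = sum(vapply(as_species, function(s)
      concentration(res, s, "liver")[i], numeric(1))))
}

#' Run the mixture case study
#'
#' Runs the joint seven-chemical simulation (five metals plus benzene and
#' toluene, with the arsenic metabolites tracked as additional species):
#' first the base case with no metal-to-organics interaction, then one
#' variant per entry of `variant_multipliers`, each scaling the
#' interaction weights by that factor. Interaction weights follow the
#' equal-contribution rule: at the base-case liver concentrations
#' reached just before the intake step, each of the four metals (total
#' arsenic counted as one) contributes equally to the targeted
#' steady-state fractional V_max decrease `total_effect`.
#'
#' @param config Configuration from [mixture_config()].
#' @param variant_multipliers Numeric vector of weight multipliers for the
#'   interaction variants (0 = base case is reused).
#' @param body Shared body physiology.
#' @param init Optional initial amounts; defaults to the cadmium pre-run.
#' @return List with `results` (named `pbtk_result` list: `base` plus
#'   `variant_x<multiplier>`), `weights`, `config`.
#' @export
run_mixture_scenario <- function(config = mixture_config(),
                                 variant_multipliers = c(0.5, 1, 2),
                                 body = reference_adult(), init = NULL) {
  models <- mixture_models(body)
  joint <- combine_models_with_hooks(models, name = "mixture")
  as_species <- vapply(models$arsenic$chemicals, `[[`, character(1), "name")
  if (is.null(init))
    init <- cadmium_prerun(config$prerun_cd_ug_kg_day, config$prerun_years, body)
  expo <- mixture_exposures(joint, config)
  t_end <- config$t_end_day * 24
  grid <- seq(0, t_end, by = config$report_dt_h)

  base_sys <- assemble_model(joint, exposures = expo)
  base <- simulate_system(base_sys, t_end, report_grid = grid, init = init,
                          rtol = config$rtol, atol = config$atol)

  # equal-contribution weights at the pre-step baseline
  i_base <- which.min(abs(base$time - config$step_day * 24))
  base_conc <- c(cadmium = concentration(base, "cadmium", "liver")[i_base],
                 lead = concentration(base, "lead", "liver")[i_base],
                 mehg = concentration(base, "mehg", "liver")[i_base],
                 arsenic_total = sum(vapply(as_species, function(s)
                   concentration(base, s, "liver")[i_base], numeric(1))))
  w <- equal_contribution_weights(base_conc, config$total_effect)
  sources <- c(
    list(list(chemical = "cadmium", compartment = "liver", weight = w[["cadmium"]]),
         list(chemical = "lead", compartment = "liver", weight = w[["lead"]]),
         list(chemical = "mehg", compartment = "liver", weight = w[["mehg"]])),
    lapply(as_species, function(s)
      list(chemical = s, compartment = "liver", weight = w[["arsenic_total"]]))
  )

  results <- list(base = base)
  for (m in variant_multipliers) {
    if (m == 0) { results[["variant_x0"]] <- base; next }
    spec <- interaction_spec(
      "metal_vmax_modulation",
      targets = c("benzene_oxidation", "toluene_oxidation"),
      sources = lapply(sources, function(s) { s$weight <- s$weight * m; s }),
      tau = config$tau_h, name = sprintf("metal_modulation_x%g", m))
    sys <- assemble_model(joint, exposures = expo, interactions = list(spec))
    results[[sprintf("variant_x%g", m)]] <-
      simulate_system(sys, t_end, report_grid = grid, init = init,
                      rtol = config$rtol, atol = config$atol)
  }
  list(results = results, weights = w, config = config)
}
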