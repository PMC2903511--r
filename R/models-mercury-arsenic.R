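# Builders for methylmercury (with optional pregnancy subsystem) and the
# six-species arsenic metabolic network.

#' Build the methylmercury model
#'
#' Two tracked species: methylmercury distributes to brain (it crosses the
#' blood-brain barrier), liver, kidney and remaining tissues; it is
#' excreted in urine, hair and feces (and breast milk when lactation is
#' configured) and slowly demethylated to inorganic mercury in a
#' configurable set of tissues (default: throughout the body). Inorganic
#' mercury accumulates renally and leaves in urine and feces. The
#' pregnancy flag adds a fetal compartment with bidirectional placental
#' transfer and a fetal volume that grows linearly over gestation (used
#' for concentration reporting); transfer parameters default to a regime
#' in which fetal blood concentration exceeds maternal blood.
#'
#' @param params Optional overrides of the packaged parameter file.
#' @param pregnancy Add the fetal subsystem.
#' @param lactation Enable the breast-milk excretion route (ledger only).
#' @param body Shared body physiology.
#' @return A `configured_system` with a dietary dose hook for
#'   methylmercury.
#' @export
build_mehg_model <- function(params = NULL, pregnancy = FALSE,
                             lactation = FALSE, body = reference_adult()) {
  p <- load_model_params("params_mercury.yaml", params)
  states_mehg <- pool_states(p$pools_mehg)
  volume_fns <- list()
  if (pregnancy) {
    pg <- p$pregnancy
    if (is.null(pg) || is.null(pg$maternal_to_fetal_k))
      stop("pregnancy flag set but fetal parameters are missing")
    states_mehg <- c(states_mehg,
                     list(list(compartment = "fetal", scheme = "pool",
                               volume = pg$fetal_volume_final)))
    v0 <- pg$fetal_volume_initial; v1 <- pg$fetal_volume_final; tg <- pg$gestation_h
    volume_fns[[state_key("mehg", "fetal")]] <-
      function(t) v0 + (v1 - v0) * min(t / tg, 1)
  }
  mehg <- chemical_species("mehg", p$molecular_mass_mehg, states_mehg)
  ihg <- chemical_species("ihg", p$molecular_mass_ihg, pool_states(p$pools_ihg))

  tr <- c(transfers_to_transports("mehg", p$transfers_mehg),
          transfers_to_transports("ihg", p$transfers_ihg))
  if (pregnancy) {
    pg <- p$pregnancy
    tr <- c(tr, list(
      transport_process("first_order_transfer", "mehg", source = "blood",
                        destination = "fetal", rate = pg$maternal_to_fetal_k),
      transport_process("first_order_transfer", "mehg", source = "fetal",
                        destination = "blood", rate = pg$fetal_to_maternal_k)
    ))
  }
  if (lactation && p$lactation$milk_k > 0) {
    tr <- c(tr, list(transport_process("milk_excretion", "mehg",
                                       source = "blood", rate = p$lactation$milk_k)))
  }
  gam <- lapply(p$demethylation_tissues, function(tis)
    list(tissue = tis, parent = "mehg", product = "ihg", k = p$demethylation_k))
  # demethylation edges only where both species have a state; brain MeHg
  # demethylation (if configured) transforms into the iHg 'rest' bucket
  ihg_comps <- vapply(p$pools_ihg, `[[`, character(1), "name")
  gam <- Filter(function(g) g$tissue %in% ihg_comps, gam)

  cs <- configured_system(
    name = "mehg", body = body, chemicals = list(mehg, ihg),
    reactions = list(gamma = gam), transports = tr,
    volume_fns = volume_fns,
    provenance = list(file = attr(p, "file"), note = p$provenance)
  )
  cs$dose_hooks <- list(mehg = list(route = "oral_continuous", target = "blood",
                                    F_abs = p$absorption$F_abs,
                                    molecular_mass = p$molecular_mass_mehg))
  cs
}

#' Build the arsenic metabolic-network model
#'
#' Six tracked species (inorganic arsenate and arsenite, mono- and
#' dimethylated arsenicals in both oxidation states) distributed by
#' perfusion-limited flow over the shared physiology, with hepatic
#' metabolism forming the canonical six-step network:
#' (1) reduction of As(V) to As(III); (2) methylation of As(III) to
#' MMA(V); (3) methylation of As(III) to DMA(V); (4) reduction of MMA(V)
#' to MMA(III); (5) methylation of MMA(III) to DMA(V); (6) reduction of
#' DMA(V) to DMA(III). Methylations (steps 2, 3 and 5) are saturable
#' AS3MT reactions; step 2 is noncompetitively inhibited by liver MMA(III)
#' and step 5 by liver As(III). Small first-order oxidations run every
#' trivalent species back to its pentavalent form; demethylation does not
#' occur. Urinary excretion is the only elimination route.
#'
#' @param params Optional overrides of the packaged parameter file.
#' @param body Shared body physiology.
#' @return A `configured_system` with a dietary dose hook for arsenate
#'   (`as5`) and arsenite (`as3`).
#' @export
build_arsenic_model <- function(params = NULL, body = reference_adult()) {
  p <- load_model_params("params_arsenic.yaml", params)
  sp_names <- unlist(p$species)
  chems <- lapply(sp_names, function(s) {
    part <- p$partition[[s]]
    if (is.null(part)) stop(sprintf("arsenic parameters: missing partition set for species '%s'", s))
    states <- c(list(list(compartment = "blood", scheme = "blood")),
                lapply(unlist(p$compartments), function(cmp) {
                  if (is.null(part[[cmp]]))
                    stop(sprintf("arsenic parameters: species '%s' missing partition for '%s'", s, cmp))
                  list(compartment = cmp, scheme = "perfusion", P = part[[cmp]])
                }))
    chemical_species(s, p$molecular_mass, states)
  })
  m <- p$metabolism
  gam <- list(
    list(tissue = "liver", parent = "as5", product = "as3", k = m$step1_reduction_k),
    list(tissue = "liver", parent = "mma5", product = "mma3", k = m$step4_reduction_k),
    list(tissue = "liver", parent = "dma5", product = "dma3", k = m$step6_reduction_k),
    # back-oxidation, small, for all trivalent species; no demethylation
    list(tissue = "liver", parent = "as3", product = "as5", k = m$oxidation_k),
    list(tissue = "liver", parent = "mma3", product = "mma5", k = m$oxidation_k),
    list(tissue = "liver", parent = "dma3", product = "dma5", k = m$oxidation_k)
  )
  mm <- list(
    mm_reaction("liver", "as3", "mma5", V_max = m$step2_methylation$V_max,
                K_m = m$step2_methylation$K_m,
                modifiers = list(list(kind = "noncompetitive", chemical = "mma3",
                                      compartment = "liver",
                                      K = m$step2_methylation$K_nc_by_mma3)),
                name = "as3_methylation_mma"),
    mm_reaction("liver", "as3", "dma5", V_max = m$step3_methylation$V_max,
                K_m = m$step3_methylation$K_m, name = "as3_methylation_dma"),
    mm_reaction("liver", "mma3", "dma5", V_max = m$step5_methylation$V_max,
                K_m = m$step5_methylation$K_m,
                modifiers = list(list(kind = "noncompetitive", chemical = "as3",
                                      compartment = "liver",
                                      K = m$step5_methylation$K_nc_by_as3)),
                name = "mma3_methylation_dma")
  )
  tr <- lapply(sp_names, function(s)
    transport_process("urinary_excretion", s, source = "blood",
                      clearance = p$urinary_clearance[[s]]))
  cs <- configured_system(
    name = "arsenic", body = body, chemicals = chems,
    reactions = list(gamma = gam, mm = mm), transports = tr,
    provenance = list(file = attr(p, "file"), note = p$provenance)
  )
  cs$dose_hooks <- list(
    as5 = list(route = "oral_continuous", target = "blood",
               F_abs = p$absorption$F_abs, molecular_mass = p$molecular_mass),
    as3 = list(route = "oral_continuous", target = "blood",
               F_abs = p$absorption$F_abs, molecular_mass = p$molecular_mass)
  )
  cs
}
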