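#' Perfusion-limited tissue concentration balance
#'
#' Rate of change of tissue concentration when the tissue equilibrates
#' instantaneously with its exiting blood, so the outlet concentration is
#' `C_tissue / P`:
#' `dC/dt = (Q * (C_in - C_tissue / P) + source_sink) / V`.
#'
#' @param C_tissue Tissue concentration (umol/L).
#' @param C_in Inlet (arterial) concentration (umol/L).
#' @param Q Tissue blood flow (L/h).
#' @param V Tissue volume (L).
#' @param P Tissue:blood partition coefficient (dimensionless).
#' @param source_sink Net local source term (umol/h); negative = loss.
#' @return dC/dt (umol/L/h).
#' @export
perfusion_tissue_rate <- function(C_tissue, C_in, Q, V, P, source_sink = 0) {
  stopifnot(V > 0, P > 0)
  (Q * (C_in - C_tissue / P) + source_sink) / V
}

#' Trans-membrane permeation rate
#'
#' Diffusive flux between the extracellular and cellular spaces of a
#' diffusion-limited tissue, positive into the cellular space. The default
#' driving force is `H * (C_E - C_C / P)`; model dialects that place the
#' partition on the extracellular side can request
#' `convention = "extracellular_partitioned"` for `H * (C_E / P - C_C)`.
#'
#' @param C_E Extracellular concentration (umol/L).
#' @param C_C Cellular concentration (umol/L).
#' @param H Permeability-area product (L/h).
#' @param P Tissue:blood partition coefficient.
#' @param convention Driving-force convention (see Details).
#' @return Permeation rate (umol/h), positive into the cellular space.
#' @export
permeation_rate <- function(C_E, C_C, H, P,
                            convention = c("cellular_partitioned", "extracellular_partitioned")) {
  stopifnot(H >= 0, P > 0)
  convention <- match.arg(convention)
  if (convention == "cellular_partitioned") H * (C_E - C_C / P)
  else H * (C_E / P - C_C)
}

#' Diffusion-limited tissue concentration balances
#'
#' Two-subcompartment mass balance for a tissue whose uptake is limited by
#' a membrane permeability rather than blood flow. The outlet concentration
#' equals the extracellular concentration:
#' `dC_E/dt = (Q*(C_in - C_E) - permeation + source_sink_E)/V_E`,
#' `dC_C/dt = (permeation + source_sink_C)/V_C`.
#'
#' @inheritParams permeation_rate
#' @param C_in Inlet (arterial) concentration (umol/L).
#' @param Q Tissue blood flow (L/h).
#' @param V_E,V_C Extracellular and cellular volumes (L).
#' @param source_sink_E,source_sink_C Local source terms (umol/h).
#' @return Named numeric vector `c(dC_E, dC_C)` (umol/L/h).
#' @export
diffusion_tissue_rates <- function(C_E, C_C, C_in, Q, V_E, V_C, H, P,
                                   source_sink_E = 0, source_sink_C = 0,
                                   convention = "cellular_partitioned") {
  stopifnot(V_E > 0, V_C > 0)
  perm <- permeation_rate(C_E, C_C, H, P, convention)
  c(dC_E = (Q * (C_in - C_E) - perm + source_sink_E) / V_E,
    dC_C = (perm + source_sink_C) / V_C)
}

#' Build the net first-order rate-constant matrix
#'
#' Assembles the per-tissue matrix of net first-order metabolic rate
#' constants from a list of pathways `parent -> product` with rate `k`.
#' For each pathway the parent's diagonal entry gains `+k` and, when the
#' product is a tracked species, the off-diagonal `(product, parent)` entry
#' gains `-k`, so the formation rate of the product is the negative of the
#' parent's loss. Columns of an all-tracked network therefore sum to zero;
#' pathways whose product is untracked (`NA` or absent from `species`)
#' leave a positive column sum, i.e. a net loss to a metabolic sink.
#'
#' @param pathways List of pathways, each `list(parent=, product=, k=)`
#'   (`product = NA` for an untracked sink); or a data.frame with those
#'   columns.
#' @param species Character vector of tracked species names fixing row and
#'   column order. Defaults to the union of parents and tracked products.
#' @return Square matrix (1/h) with species names on both dimensions.
#' @export
build_gamma_matrix <- function(pathways, species = NULL) {
  if (is.data.frame(pathways))
    pathways <- lapply(seq_len(nrow(pathways)), function(i) as.list(pathways[i, ]))
  parents <- vapply(pathways, function(p) as.character(p$parent), character(1))
  products <- vapply(pathways, function(p) {
    pr <- p$product
    if (is.null(pr) || length(pr) == 0L || is.na(pr)) NA_character_ else as.character(pr)
  }, character(1))
  ks <- vapply(pathways, function(p) as.numeric(p$k), numeric(1))
  if (any(ks < 0)) stop("pathway rate constants must be >= 0")
  if (any(!is.na(products) & products == parents)) stop("pathway parent must differ from product")
  if (is.null(species)) species <- unique(c(parents, products[!is.na(products)]))
  if (length(bad <- setdiff(parents, species)))
    stop("unknown species name(s): ", paste(bad, collapse = ", "))
  n <- length(species)
  G <- matrix(0, n, n, dimnames = list(species, species))
  for (i in seq_along(pathways)) {
    a <- parents[i]; b <- products[i]; k <- ks[i]
    G[a, a] <- G[a, a] + k
    if (!is.na(b) && b %in% species) G[b, a] <- G[b, a] - k
  }
  G
}

#' First-order metabolic rate contributions
#'
#' Net first-order metabolic rates for all species in one tissue, as the
#' matrix product of the rate-constant matrix with the concentration
#' vector. A positive entry is a net metabolic loss of that species, a
#' negative entry net formation.
#'
#' @param gamma Square rate-constant matrix (1/h) from
#'   [build_gamma_matrix()].
#' @param y Concentration vector (umol/L), same length/order as `gamma`.
#' @return Net loss-rate vector (umol/L/h).
#' @export
first_order_metabolic_rates <- function(gamma, y) {
  if (length(y) != ncol(gamma)) stop("dimension mismatch between gamma and y")
  drop(gamma %*% y)
}

#' Effective maximum reaction velocity under modifiers
#'
#' Applies noncompetitive inhibition, enzyme induction and mixture
#' interaction effects multiplicatively to a baseline `V_max`:
#' each noncompetitive modifier contributes `1 / (1 + C / K_nc)`, each
#' induction modifier `1 + f_ind`, and each interaction effect
#' `max(0, 1 - E)` (clamped so the effective velocity is never negative).
#' The product is order-independent.
#'
#' @param V_max Baseline maximum velocity (umol/h).
#' @param modifiers List of modifier descriptors:
#'   `list(kind = "noncompetitive", conc = C, K = K_nc)`,
#'   `list(kind = "induction", factor = f_ind)`, or
#'   `list(kind = "interaction", effect = E)`.
#' @return Effective V_max (umol/h).
#' @export
effective_vmax <- function(V_max, modifiers = list()) {
  v <- V_max
  for (m in modifiers) {
    v <- v * switch(m$kind,
      noncompetitive = {
        if (m$K <= 0) stop("noncompetitive modifier needs K > 0")
        1 / (1 + max(m$conc, 0) / m$K)
      },
      induction = {
        if (m$factor < 0) stop("induction factor must be >= 0")
        1 + m$factor
      },
      interaction = max(0, 1 - m$effect),
      stop(sprintf("unknown modifier kind '%s'", m$kind))
    )
  }
  v
}

#' Multi-chemical Michaelis-Menten metabolic rate
#'
#' Rate of metabolism of chemical `i` under saturable enzyme kinetics with
#' competitive inhibition by co-occurring chemicals:
#' `v = Vmax_eff * C_i / (K_m * (1 + sum_k C_k / I_k) + C_i)`,
#' where `Vmax_eff` is the [effective_vmax()] of the reaction under its
#' modifiers. With no inhibitors this is plain Michaelis-Menten; at
#' `C_i << K_m` it reduces to a first-order rate with
#' `k = Vmax / (K_m * V_tissue)` on a concentration basis.
#'
#' @param i Name of the metabolized chemical (must index into `C`).
#' @param C Named concentration vector over chemicals (umol/L).
#' @param rxn An [mm_reaction()] (fields `V_max`, `K_m`, `competitive`
#'   named vector of inhibition constants, `modifiers`).
#' @param modifier_values Optional list of resolved modifier descriptors
#'   overriding `rxn$modifiers` (used by the engine at integration time).
#' @return Metabolic rate (umol/h).
#' @export
mm_metabolic_rate <- function(i, C, rxn, modifier_values = NULL) {
  Ci <- max(C[[i]], 0)
  mods <- if (is.null(modifier_values)) rxn$modifiers else modifier_values
  vmax <- effective_vmax(rxn$V_max, mods)
  inh <- 0
  if (length(rxn$competitive)) {
    for (k in names(rxn$competitive)) {
      if (!is.null(C[[k]])) inh <- inh + max(C[[k]], 0) / rxn$competitive[[k]]
    }
  }
  vmax * Ci / (rxn$K_m * (1 + inh) + Ci)
}

#' Define a saturable metabolic reaction
#'
#' @param tissue Compartment in which the reaction occurs.
#' @param substrate Metabolized chemical name.
#' @param product Tracked product chemical name, or `NA` for an untracked
#'   sink (losses go to the transformation ledger either way).
#' @param V_max Maximum reaction velocity (umol/h).
#' @param K_m Michaelis constant (umol/L).
#' @param competitive Named numeric vector of competitive inhibition
#'   constants `I_k` (umol/L) keyed by inhibiting chemical.
#' @param modifiers List of V_max modifiers; structural forms
#'   `list(kind = "noncompetitive", chemical =, compartment =, K =)` and
#'   `list(kind = "induction", factor =)` are resolved by the engine.
#' @param name Optional reaction label (used to target interactions).
#' @return An `mm_reaction` object.
#' @export
mm_reaction <- function(tissue, substrate, product = NA, V_max, K_m,
                        competitive = numeric(), modifiers = list(), name = NULL) {
  if (V_max < 0) stop("V_max must be >= 0")
  if (K_m <= 0) stop("K_m must be > 0")
  if (length(competitive) && any(competitive <= 0)) stop("competitive inhibition constants must be > 0")
  structure(list(tissue = tissue, substrate = substrate, product = product,
                 V_max = V_max, K_m = K_m, competitive = competitive,
                 modifiers = modifiers,
                 name = if (is.null(name)) paste0(substrate, "_", tissue, "_mm") else name),
            class = "mm_reaction")
}

#' Define a transport process
#'
#' First-order transport of one chemical between states or out of the body
#' to an excretion ledger. `rate` is a first-order constant (1/h) applied
#' to the source amount; alternatively `clearance` (L/h) is applied to the
#' source concentration. Excretion kinds route to the chemical's mass
#' ledger under `route`; `gas_exchange` is the alveolar washout term and
#' routes to the `exhaled` ledger.
#'
#' @param kind One of `"first_order_transfer"`, `"urinary_excretion"`,
#'   `"fecal_excretion"`, `"hair_excretion"`, `"biliary"`,
#'   `"bone_exchange"`, `"gi_absorption"`, `"gas_exchange"`,
#'   `"milk_excretion"`.
#' @param chemical Chemical name.
#' @param source Source state: compartment name, or `c(compartment, sub)`.
#' @param destination Destination state (same forms) for transfer kinds;
#'   ignored for excretions.
#' @param rate First-order rate constant (1/h); give this or `clearance`.
#' @param clearance Clearance (L/h) applied to the source concentration.
#' @return A `transport_process` object.
#' @export
transport_process <- function(kind, chemical, source, destination = NULL,
                              rate = NULL, clearance = NULL) {
  kinds <- c("first_order_transfer", "urinary_excretion", "fecal_excretion",
             "hair_excretion", "biliary", "bone_exchange", "gi_absorption",
             "gas_exchange", "milk_excretion")
  if (!kind %in% kinds) stop(sprintf("unknown transport kind '%s'", kind))
  if (is.null(rate) == is.null(clearance))
    stop("give exactly one of 'rate' (1/h) or 'clearance' (L/h)")
  if (!is.null(rate) && rate < 0) stop("transport rate must be >= 0")
  if (!is.null(clearance) && clearance < 0) stop("transport clearance must be >= 0")
  route <- switch(kind,
                  urinary_excretion = "urine", fecal_excretion = "feces",
                  hair_excretion = "hair", gas_exchange = "exhaled",
                  milk_excretion = "milk", biliary = NULL, NULL)
  structure(list(kind = kind, chemical = chemical,
                 source = as.character(source), destination =
                   if (is.null(destination)) NULL else as.character(destination),
                 rate = rate, clearance = clearance, route = route),
            class = "transport_process")
}

#' Define a chemical species
#'
#' A chemical (or tracked metabolite) with its molecular mass and the set
#' of body states it occupies. Each state entry gives the compartment, the
#' mass-balance scheme linking it to blood, and the chemical-specific
#' parameters:
#' \describe{
#'   \item{`blood`}{the central distribution pool (required when any
#'     perfusion/diffusion state exists).}
#'   \item{`perfusion`}{flow-limited tissue; needs partition coefficient
#'     `P`.}
#'   \item{`diffusion`}{membrane-limited tissue; needs `P` and
#'     permeability-area product `H` (L/h); expands to extracellular and
#'     cellular sub-states.}
#'   \item{`pool`}{a chemical-specific storage state (plasma/RBC sub-pools,
#'     bone shells, gut lumen) coupled only through explicit transport
#'     processes; may carry its own `volume` (L).}
#' }
#'
#' @param name Chemical name.
#' @param molecular_mass Molar mass (g/mol), > 0.
#' @param states List of state entries
#'   `list(compartment=, scheme=, P=, H=, volume=, f_extracellular=)`.
#' @return A `chemical_species` object.
#' @export
chemical_species <- function(name, molecular_mass, states) {
  if (!is.finite(molecular_mass) || molecular_mass <= 0)
    stop(sprintf("chemical '%s': molecular_mass must be > 0", name))
  for (st in states) {
    if (is.null(st$compartment)) stop(sprintf("chemical '%s': state without compartment", name))
    sch <- if (is.null(st$scheme)) "perfusion" else st$scheme
    if (!sch %in% c("blood", "perfusion", "diffusion", "pool"))
      stop(sprintf("chemical '%s', state '%s': unknown scheme '%s'", name, st$compartment, sch))
    if (sch %in% c("perfusion", "diffusion")) {
      if (is.null(st$P) || st$P <= 0)
        stop(sprintf("chemical '%s', state '%s': partition coefficient P must be > 0", name, st$compartment))
    }
    if (sch == "diffusion" && (is.null(st$H) || st$H < 0))
      stop(sprintf("chemical '%s', state '%s': permeability H must be >= 0", name, st$compartment))
  }
  structure(list(name = name, molecular_mass = molecular_mass, states = states),
            class = "chemical_species")
}
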