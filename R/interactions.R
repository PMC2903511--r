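# Mixture-interaction layer: cross-chemical inhibition registration and
# the lagged metal -> metabolism exposure-response effect.

#' Define a mixture interaction
#'
#' Four kinds are supported:
#' \describe{
#'   \item{`competitive`}{chemical `chemical` competitively inhibits the
#'     target reactions with inhibition constant `I` (umol/L): it enters
#'     the Michaelis-Menten denominator as `K_m * (1 + C_k / I)`.}
#'   \item{`noncompetitive`}{the concentration of `chemical` in
#'     `compartment` scales the target reactions' V_max by
#'     `1 / (1 + C / K_nc)`.}
#'   \item{`induction`}{V_max of the targets is multiplied by
#'     `1 + factor`.}
#'   \item{`metal_vmax_modulation`}{a lagged linear tissue
#'     exposure-response effect: an auxiliary state `E` relaxes with time
#'     constant `tau` (h) toward the weighted sum of the source tissue
#'     concentrations, `sum_m w_m * C_m` (weights in L/umol), and the
#'     targets' V_max is multiplied by `max(0, 1 - E)`.}
#' }
#'
#' @param kind Interaction kind (see Details).
#' @param targets Character vector of target reaction names.
#' @param chemical,compartment Source chemical/tissue (competitive and
#'   noncompetitive kinds).
#' @param I Competitive inhibition constant (umol/L).
#' @param K_nc Noncompetitive inhibition constant (umol/L).
#' @param factor Induction factor, >= 0.
#' @param sources For modulation: list of
#'   `list(chemical=, compartment=, weight=)` with weights in L/umol.
#' @param tau Lag time-constant (h), > 0; default 24 h.
#' @param name Spec label (used by [remove_interaction()]).
#' @return An `interaction_spec` object.
#' @export
interaction_spec <- function(kind = c("competitive", "noncompetitive",
                                      "induction", "metal_vmax_modulation"),
                             targets, chemical = NULL, compartment = NULL,
                             I = NULL, K_nc = NULL, factor = NULL,
                             sources = NULL, tau = 24, name = NULL) {
  kind <- match.arg(kind)
  if (kind == "competitive" && (is.null(chemical) || is.null(I) || I <= 0))
    stop("competitive interactions need 'chemical' and 'I' > 0")
  if (kind == "noncompetitive" && (is.null(chemical) || is.null(compartment) ||
                                   is.null(K_nc) || K_nc <= 0))
    stop("noncompetitive interactions need 'chemical', 'compartment' and 'K_nc' > 0")
  if (kind == "induction" && (is.null(factor) || factor < 0))
    stop("induction interactions need 'factor' >= 0")
  if (kind == "metal_vmax_modulation") {
    if (is.null(sources) || !length(sources)) stop("modulation interactions need 'sources'")
    if (tau <= 0) stop("tau must be > 0")
    for (s in sources) if (s$weight < 0) stop("interaction weights must be >= 0")
  }
  structure(list(kind = kind, targets = targets, chemical = chemical,
                 compartment = compartment, I = I, K_nc = K_nc,
                 factor = factor, sources = sources, tau = tau,
                 name = if (is.null(name)) paste0(kind, "_", length(targets), "_",
                                                  paste(targets[1], collapse = "")) else name),
            class = "interaction_spec")
}

#' Register an interaction on an assembled system
#'
#' Re-assembles the system with the extra interaction wired in:
#' competitive specs populate the inhibition constants of the target
#' reactions, noncompetitive/induction specs attach V_max modifiers, and
#' modulation specs append an effect state. Registering no specs leaves
#' the system identical; [remove_interaction()] restores the base system.
#'
#' @param system A `pbtk_system`.
#' @param spec An [interaction_spec()].
#' @return A new `pbtk_system`.
#' @export
register_interaction <- function(system, spec) {
  bp <- system$blueprint
  bp$interactions <- c(bp$interactions, list(spec))
  assemble_system(bp$body, bp$chemicals, bp$reactions, bp$transports,
                  bp$exposures, bp$interactions, bp$volume_fns)
}

#' Remove a registered interaction by name
#'
#' @param system A `pbtk_system`.
#' @param name Name of the spec to drop.
#' @return A new `pbtk_system` without that interaction.
#' @export
remove_interaction <- function(system, name) {
  bp <- system$blueprint
  keep <- vapply(bp$interactions, function(s) s$name != name, logical(1))
  bp$interactions <- bp$interactions[keep]
  assemble_system(bp$body, bp$chemicals, bp$reactions, bp$transports,
                  bp$exposures, bp$interactions, bp$volume_fns)
}

#' Lagged exposure-response effect derivative
#'
#' First-order relaxation of the interaction effect level toward the
#' weighted linear tissue response:
#' `dE/dt = (sum_m w_m * C_m - E) / tau`. At steady state
#' `E = sum_m w_m * C_m`.
#'
#' @param E Current effect level (dimensionless fractional V_max decrease).
#' @param liver_concentrations Numeric vector of source tissue
#'   concentrations (umol/L).
#' @param weights Weights (L/umol), same length.
#' @param tau Lag time-constant (h), > 0.
#' @return dE/dt (1/h).
#' @export
effect_derivative <- function(E, liver_concentrations, weights, tau) {
  if (tau <= 0) stop("tau must be > 0")
  if (length(liver_concentrations) != length(weights)) stop("length mismatch")
  (sum(weights * liver_concentrations) - E) / tau
}

#' Equal-contribution interaction weights
#'
#' Implements the weighting rule that gives metals with low tissue
#' concentrations higher weights so that each source contributes equally
#' to the steady-state effect: `w_m = (E_total / n) / C_m` at the supplied
#' baseline concentrations.
#'
#' @param baseline_conc Named numeric vector of baseline source tissue
#'   concentrations (umol/L), all > 0.
#' @param E_total Targeted total steady-state effect level at baseline.
#' @return Named numeric vector of weights (L/umol).
#' @export
equal_contribution_weights <- function(baseline_conc, E_total) {
  if (any(baseline_conc <= 0)) stop("baseline concentrations must be > 0")
  (E_total / length(baseline_conc)) / baseline_conc
}
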