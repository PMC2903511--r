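---
title: "Methods: a generalized multi-chemical PBTK engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a generalized multi-chemical PBTK engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbtkmix)
```

## The modeling problem

Physiologically based toxicokinetic (PBTK) models estimate the
time-course of chemical amounts and concentrations in body tissues from
exposure histories. Published models for individual toxicants differ
radically in structure: cadmium is usually described by a first-order
transfer-coefficient ("biokinetic") network, lead by a model with
explicit diffusion into bone, methylmercury by a whole-body flow model
with a fetal subsystem, and volatile organics by perfusion-limited
inhalation PBPK with saturable hepatic metabolism. `pbtkmix` maps all of
these structures onto one chemical-independent whole-body compartment
network so that several chemicals — and their metabolic interactions —
can be simulated simultaneously and consistently.

## The mathematical core

All internal quantities are molar (µmol, µmol/L) on an hour time base,
so that one mole of metabolized parent yields exactly one mole of
metabolite; mass-unit doses are converted through each species' molar
mass at the interface. The full state vector is

    [ amounts | interaction effects | ledgers ]

and everything except saturable metabolism is linear in it, so assembly
precomputes one constant rate matrix `M`; the derivative at integration
time is `M y + u(t)` plus the Michaelis–Menten terms.

**Whole-body mass balance.** Each tissue `j` occupied by chemical `i`
obeys `dA_ij/dt = Q_j (C_in − C_out) − R_ij − T_ij`, with `R` the net
metabolic loss (negative = formation) and `T` the net loss through
explicit transport processes (excretion, absorption, transfer between
chemical-specific pools). The inlet is the mixed arterial (blood pool)
concentration.

**Tissue schemes.** Perfusion-limited tissues equilibrate with exiting
blood, so the outlet concentration is `C/P` with `P` the tissue:blood
partition coefficient. Diffusion-limited tissues split into
extracellular and cellular sub-states exchanging through a
permeability–area product `H` (L/h); the outlet equals the
extracellular concentration and the default driving force is
`H (C_E − C_C / P)`. Because published models disagree on where the
partition sits in that driving force, the convention is selectable per
tissue (`H (C_E/P − C_C)` as the alternative). Chemical-specific
storage states (plasma/red-cell pools, bone shells, gut lumen, a fetal
compartment) are "pool" states coupled only by explicit first-order
transport.

**First-order reaction networks.** Within each tissue a matrix of net
rate constants maps concentrations to net loss rates; for a pathway
A → B with constant `k`, A's diagonal entry gains `+k` and the (B, A)
entry gains `−k`, so the formation rate of B is exactly the negative of
A's loss and the columns of an all-tracked network sum to zero.
Pathways to untracked products leave a positive column sum whose losses
are routed to the transformation ledger.

**Saturable metabolism.** Reactions competing for finite enzyme sites
follow `v = Vmax_eff C_i / (K_m (1 + Σ_k C_k / I_k) + C_i)`, with
competitive inhibitors raising the apparent `K_m`. `Vmax_eff` applies
noncompetitive inhibition `1/(1 + C/K_nc)`, induction `(1 + f)` and
mixture-interaction effects `max(0, 1 − E)` multiplicatively; the clamp
at zero is a package choice (the effective velocity can never be
negative, and the literature gives no saturation form for the
interaction effect).

**Interaction effects.** The metal → metabolism interaction is a lagged
linear tissue exposure-response: an auxiliary state `E` relaxes with
time constant `τ` (default 24 h — the lag is described as "short" in
this class of models but is otherwise unquantified) toward
`Σ_m w_m C_liver,m`, and scales the target reactions' `Vmax` by
`1 − E`. The lag is realized as a first-order filter rather than a
delay term, which keeps the system an ODE. Default weights follow an
equal-contribution rule: at baseline steady state each metal (total
arsenic counted as one) contributes equally to a configurable total
effect (default 0.25), which gives metals with low liver concentrations
proportionally higher weights. The absolute magnitudes are a study
assumption, not a measured quantity, so results under interaction
variants are qualitative.

## Physiological consistency

Volumes and blood flows live in one `body_physiology` shared by every
chemical model; perfused tissue flows must sum to cardiac output within
1e-9 relative. Tissues not explicitly modeled for a chemical can be
lumped into rapidly/slowly perfused groups whose combined flow is
constrained to cardiac output minus the explicit flows, so lumping never
creates or destroys perfusion. Storage compartments and the central
blood pool are excluded from the cardiac-output budget because they do
not draw arterial flow. The rapid/slow membership table is a package
default keyed on role tags and is editable, since no canonical
enumeration exists. The packaged reference adult (70 kg, cardiac output
312 L/h, standard tissue set) is a package default in textbook
physiological ranges.

Virtual individuals are sampled lognormally (mean-preserving, with the
requested coefficient of variation) and flows are renormalized to the
sampled cardiac output; body mass moves with the sampled tissue volumes
at ~1 kg/L so the volume–mass invariant always holds. `cv = 0` is the
identity and sampling is deterministic given a seed.

## Chemical models and their parameters

Builders contain structure only; every number lives in a packaged YAML
file with a provenance string. **These parameter sets are synthetic
package defaults**: they are chosen once to sit in the physiological
regimes of the classical source-model families (cadmium: slow
urinary/kidney biokinetics with decade-scale half-life; lead: fast
plasma clearance, strong red-cell binding, trabecular turnover ~1 y and
cortical return on the decade scale so that the chronic body burden is
~95% bone; chromium: Cr(VI) blood reduction on the minutes scale over a
lead-like skeleton; methylmercury: whole-body half-life in the 50–70 d
range with fecal-dominant excretion, hair as a first-order blood route
and slow tissue demethylation; arsenic: the six-step
reduction/methylation network with AS3MT noncompetitive inhibition and
urinary-only elimination; benzene/toluene: published human ranges of
blood:air and tissue:blood partitions with hepatic saturable
oxidation). They are not transcriptions of any specific published table
and should be replaced with study-specific values (every builder takes
a `params` override) for quantitative work against data.

Model-specific notes:

* **Lead bone.** Mature cortical bone is discretized into eight
  concentric cylindrical shells of equal thickness, so shell volumes
  grow as the odd numbers `2k − 1` and interface conductances scale
  with the interface radius index, all derived from one conductance
  scale; the innermost shell exchanges with plasma. This is the
  simplest geometry consistent with "radial diffusion across eight
  shells". The optional age-growth hook is a static piecewise-linear
  scaling of pool sizes and bone-turnover rates (a full growth model is
  out of scope).
* **Arsenic distribution** uses perfusion-limited flow over blood,
  liver, kidney, muscle and the two rest-of-body compartments; tissues
  a species does not occupy simply return blood unchanged.
* **Methylmercury pregnancy.** Placental exchange uses constant
  amount-based transfer rates (keeping the system linear); the growing
  fetal volume (linear from conception to term) enters concentration
  reporting. This reproduces the qualitative property that fetal blood
  concentration can exceed maternal blood, but fetal growth does not
  feed back on transfer rates.
* **Gas exchange** is the steady-inhalation alveolar balance: a
  continuous uptake `Q_alv C_air` into the blood pool and a first-order
  exhalation clearance `Q_alv / P_ba`, with ppm converted through the
  ideal-gas molar volume at 25 °C (24.45 L/mol). No explicit lung
  compartment is carried.

## Numerical choices

* Solver: `deSolve` with `lsoda` (automatic stiff/non-stiff switching;
  BDF in stiff regions), default `rtol = 1e-8`, `atol = 1e-12` µmol.
  The reporting grid is decoupled from solver steps.
* Dose boluses and intake scaling switches are solver-restart events:
  the integration stops at each event time, state jumps are applied
  exactly, and piecewise-constant inputs are rebuilt per segment. No
  stiff impulse approximations.
* Negative amounts in `(−1e-9, 0)` µmol are treated as solver noise and
  clipped to zero; anything below aborts, distinguishing noise from
  modeling bugs.
* Mass ledgers (cumulative administered, excreted by route, net
  transformed) are integrated as extra states, so conservation —
  administered = in-body + excreted + net transformed, per chemical —
  is audited on every run at 1e-6 relative tolerance. Externally
  imposed initial burdens are counted as administered so hand-off
  initial conditions (e.g. the cadmium birth-to-30 pre-run) still
  close.

## What the synthetic fixtures do and do not show

The test oracle draws random compartmental matrices (non-negative
off-diagonals, strictly diagonally dominated columns, hence stable) and
compares the engine against the matrix-exponential closed form computed
with `Matrix::expm` — an independent solution path. Passing this shows
the assembly and integration machinery is correct for linear dynamics;
together with the unit identities of the saturable-kinetics primitives
it covers the full derivative. It does not validate any chemical
parameter set against human data: the packaged scenarios emulate the
study conditions (intake rates, step changes, co-exposure) rather than
observed biomarker series, so passing tests demonstrate structural and
numerical fidelity, not predictive accuracy for real populations.

## Problem sizes used in the packaged analyses

The packaged mixture study runs all species jointly (about 80 amount
states plus ledgers) for 700 days with the metal step at day 500, the
chronic lead scenario integrates 30 years, and the cadmium pre-run 30
years at 0.2 µg/kg/day; oracle sweeps use twenty fixtures of up to ten
states. These sizes were chosen as the smallest that exercise every
mechanism at steady state; all complete in seconds on one core.

## Known limitations

* No dermal route, no exposure-model linkage, no toxicodynamics.
* Metals' biokinetic pools are not flow-coupled, so a metal's blood
  pool is a kinetic, not a circulatory, entity; arterial/venous
  distinction is not resolved anywhere.
* Interaction magnitudes (weights, lag) are assumptions; only
  qualitative statements (direction, monotonicity) are supported.
* Enterohepatic recirculation, carrier-mediated transport and
  age-dependent growth beyond the static hooks are not modeled.
```{r example, eval = FALSE}
# A minimal end-to-end run: chronic dietary lead for 30 years
pb <- build_lead_model()
sys <- assemble_model(pb, exposures = list(dietary_profile(pb, "lead", 70)))
res <- simulate_system(sys, 30 * 8766, report_grid = seq(0, 30 * 8766, 2190))
bone <- grepl("bone", res$layout$compartment)
100 * sum(res$amounts[nrow(res$amounts), bone]) / sum(res$amounts[nrow(res$amounts), ])
```
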