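# pbtkmix

A generalized, physiologically consistent toxicokinetic (PBTK) engine
for **chemical mixtures**. Published toxicokinetic models for individual
chemicals use incompatible structures — transfer-coefficient biokinetics
for cadmium, bone-diffusion models for lead, a pregnancy-capable
whole-body model for methylmercury, perfusion-limited inhalation PBPK
for volatile organics. `pbtkmix` maps all of them onto **one
chemical-independent whole-body compartment network** and integrates
them *simultaneously*, so metabolic and absorption interactions between
chemicals (competitive inhibition between co-inhaled organics, toxic
metals suppressing hepatic metabolism) can be simulated instead of
ignored. It is aimed at exposure and risk modelers who need internal
doses for co-occurring contaminants on one consistent physiology.

## The model

For every chemical *i* and tissue *j* the engine solves the matrix
mass balance

    dA_ij/dt = Q_j (C_in,i − C_out,ij) − R_ij − T_ij

with `A` amounts (µmol), `Q` tissue blood flows (L/h), `R` net metabolic
loss and `T` net loss through explicit transport (excretion, GI
absorption, inter-pool transfer, gas exchange). Tissue schemes:

* **perfusion-limited** — outlet concentration `C/P` (tissue:blood
  partition `P`);
* **diffusion-limited** — extracellular/cellular sub-states exchanging
  at `H (C_E − C_C / P)` with permeability–area product `H` (L/h),
  outlet `C_E`;
* **pool** — chemical-specific storage (plasma/RBC pools, eight
  cylindrical cortical-bone shells, gut lumen, fetal compartment)
  coupled by first-order transport only.

Metabolism is either a per-tissue matrix of net first-order rate
constants Γ (`Γ y` = net loss vector; the formation rate of a tracked
product is the negative of the parent's loss) or saturable
Michaelis–Menten kinetics with mixture terms:

    v_i = Vmax_eff,i · C_i / ( K_m,i (1 + Σ_k C_k / I_k,i) + C_i )

where competitive inhibitors `k` raise the apparent `K_m`, and
`Vmax_eff` applies noncompetitive inhibition `1/(1 + C/K_nc)`, enzyme
induction `(1 + f)` and lagged metal-interaction effects `max(0, 1 − E)`
with `dE/dt = (Σ_m w_m C_liver,m − E)/τ`. Mass ledgers (administered,
excreted by route, net transformed) are carried as extra states, so
every simulation is audited for conservation at 1e-6 relative.

Six chemical model builders ship with packaged (synthetic,
literature-regime) parameter sets: `build_cadmium_model()`,
`build_lead_model()` (trabecular + 8-shell cortical bone),
`build_chromium_model()` (fast Cr(VI)→Cr(III) blood reduction),
`build_mehg_model()` (urine/hair/feces routes, demethylation, optional
pregnancy subsystem), `build_arsenic_model()` (six-step
reduction/methylation network with AS3MT noncompetitive inhibition),
and `build_voc_model()` (benzene/toluene with mutual competitive
inhibition). All share one reference adult body and can be combined
into a joint multi-chemical system.

## Worked example

Thirty years of chronic dietary lead (70 µg/day) in the reference
adult:

```r
library(pbtkmix)
pb  <- build_lead_model()
sys <- assemble_model(pb, exposures = list(dietary_profile(pb, "lead", 70)))
res <- simulate_system(sys, 30 * 8766, report_grid = seq(0, 30 * 8766, 2190))
res
#> pbtk_result: 122 time points over 262980.0 h, 14 amount states
#> ledger audit: max relative error 2.38e-15 (closed)

n <- nrow(res$amounts); bone <- grepl("bone", res$layout$compartment)
100 * sum(res$amounts[n, bone]) / sum(res$amounts[n, ])
#> [1] 95.8
```

Of 3702 µmol administered over 30 years, 38.7 µmol remain in the body
(the rest was excreted), and 95.8% of that body burden sits in bone —
the hallmark of chronic lead kinetics: bone is the long-term reservoir
that keeps replenishing blood lead long after exposure ends.

The seven-chemical mixture study (`run_mixture_scenario()`) simulates
continuous dietary metals (15/40/70/100 µg/day Cd/MeHg/Pb/iAs, with
cadmium initialized from a birth-to-age-30 pre-run) plus inhaled
toluene (20 ppm) and benzene (10 ppm) for 700 days, stepping the metal
intakes up 40% at day 500. With the metal→metabolism interaction
enabled, liver benzene rises ~4% after the step purely because the
accumulating metals suppress its oxidation; in the base case it is
flat, because benzene's own exposure never changed.

A command-line interface is installed at `inst/cli/pbtkmix`
(`validate`, `simulate`, `fixtures` subcommands); scenario files are
YAML (see `inst/extdata/scenario_*.yaml`), with units mandatory on
every dosed quantity.

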