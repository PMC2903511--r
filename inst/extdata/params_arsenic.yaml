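# Arsenic toxicokinetic parameters (6 tracked species).
# Package defaults (synthetic): perfusion-limited whole-body distribution
# with hepatic metabolism -- the six-step reduction/methylation network
# (reductions first-order, methylations saturable and catalyzed by AS3MT
# with noncompetitive inhibition of the As(III) methylation by liver
# MMA(III) and of the MMA(III) methylation by liver As(III)), small
# oxidation back-reactions for every trivalent species, no demethylation,
# and urinary excretion as the only elimination route.
# Units: 1/h, umol/h, umol/L, L/h; arsenic mass expressed as elemental As.
provenance: "params_arsenic.yaml - package default (synthetic), six-step hepatic methylation network regime"
molecular_mass: 74.92     # elemental-As basis, shared by all species
absorption:
  F_abs: 0.95
species: [as5, as3, mma5, mma3, dma5, dma3]
# tissue:blood partition coefficients (rows: species; shared tissue set)
compartments: [liver, kidney, muscle, richly_perfused_rest, slowly_perfused_rest]
partition:
  as5:  {liver: 8.0,  kidney: 8.0,  muscle: 4.0, richly_perfused_rest: 8.0, slowly_perfused_rest: 4.0}
  as3:  {liver: 10.0, kidney: 10.0, muscle: 4.0, richly_perfused_rest: 10.0, slowly_perfused_rest: 4.0}
  mma5: {liver: 6.0,  kidney: 6.0,  muscle: 3.0, richly_perfused_rest: 6.0, slowly_perfused_rest: 3.0}
  mma3: {liver: 8.0,  kidney: 8.0,  muscle: 3.0, richly_perfused_rest: 8.0, slowly_perfused_rest: 3.0}
  dma5: {liver: 5.0,  kidney: 5.0,  muscle: 2.5, richly_perfused_rest: 5.0, slowly_perfused_rest: 2.5}
  dma3: {liver: 6.0,  kidney: 6.0,  muscle: 2.5, richly_perfused_rest: 6.0, slowly_perfused_rest: 2.5}
metabolism:
  step1_reduction_k: 1.0        # As(V) -> As(III), liver, 1/h
  step2_methylation:            # As(III) -> MMA(V), AS3MT
    V_max: 30.0                 # umol/h
    K_m: 10.0                   # umol/L
    K_nc_by_mma3: 4.0           # noncompetitive, liver MMA(III), umol/L
  step3_methylation:            # As(III) -> DMA(V), AS3MT
    V_max: 10.0
    K_m: 15.0
  step4_reduction_k: 0.3        # MMA(V) -> MMA(III)
  step5_methylation:            # MMA(III) -> DMA(V), AS3MT
    V_max: 25.0
    K_m: 8.0
    K_nc_by_as3: 6.0            # noncompetitive, liver As(III), umol/L
  step6_reduction_k: 0.05       # DMA(V) -> DMA(III)
  oxidation_k: 0.01             # small back-oxidation of every trivalent species
urinary_clearance:              # L/h on blood concentration; only elimination
  as5: 5.0
  as3: 1.5
  mma5: 4.0
  mma3: 2.0
  dma5: 5.0
  dma3: 3.0
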