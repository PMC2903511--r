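# Lead biokinetic parameters.
# Package defaults (synthetic): plasma/RBC binding, soft-tissue exchange,
# urinary elimination and bone exchange rates set in the regime of the
# classical adult lead bone-diffusion models: fast plasma clearance,
# strong red-cell binding, trabecular turnover ~ 1 y, cortical return on
# the decade scale, so that the chronic body burden is dominated (~95%)
# by bone. Units: 1/h, L.
provenance: "params_lead.yaml - package default (synthetic), adult bone-diffusion lead model regime"
molecular_mass: 207.2
absorption:
  F_abs: 0.08
pools:
  - {name: plasma, volume: 3.0}
  - {name: rbc,    volume: 2.0}
  - {name: liver,  volume: 1.8}
  - {name: kidney, volume: 0.31}
  - {name: soft,   volume: 40.0}
  - {name: bone_trab, volume: 1.0}
transfers:
  - {from: plasma, to: rbc,    k: 5.0}      # red-cell binding (fast)
  - {from: rbc,    to: plasma, k: 5.0e-2}   # ~99% of blood lead in RBC
  - {from: plasma, to: liver,  k: 0.5}
  - {from: liver,  to: plasma, k: 3.0e-3}
  - {from: liver,  route: feces, k: 1.0e-3} # biliary
  - {from: plasma, to: kidney, k: 0.3}
  - {from: kidney, to: plasma, k: 3.0e-3}
  - {from: plasma, to: soft,   k: 1.0}
  - {from: soft,   to: plasma, k: 1.0e-3}
  - {from: plasma, route: urine, k: 0.7}
bone:
  trabecular_uptake_k: 0.4          # plasma -> trabecular (1/h)
  trabecular_return_k: 7.9e-5       # resorption, t1/2 ~ 1 y
  cortical_volume: 3.0              # lead-accessible mature cortical volume (L)
  n_shells: 8                       # concentric cylindrical shells (radial)
  cortical_uptake_k: 0.1            # plasma -> innermost shell (1/h)
  cortical_return_k: 5.0e-6         # shell-1 -> plasma, t1/2 ~ 16 y
  shell_conductance: 1.0e-3         # radial diffusive conductance scale (L/h)
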