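# Methylmercury / inorganic mercury parameters.
# Package defaults (synthetic): MeHg is well absorbed, crosses the
# blood-brain barrier, is excreted in urine, hair and feces, and is
# slowly demethylated to inorganic mercury in tissues; whole-body MeHg
# half-life lands in the 50-70 day literature regime. Optional pregnancy
# subsystem: a fetal compartment with bidirectional placental transfer and
# a volume that grows over gestation. Units: 1/h, L.
provenance: "params_mercury.yaml - package default (synthetic), human MeHg excretion/demethylation regime"
molecular_mass_mehg: 215.6
molecular_mass_ihg: 200.6
absorption:
  F_abs: 0.95
pools_mehg:
  - {name: blood,  volume: 5.0}
  - {name: brain,  volume: 1.4}
  - {name: liver,  volume: 1.8}
  - {name: kidney, volume: 0.31}
  - {name: rest,   volume: 40.0}
pools_ihg:
  - {name: blood,  volume: 5.0}
  - {name: liver,  volume: 1.8}
  - {name: kidney, volume: 0.31}
  - {name: rest,   volume: 40.0}
transfers_mehg:
  - {from: blood,  to: brain,  k: 1.0e-2}   # crosses blood-brain barrier
  - {from: brain,  to: blood,  k: 2.0e-3}
  - {from: blood,  to: liver,  k: 5.0e-2}
  - {from: liver,  to: blood,  k: 1.0e-2}
  - {from: blood,  to: kidney, k: 2.0e-2}
  - {from: kidney, to: blood,  k: 1.0e-2}
  - {from: blood,  to: rest,   k: 1.0e-1}
  - {from: rest,   to: blood,  k: 1.0e-2}
  - {from: liver,  route: feces, k: 2.0e-3} # biliary, dominant route
  - {from: blood,  route: hair,  k: 2.0e-4} # first-order on blood
  - {from: blood,  route: urine, k: 1.0e-4}
transfers_ihg:
  - {from: blood,  to: kidney, k: 5.0e-2}   # inorganic Hg accumulates renally
  - {from: kidney, to: blood,  k: 1.0e-3}
  - {from: blood,  to: liver,  k: 1.0e-2}
  - {from: liver,  to: blood,  k: 2.0e-3}
  - {from: blood,  to: rest,   k: 2.0e-2}
  - {from: rest,   to: blood,  k: 5.0e-3}
  - {from: kidney, route: urine, k: 5.0e-4}
  - {from: blood,  route: feces, k: 2.0e-4}
demethylation_k: 1.0e-4        # MeHg -> iHg (1/h, per tissue)
demethylation_tissues: [blood, liver, kidney, rest]
lactation:
  milk_k: 0.0                  # milk route ledger; > 0 only when configured
pregnancy:
  fetal_volume_initial: 0.05   # L at conception
  fetal_volume_final: 3.4      # L at term
  gestation_h: 6480.0          # 270 days
  maternal_to_fetal_k: 6.8e-4  # blood -> fetal (1/h)
  fetal_to_maternal_k: 1.0e-3  # fetal -> blood (1/h)
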