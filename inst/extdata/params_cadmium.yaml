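# Cadmium biokinetic parameters.
# Package defaults (synthetic): first-order transfer coefficients chosen in
# the physiological regimes of classical human cadmium biokinetics
# (slow whole-body elimination, kidney/liver accumulation on
# metallothionein, urinary half-life on the decade scale).
# Units: 1/h for rate constants, L for volumes.
provenance: "params_cadmium.yaml - package default (synthetic), classical human Cd biokinetic regime"
molecular_mass: 112.41
absorption:
  F_abs_male: 0.05      # fractional GI absorption, adult male
  F_abs_female: 0.10    # higher fractional absorption in females
pools:
  - {name: blood,  volume: 5.0}
  - {name: liver,  volume: 1.8}
  - {name: kidney, volume: 0.31}
  - {name: other,  volume: 40.0}
transfers:
  - {from: blood,  to: liver,  k: 2.0e-2}   # uptake, metallothionein binding
  - {from: blood,  to: kidney, k: 1.0e-2}
  - {from: blood,  to: other,  k: 1.0e-2}
  - {from: other,  to: blood,  k: 1.0e-3}
  - {from: liver,  to: blood,  k: 2.0e-5}   # slow hepatic release (t1/2 ~ 4 y)
  - {from: liver,  route: feces, k: 1.0e-5} # biliary
  - {from: kidney, route: urine, k: 5.3e-6} # renal elimination t1/2 ~ 15 y
  - {from: blood,  route: urine, k: 2.0e-4} # direct filtered fraction
cortex_kidney_ratio: 1.25   # kidney-cortex : whole-kidney concentration
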