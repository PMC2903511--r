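# Chromium biokinetic parameters (Cr(VI)/Cr(III)).
# Package defaults (synthetic): hexavalent chromium is reduced rapidly to
# trivalent chromium in blood (half-life minutes); Cr(III) kinetics sit on
# a simplified version of the lead-model skeleton with urinary
# elimination of both species. Units: 1/h, L.
provenance: "params_chromium.yaml - package default (synthetic), rapid blood reduction + lead-skeleton regime"
molecular_mass: 52.0
absorption:
  F_abs_cr6: 0.02
  F_abs_cr3: 0.005
reduction_k: 5.0        # Cr(VI) -> Cr(III) in blood, t1/2 ~ 8 min
pools_cr6:
  - {name: blood, volume: 5.0}
pools_cr3:
  - {name: blood,  volume: 5.0}
  - {name: liver,  volume: 1.8}
  - {name: kidney, volume: 0.31}
  - {name: bone,   volume: 8.5}
  - {name: soft,   volume: 40.0}
transfers_cr6:
  - {from: blood, route: urine, k: 5.0e-2}
transfers_cr3:
  - {from: blood,  to: liver,  k: 5.0e-2}
  - {from: liver,  to: blood,  k: 5.0e-3}
  - {from: liver,  route: feces, k: 2.0e-3}
  - {from: blood,  to: kidney, k: 3.0e-2}
  - {from: kidney, to: blood,  k: 1.0e-2}
  - {from: blood,  to: bone,   k: 1.0e-2}
  - {from: bone,   to: blood,  k: 1.0e-4}
  - {from: blood,  to: soft,   k: 5.0e-2}
  - {from: soft,   to: blood,  k: 1.0e-2}
  - {from: blood,  route: urine, k: 8.0e-2}
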