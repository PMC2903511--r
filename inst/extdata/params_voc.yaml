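# Benzene / toluene inhalation parameters.
# Package defaults (synthetic): whole-body perfusion-limited PBTK with
# blood:air and tissue:blood partition coefficients and hepatic
# Michaelis-Menten oxidation in the published human ranges; mutual
# competitive inhibition constants default to the inhibitor's own K_m.
# Units: dimensionless partitions, umol/h, umol/L, L/h.
provenance: "params_voc.yaml - package default (synthetic), human benzene/toluene PBPK regime"
alveolar_ventilation: 300.0    # L/h
benzene:
  molecular_mass: 78.11
  blood_air_partition: 7.4
  partition:                   # tissue:blood
    liver: 1.6
    kidney: 1.6
    brain: 1.9
    fat: 28.0
    muscle: 0.8
    skin: 0.8
    richly_perfused_rest: 1.6
    slowly_perfused_rest: 0.8
  V_max: 150.0                 # hepatic oxidation, umol/h
  K_m: 5.0                     # umol/L
toluene:
  molecular_mass: 92.14
  blood_air_partition: 15.6
  partition:
    liver: 4.6
    kidney: 4.6
    brain: 2.7
    fat: 56.0
    muscle: 1.5
    skin: 1.5
    richly_perfused_rest: 4.6
    slowly_perfused_rest: 1.5
  V_max: 300.0
  K_m: 7.0
mutual_inhibition:
  I_toluene_on_benzene: 7.0    # umol/L (defaults to K_m of toluene)
  I_benzene_on_toluene: 5.0    # umol/L (defaults to K_m of benzene)
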