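# Reference adult body used by all chemical model builders.
# Package defaults in standard physiological ranges (70 kg adult,
# cardiac output 5.2 L/min = 312 L/h); tissue flows are fractions of
# cardiac output and sum to it exactly.  Units: L, L/h, kg.
cardiac_output: 312.0
body_mass: 70.0
compartments:
  - {name: blood,  volume: 5.0,  blood_flow: 0.0,    scheme: perfusion_limited, tags: [blood]}
  - {name: liver,  volume: 1.8,  blood_flow: 78.0,   scheme: perfusion_limited, tags: [liver]}       # 25% CO (incl. splanchnic)
  - {name: kidney, volume: 0.31, blood_flow: 59.28,  scheme: perfusion_limited, tags: [kidney]}      # 19% CO
  - {name: brain,  volume: 1.4,  blood_flow: 37.44,  scheme: perfusion_limited, tags: [brain]}       # 12% CO
  - {name: muscle, volume: 28.0, blood_flow: 53.04,  scheme: perfusion_limited, tags: [muscle]}      # 17% CO
  - {name: skin,   volume: 2.6,  blood_flow: 15.6,   scheme: perfusion_limited, tags: [skin]}        # 5% CO
  - {name: fat,    volume: 10.0, blood_flow: 15.6,   scheme: perfusion_limited, tags: [fat]}         # 5% CO
  - {name: bone,   volume: 8.5,  blood_flow: 15.6,   scheme: perfusion_limited, tags: [bone]}        # 5% CO
  - {name: richly_perfused_rest, volume: 3.5, blood_flow: 24.96, scheme: perfusion_limited, tags: [viscera]} # 8% CO
  - {name: slowly_perfused_rest, volume: 5.0, blood_flow: 12.48, scheme: perfusion_limited, tags: [slowly_perfused]} # 4% CO
  - {name: gi_lumen, volume: 1.2, blood_flow: 0.0, scheme: storage, tags: [gi_lumen]}
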