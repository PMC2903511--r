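# Seven-chemical mixture scenario (base case, no metal-organics
# interaction): continuous dietary metals, inhaled volatile organics, and
# a 40% step increase of the metal intakes at day 500 (h 12000) while the
# organics stay constant.
name: mixture_base
physiology: reference_adult
models:
  - {model: cadmium, sex: male}
  - {model: mehg}
  - {model: lead}
  - {model: arsenic}
  - {model: voc}
exposures:
  - {chemical: cadmium, route: oral_continuous, magnitude: 15,  units: ug/day}
  - {chemical: mehg,    route: oral_continuous, magnitude: 40,  units: ug/day}
  - {chemical: lead,    route: oral_continuous, magnitude: 70,  units: ug/day}
  - {chemical: as5,     route: oral_continuous, magnitude: 100, units: ug/day}
  - {chemical: toluene, route: inhalation, magnitude: 20, units: ppm}
  - {chemical: benzene, route: inhalation, magnitude: 10, units: ppm}
scaling:
  - {time_h: 12000, factor: 1.4, chemicals: [cadmium, mehg, lead, as5]}
simulation:
  t_end_h: 16800        # 700 days
  report_dt_h: 48
  rtol: 1.0e-8
  atol: 1.0e-12
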