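# Single oral 5 mg dose of hexavalent chromium in an adult male:
# Cr(VI) is reduced to Cr(III) in blood within minutes, and Cr(III)
# plasma levels and urinary elimination are followed for two weeks.
name: chromium_bolus
physiology: reference_adult
models:
  - {model: chromium}
exposures:
  - {chemical: cr6, route: oral_bolus, magnitude: 5, units: mg, time_h: 0}
simulation:
  t_end_h: 336          # 14 days
  report_dt_h: 1
  rtol: 1.0e-8
  atol: 1.0e-12
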