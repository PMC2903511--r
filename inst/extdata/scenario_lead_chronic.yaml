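# Chronic adult lead exposure: 70 ug/day dietary lead for 30 years.
# Used to examine the long-term distribution of the lead body burden
# between bone (trabecular + cortical shells) and soft tissues.
name: lead_chronic
physiology: reference_adult
models:
  - {model: lead}
exposures:
  - {chemical: lead, route: oral_continuous, magnitude: 70, units: ug/day}
simulation:
  t_end_h: 262980       # 30 years
  report_dt_h: 2160     # 90-day reporting
  rtol: 1.0e-8
  atol: 1.0e-12
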