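dose: 2000.0
incidence_rate: 0.0176
alpha: 0.05
person_years_per_arm: 4000.0
treatment_person_years: 4000.0
population:
- 11.0
- 14.0
- 17.0
- 20.0
- 23.0
- 26.0
- 29.0
- 33.0
- 36.0
- 40.0
population_label: Canadian ages 50-79
weights:
- 0.2
- 0.2
- 0.2
- 0.2
- 0.2
curve:
  coefficient: 18.3
  exponent: -0.833
  min_concentration: 1.0
status_backend: calibration
selected_deciles:
- 6
- 7
- 8
- 9
- 10
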