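# Example run configuration: overrides are merged over the packaged
# defaults (see ?default_config); absent keys keep their defaults.
# Data tables can be swapped via *_csv keys:
#   outdoor_csv, tef_csv, particle_fraction_csv, emission_factor_csv
population:
  smoker_fraction: 0.311
  rural:
    coal_prevalence: 0.6875
  shared:
    t_home: 16
risk:
  urr: 4.49
  lifetime_years: 70
intervention:
  cleaner_cadr: 134
  cleaner_hours: 16
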