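# Minimal two-site assessment configuration. Defaults (window 5 years,
# beta 0.67, 2-sigma outlier screening, 0-100 reporting) apply unless
# overridden under `assessment`.
assessment:
  evaluation_year: 2013
sites:
  - site_id: A
    name: Artificial flat
    natural_or_artificial: artificial
    area_m2: 440
  - site_id: B
    name: Natural flat
    natural_or_artificial: natural
    area_m2: 250000
services:
  - service_id: food
    name: Food provision
    index_description: Wet weight of commercially important species
    spatial_basis: per_unit_area
    temporal_statistic: annual_mean
    unit: g/m2
  - service_id: research
    name: Research
    spatial_basis: whole_site
    temporal_statistic: annual_total
    unit: papers/year
factors:
  - factor_id: anoxic_water
    service_id: food
    kind: quantitative
    lo_threshold: 2
    hi_threshold: 6
    description: DO concentration, mg/L
  - factor_id: blue_tide
    service_id: food
    kind: qualitative
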