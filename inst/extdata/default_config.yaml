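# Default vegrisk pipeline configuration (mirrors default_config()).
# Toxicity constants: IRIS oral reference doses (mg/kg/day) and oral slope
# factors ((mg/kg/day)^-1); exposure profiles per demographic group.
at_convention: ed_years      # ed_years (AT = ED x 365) or table
unit_factor: 1.0e-3          # scaling retained in the carcinogenic-risk equation
analytes:
  Cd:  {name: Cd,  rfd: 0.001,   slope_factor: 0.38}
  Pb:  {name: Pb,  rfd: 0.00357, slope_factor: 0.0085}
  Zn:  {name: Zn,  rfd: 0.3}
  Ni:  {name: Ni,  rfd: 0.02,    slope_factor: 1.7}
  NO3: {name: NO3, rfd: 1.6}
profiles:
  children:     {group: children,     ir: 0.13, ef: 365, ed: 6,  bw: 18.6,
                 at_noncarc: 10950, at_carc: 25550}
  adult_male:   {group: adult_male,   ir: 0.26, ef: 365, ed: 30, bw: 66.2,
                 at_noncarc: 10950, at_carc: 25550}
  adult_female: {group: adult_female, ir: 0.26, ef: 365, ed: 30, bw: 57.3,
                 at_noncarc: 10950, at_carc: 25550}
synth:
  n_sites: 21
  n_districts: 11
  extent: [0, 20, 0, 20]     # km
mc:
  n_iter: 50000
sobol:
  n_base: 2048
  second_order: true
  endpoint: tcr              # hq | cr | hi | tcr
  vegetable: radish
  group: children
  exposure_cv: 0.2           # lognormal CV assumed for IR and BW
idw:
  power: 2
  nrow: 40
  ncol: 40
  vegetable: radish
stages: [synth, risk, mc, sobol, idw]
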