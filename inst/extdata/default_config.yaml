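# Default simulation configuration. Every field of sim_config() is listed;
# values mirror the package defaults (a ~25,600-woman screening cohort).
n_women: 25591
group_proportions:
  Africa: 0.019499043
  Americas: 0.145676214
  EastAsia: 0.032511430
  Europe: 0.761361416
  Other: 0.036301825
  SouthAsia: 0.004650072
gene_carrier_counts:
  BRCA1: 70
  BRCA2: 89
  PALB2: 39
  ATM: 94
  CHEK2: 118
gene_hr:
  BRCA1: 16.2
  BRCA2: 8.5
  PALB2: 6.3
  ATM: 4.3
  CHEK2: 2.6
prs_top10_hr: 2.4
baseline_cuminc_70: 0.093
fhx_prevalence: 0.069
fhx_carrier_or: 3.5
fhx_prs_beta: 0.25
fhx_timing_mix:
  before: 0.22
  simultaneous: 0.30
  after: 0.48
ehr_span_mean: 12.0
ehr_span_sd: 5.0
age_mix:
  weights: [0.68, 0.32]
  means: [45.0, 71.0]
  sds: [12.0, 7.0]
  range: [19.0, 89.0]
age_bands: [0, 40, 50, 60, 70, 90]
band_rel_hazard: [0.15, 1.0, 1.4, 1.8, 2.0]
prs_group_mean:
  Africa: -0.30
  Americas: 0.15
  EastAsia: -0.45
  Europe: 0.0
  Other: 0.05
  SouthAsia: 0.20
prs_group_sd:
  Africa: 1.0
  Americas: 1.0
  EastAsia: 1.0
  Europe: 1.0
  Other: 1.0
  SouthAsia: 1.0
other_fhx_prevalence: 0.268
comparator_prevalence:
  T2D: 0.12
  HTN: 0.35
seed: 1
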