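# Example pipeline configuration: a synthetic cohort at the study's design
# scale. Every key maps 1:1 onto run_config()/cohort_config().
seed: 20230901
changepoint: 40
nonconsumer_threshold: 0
allow_extrapolation: false
simulation:
  n_per_group: 10
  sexes: [male, female]
  ip_doses: [0, 0.3, 1, 3, 10, 30]
  gel_concentrations: [2, 5, 10]
  oral_dose_means:
    "2": 10.5
    "5": 17.2
    "10": 29.2
  oral_dose_cv: 0.25
  oral_potency: 0.1267  # 3.7 / 29.2: consumed mg/kg per i.p.-equivalent mg/kg
  noise_sd:
    locomotion: 700    # cm over 15 min
    tail_flick: 1.6    # s latency
    temperature: 1.7   # deg C
  assay_params:
    locomotion:  {bottom: 0, top: -3500, ed50: 1.3}
    tail_flick:  {bottom: 0, top: 8,     ed50: 3.9}
    temperature: {bottom: 0, top: -8.64, ed50: 14.4}
  consumption_profile_thc:
    early_rate: 13.0
    late_rate: 4.2
    changepoint: 40
    duration: 120
    animal_rate_cv: 0.3
  consumption_profile_veh:
    early_rate: 16.3
    late_rate: 9.9
    changepoint: 40
    duration: 120
    animal_rate_cv: 0.3
  seed: 20230901
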