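schema_version: '1.0'
rates:
  k_open_per_day: 0.8
  k_close_per_day: 145.454545454545467
  k_nuc_per_uM_per_day: 0.7
  k_el_per_uM_per_day: 6000.0
  k_join_per_uM_per_day: 220.0
  k_relax_free_per_day: 0.1497866136777
  k_relax_chain_per_day: 0.07
  uv_factor: 20000.0
  activation_efficiency: 1.0
initial:
  n_units: 10000.0
  conc_uM: 30.0
protocol:
- kind: heat_pulse
  time_days: 0.0
geometry:
  external_diameter_nm: 12.0
  tube_diameter_nm: 3.0
  pitch_nm: 3.0
  chirality: 1.0
observables:
  cd_baseline: 0.0
  cd_amplitude: 1.0
  cryotem_include_monomers: yes
  cryotem_noise_sd_log: 0.1
simulation:
  t_end_days: 15.0
  record_every_days: 1.0
  seed: 1.0
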