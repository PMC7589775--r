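seed: 7
grid:
  start_nm: 900.0
  stop_nm: 2494.0
  n_bands: 275
crop:
  low_nm: 935.0
  high_nm: 1965.0
layout:
  rows: 5
  cols: 5
  well_diameter_px: 14
  well_pitch_px: 22
  image_width_px: 118
noise:
  additive_sd: 0.01
  scatter_slope_sd: 0.02
  scatter_offset_sd: 0.005
  baseline_tilt_sd: 0.005
external_scatter_slope_multiplier: 2.0
endmembers:
  baseline_level: 0.6
  variety_shift: 0.04
ddsimca:
  alpha: 0.01
  gamma: 0.01
  factors: auto
  max_factors: 5
  preprocess: snv
  window: 11
  polyorder: 2
plsr:
  max_factors: 12
  methods:
  - mean_norm
  - max_norm
  - range_norm
  - msc
  - snv
  - sg_first
  - sg_second
  - raw
designs:
  dds_cal_v1:
    adulterant: apricot
    variety: 1
    wells_pct:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    seed_offset: 1
  dds_cal_v2:
    adulterant: apricot
    variety: 2
    wells_pct:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    seed_offset: 2
  dds_val1_aa:
    adulterant: apricot
    variety: 1
    wells_pct:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 5.0
    - 5.0
    - 5.0
    - 5.0
    - 5.0
    - 10.0
    - 10.0
    - 10.0
    - 10.0
    - 10.0
    - 15.0
    - 15.0
    - 15.0
    - 15.0
    - 15.0
    - 20.0
    - 20.0
    - 20.0
    - 20.0
    - 20.0
    - 25.0
    - 25.0
    - 25.0
    - 25.0
    - 25.0
    - 30.0
    - 30.0
    - 30.0
    - 30.0
    - 30.0
    - 35.0
    - 35.0
    - 35.0
    - 35.0
    - 35.0
    - 40.0
    - 40.0
    - 40.0
    - 40.0
    - 40.0
    - 45.0
    - 45.0
    - 45.0
    - 45.0
    - 45.0
    - 50.0
    - 50.0
    - 50.0
    - 50.0
    - 50.0
    seed_offset: 3
  dds_val2_aa:
    adulterant: apricot
    variety: 2
    wells_pct:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 7.0
    - 7.0
    - 7.0
    - 7.0
    - 7.0
    - 15.0
    - 15.0
    - 15.0
    - 15.0
    - 15.0
    - 22.0
    - 22.0
    - 22.0
    - 22.0
    - 22.0
    - 30.0
    - 30.0
    - 30.0
    - 30.0
    - 30.0
    seed_offset: 4
  dds_val1_ap:
    adulterant: peanut
    variety: 1
    wells_pct:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 5.0
    - 5.0
    - 5.0
    - 5.0
    - 5.0
    - 10.0
    - 10.0
    - 10.0
    - 10.0
    - 10.0
    - 15.0
    - 15.0
    - 15.0
    - 15.0
    - 15.0
    - 20.0
    - 20.0
    - 20.0
    - 20.0
    - 20.0
    - 25.0
    - 25.0
    - 25.0
    - 25.0
    - 25.0
    - 30.0
    - 30.0
    - 30.0
    - 30.0
    - 30.0
    - 35.0
    - 35.0
    - 35.0
    - 35.0
    - 35.0
    - 40.0
    - 40.0
    - 40.0
    - 40.0
    - 40.0
    - 45.0
    - 45.0
    - 45.0
    - 45.0
    - 45.0
    - 50.0
    - 50.0
    - 50.0
    - 50.0
    - 50.0
    seed_offset: 5
  dds_val2_ap:
    adulterant: peanut
    variety: 2
    wells_pct:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 7.0
    - 7.0
    - 7.0
    - 7.0
    - 7.0
    - 15.0
    - 15.0
    - 15.0
    - 15.0
    - 15.0
    - 22.0
    - 22.0
    - 22.0
    - 22.0
    - 22.0
    - 30.0
    - 30.0
    - 30.0
    - 30.0
    - 30.0
    seed_offset: 6
  pls_cal_aa:
    adulterant: apricot
    variety: 1
    wells_pct:
    - 0.0
    - 0.0
    - 0.0
    - 5.0
    - 5.0
    - 5.0
    - 10.0
    - 10.0
    - 10.0
    - 15.0
    - 15.0
    - 15.0
    - 20.0
    - 20.0
    - 20.0
    - 25.0
    - 25.0
    - 25.0
    - 30.0
    - 30.0
    - 30.0
    - 35.0
    - 35.0
    - 35.0
    - 40.0
    - 40.0
    - 40.0
    - 45.0
    - 45.0
    - 45.0
    - 50.0
    - 50.0
    - 50.0
    seed_offset: 7
  pls_val1_aa:
    adulterant: apricot
    variety: 1
    wells_pct:
    - 0.0
    - 0.0
    - 5.0
    - 5.0
    - 10.0
    - 10.0
    - 15.0
    - 15.0
    - 20.0
    - 20.0
    - 25.0
    - 25.0
    - 30.0
    - 30.0
    - 35.0
    - 35.0
    - 40.0
    - 40.0
    - 45.0
    - 45.0
    - 50.0
    - 50.0
    seed_offset: 8
  pls_val2_aa:
    adulterant: apricot
    variety: 2
    wells_pct:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 7.0
    - 7.0
    - 7.0
    - 7.0
    - 15.0
    - 15.0
    - 15.0
    - 15.0
    - 22.0
    - 22.0
    - 22.0
    - 22.0
    - 30.0
    - 30.0
    - 30.0
    - 30.0
    - 0.0
    - 0.0
    seed_offset: 9
  pls_cal_ap:
    adulterant: peanut
    variety: 1
    wells_pct:
    - 0.0
    - 0.0
    - 0.0
    - 5.0
    - 5.0
    - 5.0
    - 10.0
    - 10.0
    - 10.0
    - 15.0
    - 15.0
    - 15.0
    - 20.0
    - 20.0
    - 20.0
    - 25.0
    - 25.0
    - 25.0
    - 30.0
    - 30.0
    - 30.0
    - 35.0
    - 35.0
    - 35.0
    - 40.0
    - 40.0
    - 40.0
    - 45.0
    - 45.0
    - 45.0
    - 50.0
    - 50.0
    - 50.0
    seed_offset: 10
  pls_val1_ap:
    adulterant: peanut
    variety: 1
    wells_pct:
    - 0.0
    - 0.0
    - 5.0
    - 5.0
    - 10.0
    - 10.0
    - 15.0
    - 15.0
    - 20.0
    - 20.0
    - 25.0
    - 25.0
    - 30.0
    - 30.0
    - 35.0
    - 35.0
    - 40.0
    - 40.0
    - 45.0
    - 45.0
    - 50.0
    - 50.0
    seed_offset: 11
  pls_val2_ap:
    adulterant: peanut
    variety: 2
    wells_pct:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 7.0
    - 7.0
    - 7.0
    - 7.0
    - 15.0
    - 15.0
    - 15.0
    - 15.0
    - 22.0
    - 22.0
    - 22.0
    - 22.0
    - 30.0
    - 30.0
    - 30.0
    - 30.0
    - 0.0
    - 0.0
    seed_offset: 12
  ext_aa:
    adulterant: apricot
    variety: 1
    wells_pct:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 7.0
    - 7.0
    - 7.0
    - 7.0
    - 7.0
    - 15.0
    - 15.0
    - 15.0
    - 15.0
    - 15.0
    - 22.0
    - 22.0
    - 22.0
    - 22.0
    - 22.0
    - 30.0
    - 30.0
    - 30.0
    - 30.0
    - 30.0
    - 40.0
    - 40.0
    - 40.0
    - 40.0
    - 40.0
    - 45.0
    - 45.0
    - 45.0
    - 45.0
    - 45.0
    - 50.0
    - 50.0
    - 50.0
    - 50.0
    - 50.0
    seed_offset: 13
    external: yes
  ext_ap:
    adulterant: peanut
    variety: 1
    wells_pct:
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 7.0
    - 7.0
    - 7.0
    - 7.0
    - 7.0
    - 15.0
    - 15.0
    - 15.0
    - 15.0
    - 15.0
    - 22.0
    - 22.0
    - 22.0
    - 22.0
    - 22.0
    - 30.0
    - 30.0
    - 30.0
    - 30.0
    - 30.0
    - 40.0
    - 40.0
    - 40.0
    - 40.0
    - 40.0
    - 45.0
    - 45.0
    - 45.0
    - 45.0
    - 45.0
    - 50.0
    - 50.0
    - 50.0
    - 50.0
    - 50.0
    seed_offset: 14
    external: yes
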