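pixel_size: 0.65
channel_map:
  nuclei: 1
  glucagon: 2
  insulin: 3
  marker: 4
threshold_method: otsu
fixed_thresholds:
  glucagon: ~
  insulin: ~
  marker: ~
closing_radius_um: 1.3
mean_radius_um: 1.3
islet_closing_radius_um: 3.0
min_islet_area_um2: 1000.0
nucleus_max_diameter_um: 10.0
nucleus_mean_radius_um: 0.65
watershed_h: 1.0
fractional_mode: tissue
min_alpha_area_um2: 0.0
stats_policy: auto
s0: 0.01
n_permutations: 250.0
fdr: 0.05
seed: 1
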