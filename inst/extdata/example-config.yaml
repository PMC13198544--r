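# Example run configuration for the command-line interface.
# Unspecified fields fall back to default_config().
geometry:
  circle_radius_dva: 6.5
  dot_radius_dva: 0.7
  min_dot_distance_dva: 1.4
  min_hue_sep_deg: 5
design:
  n_subjects: 12
  trials_per_condition: 120
  conditions: uncued_CL
  presentation: simultaneous
params:
  kappa_colour: 10
  kappa_location: 15
  p_swap: 0.06
  p_cyclic_swap: 0.01
  g_feature: 0.12
  g_object: 0.05
  g_feat_swap_non: 0.1
  g_feat_swap_swp: 0.2
  g_obj_swap_non: 0.05
  g_obj_swap_swp: 0.15
  g_feat_cyclic: 0.1
  g_obj_cyclic: 0.05
priors:
  mean_loc: 0
  mean_scale: 1.5
  sd_scale: 1
  kappa_init: 5
mcmc:
  n_adapt: 5000
  n_iter: 10000
  n_chains: 4
  thin: 1
variant: full
seed: 1
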