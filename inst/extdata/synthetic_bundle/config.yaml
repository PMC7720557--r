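label: study-bundle
clock_model: igr
acrv_kind: gamma
n_rate_categories: 4
freq_model: symmetric
n_freq_categories: 4
alpha_dir_bounds:
- 0.05
- 20.0
strategy: nosa_diversity
x_cut: 66.0
rho: 1.0
shift_times: []
skyline_mask: s
clock_rate_prior:
  kind: lognormal
  meanlog: -3.912023
  sdlog: 1.0202013
clock_variance_prior_rate: 10.0
acrv_shape_prior_rate: 1.0
d_prior_rate: 10.0
r_prior:
- 1.0
- 1.0
s_prior:
- 1.0
- 1.0
root_prior:
  kind: offset_exponential
  offset: 247.2
  mean: 287.0
  sd: 15.0
  min: 247.2
  max: 298.9
partitioned: no
topology_fixed: no
base_rate_fixed: no
likelihood_on: yes
tree_prior_on: yes
fbd_fixed: ~
mode: clock
generations: 20000
sample_every: 10
burnin_frac: 0.25
n_runs: 2
seed: 7
tuning: ~
move_weights:
  node_age: 10.0
  root_age: 3.0
  tip_age: 5.0
  exchange: 5.0
  spr: 3.0
  base_rate: 3.0
  clock_variance: 3.0
  branch_rate: 10.0
  acrv_shape: 2.0
  alpha_dir: 0.0
  fbd_d: 3.0
  fbd_r: 3.0
  fbd_s: 3.0
  add_branch: 0.0
  delete_branch: 0.0
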