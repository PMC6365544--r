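# peatsim configuration. Every field is optional; omitted fields take the
# published defaults (see ?peat_params, ?sim_grid, ?sim_config).
params:
  N_in: 2.5        # nutrient input, g_N m-2 yr-1 (control parameter, 0-5)
  p: 0.5           # precipitation, m yr-1
grid:
  nx: 128
  ny: 128
  dx: 2            # m
sim:
  dt: 1.0e-4       # yr
  duration: 400    # yr
  snapshot_interval: 50
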