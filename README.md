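# peatsim

Reaction–diffusion simulation and quantitative pattern analysis of
ombrotrophic (rain-fed) peatlands, for spatial ecologists and modellers
studying vegetation self-organisation and its resilience to climate
stress.

Raised bogs arrange themselves into striking spatial patterns — moss
lawns dotted with sedge hummocks, labyrinths of ridges and hollows. One
proposed engine for this is nutrient accumulation: vascular plants
transpire, drawing down the local water table; the induced Darcy
groundwater flow advects nutrients toward them, reinforcing their growth
there and starving the surroundings. Fast water/nutrient transport
against slow biomass spread is a Turing mechanism, and a single control
parameter — the external nutrient input — carries the system through six
pattern regimes, from full *Sphagnum* cover through spots, labyrinths
and percolating networks to full vascular cover.

`peatsim` implements this model and the analysis pipeline around it:

* **Model**: four coupled PDEs on a periodic grid — vascular biomass
  `B`, *Sphagnum* biomass `S`, hydraulic head `H`, nutrient availability
  `N` (with pore-water concentration `N_c = N/(H·θ)`):

  ```
  ∂B/∂t = r_B·N_c·B·f(H) − (d+b)·B − c_BS·S − k_BS·S·B/(H_B+B) + D_B·∇²B
  ∂S/∂t = r_S·S·(1 − S/S_max) − k_SB·S·B/(H_S+S) + D_S·∇²S
  ∂H/∂t = (p − e·f(H) − t_v·f(H)·B)/θ + ∇·((k/θ)·H·∇H)
  ∂N/∂t = N_in − u·N_c·B·f(H) + (d·u/g)·B − r·N
          + ∇·(θ·D_N·H·∇N_c) + ∇·(k·H·N_c·∇H)
  ```

  where `f(H)` is a piecewise-linear water-stress gate in [0, 1].
  Explicit Euler stepping (compiled core), conservative face-flux
  transport, stability guard, yearly climate forcing.
* **Patterns**: binarisation, connected-component labelling *on the
  torus* with winding-number percolation detection, filling factors,
  regime classification (1–6), Gaussian transition peaks, and
  critical-exponent fits of the mean-cluster-area power law
  `𝒜 ∝ |p − p_c|^(−γ)`.
* **Experiments**: nutrient-input sweeps and regime thresholds,
  percolation scaling, climate-parameter sensitivity, climate-scenario
  runs, and drought experiments with resilience metrics (biomass drop,
  overshoot, recovery time, nutrient accumulation).
* **Synthetic inputs**: the published random initial condition, yearly
  climate scenarios, uncorrelated site-percolation reference fields, and
  power-law ground truth for the fitters.

## Worked example

Stabilize a peatland for 200 years at nutrient input 2.5 g m⁻² yr⁻¹ on
the scaled profile (64×64 cells at 4 m — the same 256 m domain as the
full-scale 128×128/2 m configuration) and classify the resulting
pattern:

```r
library(peatsim)
params <- peat_params(N_in = 2.5)
prof   <- scaled_profile(duration = 200)
init   <- random_initial_state(prof$grid, params, seed = 1)
traj   <- run_simulation(init, params, NULL, prof$config, prof$grid)
traj
#> <peat_trajectory> 5 snapshot(s), 200 yearly record(s), t = 200 yr
#>   final means: B = 837.20  S = 442.26  H = 0.6050  N = 4.3003
ps <- pattern_summary(traj$final, prof$grid)
```

which reports

```
regime 4 | vascular: 2 clusters, fill 0.436, percolates TRUE |
           Sphagnum: 12 clusters, fill 0.602, percolates FALSE
```

— at year 200 the vascular network percolates (wraps around the torus)
while *Sphagnum* has broken into finite fragments: regime 4, the
percolating-vascular-network state. (Run longer and the slow *Sphagnum*
reconquest pushes this toward regime 3, the steady state at this
nutrient level.) Mean head 0.61 m sits between the root depth (0.5 m)
and the stress threshold (1 m), and the mean nutrient stock has relaxed
from its nutrient-rich initial value 25 to 4.3 g m⁻².

The critical-exponent fitter, on noisy synthetic power-law data:

```r
pts <- power_law_cluster_samples(0.83, 0.37, seq(0.39, 0.5, 0.01),
                                 noise_sd = 0.05, seed = 2)
fit_percolation_exponent(pts$p, pts$area, p_c = 0.37, window = 0.2)
#> <percolation_fit> gamma = 0.801 +/- 0.023 (p_c = 0.370, 12 points, window 0.20)
```

A thin command-line wrapper over the same functions lives at
`inst/cli/peatsim.R` (subcommands `simulate`, `sweep`, `percolation`,
`sensitivity`, `climate`, `drought`; each writes its outputs plus a JSON
run manifest).

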