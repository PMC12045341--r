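# omequant

Quantitative single-molecule analysis of bacterial outer-membrane exchange
(OME). The package implements the full measurement chain used to
characterize TraAB-mediated membrane transfer between myxobacterial cells:

* **Photobleaching stoichiometry** — change-point step detection,
  unit-step (Δi) estimation by integer-lattice scoring, frame-exact
  re-segmentation, and per-focus molecule counting that handles coincident
  (2Δi) bleaching.
* **Dual-channel composition** — beam-splitter focus registration and
  pairing, per-channel counting, and zero-intercept stoichiometric ratio
  fitting (slope 1 ⇔ 1:1 complexes).
* **Single-particle tracking (sptPALM)** — sub-pixel 2D Gaussian
  localization, greedy nearest-neighbour linking inside a 0.320-µm gate,
  4–12-frame in-focus filtering, time-and-ensemble MSD, origin-constrained
  diffusion fits (`MSD = 4DΔt`), and track-resampling bootstrap errors.
* **Transfer-event detection** — trajectory/cell-mask intersection with
  boundary bridging, adjacency-aware crossing detection, event
  classification (unidirectional / bidirectional / serial), and
  crossing-to-focus proximity tests.
* **Membrane line profiles** — sub-sample density-peak localization by
  parabolic refinement, OM–OM / OM–IM separations, one-way ANOVA group
  comparison.
* **Ground-truthed synthetic data** — every estimator ships with a
  generator whose defaults reproduce the study acquisition conditions
  (160-nm pixels, 15-ms frames at 67 Hz, 200-ms frames at 5 Hz, ~25-nm
  localization precision), so parameter recovery is verified end to end.

## Worked example

Count the molecules in a simulated photobleaching focus (7 fluorophores,
unit step 5× the trace noise):

```r
library(omequant)

cfg <- sim_config(noise_sd = sim_config()$photon_scale / 5)
sim <- simulate_bleach_trace(7, cfg, n_frames = 300)
fit <- count_trace(sim$trace)
fit$n_molecules
#> [1] 7
fit$unit_step
#> [1] 1250.466
fit$change_frames
#> [1]  3  9 15 29 38 65
```

Six change points but seven molecules: one downward step is a 2Δi
coincident bleach and is counted as two.

Recover a diffusion coefficient with the full tracking pipeline
(render → localize → link → filter → MSD → fit), here 150 trajectories at
the outer-membrane preset truth of 0.19 µm²/s:

```r
set.seed(42)
cfg <- sim_config()
movie <- simulate_tracking_movie(diffusion_presets()[["om"]], 150, cfg)
dets <- detect_stack(movie$stack, cfg)
tracks <- filter_trajectories(link(dets, max_disp = 0.320))
estimate_D_tracks(tracks, frame_interval = cfg$frame_interval,
                  n_boot = 500, seed = 42)
#> D = 0.2159 um^2/s +- 0.0102 (bootstrap SD), n = 151 tracks, first 4 MSD points
```

(The origin-constrained fit overestimates D by ~7% at this localization
precision — see the vignette; the acceptance suite verifies recovery within
10% at the study scale of 1518 tracks.)

Detect an intercellular transfer event against cell masks:

```r
set.seed(7)
cfg <- sim_config(image_shape = c(48L, 48L))
cells <- adjacent_rod_pair(cfg)
sc <- simulate_ome_scenario(cfg, cells,
                            plans = list(c(1L, 2L), c(1L, 2L, 1L)),
                            render = FALSE)
masks <- cell_mask_set(sc$masks)
events <- detect_transfer_events(sc$tracks, masks, cfg)
events$events[[2]]
#> transfer_event (track 2): bidirectional, 2 boundary crossing(s), cells 1 -> 2
```

## One-command demo and CLI

```r
run_demo(seed = 1, output_dir = "demo_out")  # all stages, JSON + text report
```

A command-line front end lives at `inst/cli/omequant.R`:

```sh
Rscript inst/cli/omequant.R demo --seed 1 --out demo_out
Rscript inst/cli/omequant.R simulate --kind tracking --n 100 --out sim/
Rscript inst/cli/omequant.R track --stack sim/stack.tif --out tracks.csv
Rscript inst/cli/omequant.R msd --tracks tracks.csv --out diffusion.json
Rscript inst/cli/omequant.R bleachcount --traces traces.csv --out counts/
```

## Testing and acceptance

```r
testthat::test_dir("tests/testthat", package = "omequant",
                   load_package = "installed")
```

The acceptance experiments (full-scale recovery at 1518 OM, 2848 IM, and 39
boundary-crossing tracks, 1:1 dual-channel stoichiometry on 59 foci, 200-focus
step-count agreement, exact oracle equivalences, closed-form limits) live in
`tests/testthat/test-acceptance.R`; the three diffusion-recovery targets can
also be recomputed standalone:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

See `vignettes/outer-membrane-exchange-quantification.Rmd` for the methods
narrative and known estimator biases.
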