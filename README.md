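# erythrosim

Tools for studying how red blood cell (RBC) rigidity and shape shape the
geometry of RBC aggregates and, through it, the erythrocyte sedimentation
rate (ESR) — motivated by chorea-acanthocytosis, where spiky, rigid
acanthocytes coexist with normal-looking cells and patients show
paradoxically slow sedimentation.

The package implements four connected pieces:

* **A 2D mesoscopic aggregation simulator.** Each cell is a closed
  bead-spring ring of 50 vertices with spring, bending
  (`k_b (1 - cos θ)`) and area-constraint energies; healthy discocytes
  (bending 50 k_BT), rigidified discocytes (500 k_BT) and fully rigid
  six-lobed acanthocytes share one circumference (24.5 µm) but differ in
  enclosed area. Cells interact through a WCA excluded-volume core plus an
  adhesive Lennard-Jones tail (σ = 0.3 µm, r_cut = 0.72 µm, depth
  `eps_attr` ∈ [0, 3] k_BT) and move by overdamped Langevin dynamics
  (rigid cells as rigid bodies) in a periodic domain at 50% area fraction
  ("hematocrit").
* **Hole (void) statistics.** Configurations are rasterized; adhesive
  contacts are sealed; the plasma compartments between aggregated cells
  are labeled (4-connected, periodic) and summarized by a characteristic
  hole size — the scale of the exponential compartment-area distribution
  above a one-cell cutoff. Conditions are compared with Shapiro–Wilk,
  Kruskal–Wallis and Dunn-style rank tests (Holm-adjusted). Larger holes
  mean a more permeable aggregate and a faster ESR.
* **Sedimentation curves.** Sub-pixel extraction of the plasma/RBC
  interface from Westergren-tube image stacks (steepest-gradient with
  parabolic refinement, ≤ 0.1 mm error at realistic noise), the 2-hour
  reading, and between-visit percent change.
* **Shape phase diagrams from microfluidic flow.** Croissant and slipper
  fractions versus flow velocity are fitted with saturating exponentials
  `y(v) = y_inf + (y_0 - y_inf) e^{-v/v_char}`; the croissant/slipper
  **transition point** (equal fractions) is a deformability proxy, and the
  acanthocyte fraction is fitted with `φ_Ac(v) = N_0 e^{dv}` whose decay
  rate `d` measures acanthocyte rigidity.

A synthetic-data module (`gen_flow_records()`, `gen_tube_stack()`,
`rbc_cohort_fraction()`) generates every input with known ground truth,
including the fraction of circulating RBCs produced during a treatment
window (15-day maturation delay, 117.5-day lifespan).

## Worked example

Simulate a small mixed suspension and measure its compartment structure:

```r
library(erythrosim)

p <- model_params(domain = c(60, 60), n_steps = 20000L, seed = 1)
traj <- run_simulation(p, c(healthy_discocyte = 0.8, acanthocyte = 0.2))
fin  <- traj$snapshots[[length(traj$snapshots)]]
fin
#> rbc_snapshot: 80 cells in 60 x 60 um periodic domain, t = 1
#> kinds
#>       acanthocyte healthy_discocyte
#>                16                64

holes <- label_holes(rasterize(fin, 0.3), seal_below = 0.42)
characteristic_hole_size(holes, min_area_cutoff = p$A0_discocyte)
#> hole_stats: characteristic size 28.6 um^2 from 23 holes (censored_mean_excess)
```

The characteristic hole size is the mean compartment area in excess of the
one-cell cutoff (22.9 µm²); in sweeps over adhesion strength or over the
fraction of rigid cells it is the quantity compared across conditions.

Fit a synthetic shape phase diagram and locate the transition point:

```r
rec <- gen_flow_records(flow_generator_spec(seed = 42))
fits <- analyze_phase_diagram(rec)
fits$transition
#> transition point: v_t = 2.145 mm/s (bracket [2.136, 2.155], se 0.168)
fits$acanthocyte_fit
#> acanthocyte fit: N0 = 0.1149, d = -0.3569 per mm/s (|d| = 0.3569)
jackknife_transition_se(fits$table)$se
#> [1] 0.1570974
```

(The generating curves cross at 2.23 mm/s and use N0 = 0.12,
d = −0.35 per mm/s; the fits use binomial inverse-variance weights and
the jackknife resamples whole velocity groups.)

Extract a sedimentation curve from a synthetic tube stack and read the
2-hour value:

```r
gen <- gen_tube_stack(tube_generator_spec(n_frames = 130, plateau_mm = 40,
                                          midpoint_min = 90,
                                          steepness_min = 30,
                                          frame_rows = 900L, seed = 7))
curve <- sedimentation_curve(gen$stack)
esr_at_2h(curve)
#> ESR at 2 h: 27.35 mm
percent_change(during_treatment = 27.35, after_treatment = 11.7)
#> [1] 133.7607
```

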