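# actophase

Motility-enhanced polymer phase separation and condensate analytics.

Cytoplasmic biomolecular condensates are often transported along the
cytoskeleton by motor proteins, so their assembly is not purely passive.
`actophase` implements both halves of the computational argument that
directed transport *enhances* condensation:

* **Simulation.** Underdamped Langevin dynamics (BAOAB velocity-Verlet,
  compiled in C++) of flexible bead-spring polymers — FENE bonds
  (`K = 100 ε/σ²`, `R₀ = 1.5 σ`) plus a 12-6 Lennard-Jones pair
  potential (`ε = 0.40 k_BT`, cutoff `2.5 σ`) — in which "motility" is a
  constant force `F_act` along +z on the head bead of every active
  chain.  A fraction `f_passive` of chains receives no force.
* **Coexistence analytics.** Largest-cluster detection (union-find,
  minimum image), radial and directional density profiles, coexisting
  densities `ρ_den`/`ρ_sat`, derivative-based interfacial widths parallel
  and perpendicular to the force with a 10³-trial leave-one-out
  bootstrap, per-phase velocities in `σ/τ′` (`τ′ = 200 τ`), and
  active/passive partitioning.
* **Track motility analytics.** Windowed local MSD exponents `α`
  (12-frame windows; `α > 1` = active), per-step speeds and turning
  angles, joint speed–angle densities, speed-conditioned condensate-area
  distributions, and Kullback-Leibler divergences
  `D(P‖Q) = Σ Pᵢ ln(Pᵢ/Qᵢ)` with pseudocount regularisation.
* **Condensate sizing.** Per-spot ±5 px windows, 33%-of-max
  thresholding, nearest 8-connected component, and the standard
  normalized-second-central-moment ellipse
  (`A = π·(major/2)·(minor/2)`), with explicit exclusion accounting.
* **Synthetic data.** Ground-truth generators for condensate track
  cohorts (ballistic/Brownian mixtures with localization noise),
  fluorescence frames with elliptical Gaussian spots, and two-phase bead
  configurations — the whole pipeline is testable with no external data.

File formats: TrackMate-style CSV spot tables, TIFF stacks,
extended-XYZ and columnar trajectory dumps, flat key-value configs,
JSON/CSV reports.  A command-line entry point
(`inst/cli/actophase.R`, or `actophase_cli()` from R) exposes
`simulate`, `phase-analyze`, `tracks-analyze`, `area`, `synth` and
`pipeline` subcommands.

## Worked example

A scaled force scan (100 chains × 25 beads, box 32 × 32 × 50 σ — the
desk-size twin of the full 650-chain protocol):

```r
library(actophase)

p    <- sim_params(scale = "small", f_act = 2, seed = 1)
dump <- run_simulation(p)           # ~2 min: bias + 6e4 production steps
res  <- analyze_coexistence(dump)
res
#> coexistence_result (F_act = 2, f_passive = 0)
#>   rho_den = 0.5917, rho_sat = 0.0004972 (two-phase: TRUE)
#>   widths: parallel 9, perpendicular 6 sigma
#>   speeds (sigma/tau'): dense 16.7, dilute 18.9
```

`rho_den` is the polymer density inside the condensate and `rho_sat`
the coexisting dilute-phase (saturation) density, both in beads/σ³;
with the force on, `rho_sat` falls well below its passive value
(1.4×10⁻³ at `f_act = 0`, same seed) — the motility-enhanced condensation effect —
and the interface is visibly wider parallel to the force than
perpendicular to it.  Speeds are chain centre-of-mass displacements per
`τ′ = 200 τ`.

Track analytics on a synthetic cohort with known ground truth:

```r
tracks <- make_tracks(n_tracks = 200, n_frames = 40,
                      frame_interval = 0.15, active_fraction = 0.3,
                      speed = 2, diffusion = 0.05, seed = 7)
res <- analyze_tracks(tracks, window = 12)
res$summary$track_active_fraction
#> [1] 0.3
```

30% of tracks were generated ballistic and the windowed-MSD classifier
(`α > 1` on the per-track median exponent) recovers exactly that
fraction.

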