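---
title: "Methods: motility-enhanced phase separation and condensate analytics"
author: "actophase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motility-enhanced phase separation and condensate analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Biomolecular condensates in plant cells are not only shaped by passive
thermodynamics: many of them are hauled along the cytoskeleton by motor
proteins.  `actophase` implements the two halves of the computational
argument that such motility *enhances* condensation:

1. a coarse-grained Langevin simulation of bead-spring polymers in which
   "motility" is a constant force on one designated head bead per chain,
   together with the coexistence analytics (saturation density
   $\rho_{sat}$, dense density $\rho_{den}$, interfacial widths parallel
   and perpendicular to the force, per-phase velocities, active/passive
   partitioning); and
2. the condensate-tracking analytics applied to microscopy-derived spot
   tables: windowed mean-squared-displacement (MSD) exponents that
   classify motion as active ($\alpha > 1$) or passive, per-step speeds
   and turning angles, speed-conditioned size distributions with their
   Kullback-Leibler (KL) divergences, and moment-based ellipse sizing of
   condensates in fluorescence frames.

Synthetic-data generators stand in for the microscopy data, so every
stage of the pipeline is testable against known ground truth.

# The polymer model

Chains of 25 beads interact through a truncated 12-6 Lennard-Jones
potential $U(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]$ with
$\epsilon = 0.40\,k_BT$ and cutoff $2.5\,\sigma$ (plain truncation by
default; a cut-shifted variant is available via `shift_lj`).  Consecutive
beads are bonded by the FENE potential
$U_{FENE}(r) = -\tfrac12 K R_0^2 \ln(1 - (r/R_0)^2)$ with
$K = 100\,\epsilon/\sigma^2$ and $R_0 = 1.5\,\sigma$, the standard
Kremer–Grest maximum extension; both are exposed as parameters.

One modelling point deserves emphasis: the pair interaction is applied to
*all* bead pairs, including bonded ones (`bonded_lj = TRUE`).  A pure
FENE bond has its energy minimum at $r = 0$; without the short-range
repulsion the bonds collapse to a fraction of a bead diameter and the
chain physics changes entirely.  Standard molecular-dynamics FENE bond
implementations bundle the repulsion for exactly this reason, and the
resulting equilibrium bond length here is $\approx 0.9\,\sigma$.

Activity is a constant force $F_{act}$ along $+z$ added to the first
bead of every active chain; passive chains (a fraction `f_passive`,
assigned to the highest chain ids so labeling is seed-independent)
receive nothing.  Units are reduced throughout: $\sigma = k_BT = m = 1$,
so $\tau = \sigma\sqrt{m/k_BT} = 1$ and forces are in $k_BT/\sigma$.

## Integration

The Langevin equation is integrated with the BAOAB splitting of
underdamped Langevin dynamics: half kick, half drift, exact
Ornstein–Uhlenbeck velocity refresh with friction
$\gamma = m/\mathrm{damping}$ ($\mathrm{damping} = 0.50\,\tau$,
$dt = 0.01\,\tau$), half drift, half kick.  With the thermostat disabled
(`damping = Inf`) the scheme reduces to plain velocity-Verlet, which is
how the energy-conservation tests run.  For a free particle the O-step
is exact, so the free-bead kinetic temperature is unbiased — the
equipartition check asks for $1.00 \pm 0.02\,k_BT$ and passes with a
wide margin.  Noise comes from a self-contained xoshiro256++ generator
seeded from the run seed, making trajectories bit-reproducible
independent of R's RNG state.

Forces are evaluated through a Verlet list built from a cell list
(skin $0.3\,\sigma$, rebuilt when any bead has moved half the skin);
small systems fall back to all-pairs enumeration, and tests pin the two
paths together to $10^{-10}$.

## Initialization and protocol

Chains are laid down as random walks, overlaps are relaxed by a short
push-off in which the pair force is capped (5, then 20, then 100
$k_BT/\sigma$ at $dt = 0.002$) while the FENE restoring force is never
capped — bonds must stay below $R_0$.  A weak harmonic bias
($0.05\,\epsilon/\sigma^2$ per bead) toward the box centre then collects
all chains into one dense droplet; the bias is removed for production.
Initialization fails loudly if fewer than 90% of chains end up in one
cluster.

The full-scale protocol (`scale = "full"`) is 650 chains in a $64 \times 64 \times 100$
box, $2\times10^5$ bias steps, $5\times10^7$ production steps with
snapshots every $2\times10^4$ steps and the last half analysed.  That is
hours of CPU per force value, so the package also defines a scaled twin
used by its own test suite: 100 chains in $32 \times 32 \times 50$,
$2\times10^4$ bias steps, $6\times10^4$ production steps, snapshots
every $10^3$ steps, last half analysed.  These sizes were chosen so that
a 3-seed scan over $F_{act} \in \{0, 1, 2, 3\}$ completes in minutes
while the passive system still shows clean two-phase coexistence
($\rho_{den}/\rho_{sat} \gtrsim 100$ here, since $\epsilon = 0.4$ is
deep in the poor-solvent regime for 25-mers).

# Coexistence analytics

For every analysis snapshot the largest cluster is found by
single-linkage clustering of beads at a $1.5\,\sigma$ cutoff (the first
coordination shell) with union-find; a chain belongs to the cluster when
the majority of its beads do.  The cluster centre of mass uses circular
means per coordinate so it is well defined across periodic boundaries.

The isotropic radial density profile counts beads in spherical shells
around that centre ($0.5\,\sigma$ bins).  Shells inside the inscribed
sphere use analytic volumes; beyond it they are clipped to the periodic
box with a deterministic Monte-Carlo volume estimate, and the profile
reaches into the box corners by default.  Plateaus are detected on a
3-bin volume-weighted moving average (pooled counts over pooled shell
volumes, so the Poisson noise of tiny central shells cannot spike the
smoothed profile): bins where $|d\rho/dr|$ falls below 10% of its
maximum.  $\rho_{den}$ is the volume-weighted mean over the plateau run
containing the density maximum, where the maximum is located only among
bins of at least $15\,\sigma^3$ shell volume (smaller shells hold a
handful of beads and cannot anchor a density); when a drifting or
diffuse cluster leaves the dense arm gently sloping everywhere — no
plateau contains the maximum — the dense core, the contiguous bins
within 80% of the maximum, stands in.

Two saturation-density estimates are reported.  `rho_sat_profile` is
the volume-weighted mean over the outermost plateau — the direct
profile reading.  The primary `rho_sat` is the cluster-based gas
density: beads of chains outside the largest cluster divided by the gas
volume.  The two agree for compact droplets, but a strong force pulls
the dense phase into a prolate shape whose lobes reach the far field of
the *spherical* profile and inflate its outer plateau; the cluster
criterion is immune to the dense phase's shape, which is why it is the
headline number.  At the scaled conditions the gas holds only a few
chains, so `rho_sat` is averaged over all analysis snapshots and its
granularity (one chain $\approx 5\times10^{-4}$ beads/$\sigma^3$ per
snapshot) is the dominant noise source — see "Limitations".

Directional profiles are defined geometrically:
the $z = 0$ slab (half-thickness $1\,\sigma$) binned by in-plane radius
gives the *perpendicular* profile; the $x = 0$ and $y = 0$ slabs,
binned by in-plane radius in their own planes and averaged, give the
*parallel* profile.  Interfacial widths are the extent of the
contiguous region around the steepest descent where the derivative
magnitude exceeds 10% of its maximum, computed on the unsmoothed
profile (central differences already regularise single-bin noise, and
smoothing would broaden an exactly-constructed ramp).  An interface
sharper than one bin reports one bin width rather than an error.  The
leave-one-out bootstrap deletes one profile point per trial ($10^3$
trials, seeded, trials that destroy the interface are skipped but
counted) and returns the mean and standard deviation.

Per-phase velocities are chain-COM displacements between consecutive
snapshots divided by elapsed time, averaged within the dense (largest
cluster) and dilute populations, in units of $\sigma/\tau'$ with
$\tau' = 200\,\tau$.  Note that at short snapshot spacing the estimate
contains a diffusive floor, so its absolute value depends on the dump
interval; comparisons across force values at fixed spacing are the
meaningful statistic.  Partition fractions are reported under both
normalisations in common use — per total chains and per label class —
rather than privileging one.

# Track motility analytics

`local_msd_exponents()` slides a 12-frame window along a track; within
each window the MSD over lags $1..\lfloor\mathrm{window}/3\rfloor$ is
fit in log–log space and the slope is the local exponent $\alpha$
(1 = Brownian, 2 = ballistic; zero-MSD windows yield `NA`, flagged not
thrown).  Classification counts a window active when $\alpha > 1$; the
window-level active fraction is the primary statistic — what is counted
are occurrences of active movement, not whole trajectories — and a
per-track label (median defined $\alpha$ above threshold) is provided
as a convenience.

Speeds are per-step displacements over elapsed time; turning angles are
the angle between consecutive displacement vectors in $[0°, 180°]$.
Joint speed–angle histograms normalise to unit mass.  Area
distributions conditioned on speed intervals (quartiles of the pooled
speeds by default) share one set of bin edges, and
$D(P\|Q) = \sum_i P_i \ln(P_i/Q_i)$ is computed after adding a
pseudocount ($10^{-6}$ by default; 0 is allowed for the analytic cases,
where an empty prior bin under the posterior's support returns infinity
with a flag).  Natural log is the default; bits are available.  The divergence is
asymmetric and either cohort can meaningfully serve as the prior, so the
pipeline reports both directions and callers choose explicitly.

# Synthetic data: what it emulates and what it does not

`make_tracks()` generates active tracks (constant speed along a
persistent heading plus diffusion) and passive tracks (pure diffusion),
both observed through Gaussian localization noise, at 2.3 frames/s or
0.15 s per frame.  The default localization noise of 0.1 µm is a
typical centroid uncertainty for dim, moving spots; it matters
scientifically: noise flattens the short-lag MSD, which is what makes
passive condensates read as subdiffusive ($\alpha < 1$) in real
recordings.  Without it, a finite-window $\alpha$ estimate for ideal
Brownian motion is symmetric around 1 and no threshold-at-1 classifier
can separate the classes; with it, a 30/70 ballistic/Brownian cohort is
recovered at $0.30 \pm 0.05$ with >99% per-track accuracy.  The
generator does not emulate motor stalling, heading reversals, blinking,
or track fragmentation.

`make_images()` renders anisotropic Gaussian spots whose standard
deviations are chosen so the 33%-of-peak contour has the stated axes,
pinning the rendered ground truth to the sizing pipeline's moment
convention (axis $= 4\sqrt{\lambda}$ of the pixel covariance with the
$+1/12$ per-pixel correction).  The exactness of that correspondence
degrades as the constant background approaches the peak intensity,
because the pipeline thresholds at 33% of the *maximum pixel value*;
the generator makes no attempt to emulate deconvolution artefacts or
spatially varying background.  `make_slab_configuration()` places beads
uniformly at $\rho_{den}$ inside a sphere/ellipsoid and $\rho_{sat}$
outside, with chain ids in contiguous blocks purely for bookkeeping.

Passing tests on these generators show the *analytics* are correct and
the pipeline wiring is sound; they do not validate biological claims
about any particular protein system.

# Numerical choices and degenerate inputs

* Tolerances: neighbour-list forces match all-pairs to $10^{-10}$;
  microcanonical energy drift $< 10^{-4}\,k_BT$/bead over $10^4$ steps
  (with the cut-shifted potential, since plain truncation injects
  $O(10^{-3})$ jumps at cutoff crossings); KL identities hold to
  $10^{-12}$.
* Fixture recovery tolerances for $(\rho_{den}, \rho_{sat})$ are
  expressed relative to the density contrast
  $\rho_{den} - \rho_{sat}$: a $w = 2\,\sigma$ tanh profile never comes
  within 15% (relative) of its asymptotic $\rho_{sat}$ anywhere inside
  the box, so "within 2%" can only coherently refer to the contrast
  scale.
* Monotone/flat profiles are single-phase results, not exceptions; an
  all-dark subimage or an edge-clipped window is an excluded
  measurement with a reason, not an exception; a stationary track has
  undefined $\alpha$, not an error.
* Ties in nearest-component selection go to the lower label id
  (raster order), deterministically.
* The default speed intervals are quartiles of the pooled speed
  distribution; explicit edges are accepted.

# Design choices where the design was genuinely open

* Underdamped dynamics (velocity-Verlet plus damping implies it);
  documented rather than assumed silently.
* Periodic boundaries in all three directions, minimum image
  everywhere.
* Cluster cutoff $1.5\,\sigma$; profile bin $0.5\,\sigma$; slab
  half-thickness $1\,\sigma$; derivative threshold 10%; all exposed as
  arguments.
* Direction naming: the $z = 0$ slab samples the directions
  perpendicular to the force, so its profile is the *perpendicular* one;
  the $x = 0$ and $y = 0$ slabs contain the force axis and give the
  *parallel* profile.  The converse naming is sometimes seen but is not
  geometrically coherent.
* 8-connectivity for component labeling; "nearest" means minimum pixel
  distance from the central pixel.
* Thresholding uses $\ge$ (at exactly the threshold a pixel is
  foreground).

# Limitations

* The scaled simulation conditions put the strong-force gas in the
  small-number regime: at $F_{act} \ge 2$ the dilute phase holds of
  order one chain, so seed-to-seed medians of $\rho_{sat}$ carry
  relative errors of tens of percent and the force ordering between
  *adjacent* strong forces can invert by a fraction of one chain even
  when the overall order-of-magnitude drop is unambiguous.  The full
  protocol does not have this problem (its gas holds hundreds of
  beads); `scripts/full_scale.R` runs it for those with hours of CPU.
* $6\times10^4$ production steps leave the passive gas still slowly
  filling toward saturation, biasing the scaled $\rho_{sat}$ at
  $F_{act} = 0$ low — i.e. *against* the package's own headline trend,
  so the trend is not an equilibration artefact.
* No hydrodynamics, no GPU/MPI parallelism, no grand-canonical or
  slab-geometry free-energy machinery, no finite-size-scaling of the
  critical point; spot detection and linking are upstream concerns
  (the package consumes tracking tables, it does not produce them).
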