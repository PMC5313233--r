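---
title: "Transition pathways and enhanced sampling with pathdyn: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transition pathways and enhanced sampling with pathdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathdyn)
```

## What this package computes

`pathdyn` implements the computational machinery used to characterize slow
conformational transitions — such as the activation-loop rearrangement of a
receptor tyrosine kinase switching between its inactive and active states —
on analytic model systems where every result can be checked against an
independent oracle:

1. **Zero-temperature string method (ZTS)**: a discretized path ("string of
   images") between two minima is relaxed by steepest descent with periodic
   reparametrization, converging to the minimum energy path (MEP).
2. **Finite-temperature string method in collective variables (CVs)**: each
   image restrains a sampler to CV targets `z*`; the mean force on target
   `i` is estimated as `k <z_i* - z_i>` from the restrained average, the
   targets evolve by the overdamped rule
   `z*(t+dt) = z*(t) - dF/dz dt / (gamma m)`, and the string is
   reparametrized to equal CV-space spacing after each update.  The
   potential of mean force along the converged path is
   `F(alpha) = ∫ sum_i (dF/dz_i)(dz_i/dalpha) dalpha`, with `dz/dalpha`
   by centered differences and the integral by the trapezoidal rule.
3. **Well-tempered, multiple-walker metadynamics**: repulsive Gaussian
   hills of initial height 0.7 kcal/mol and width 0.1 are deposited every
   500 steps on the biased CVs, with the deposited height damped by
   `exp(-V_bias / kB ΔT)` at bias temperature ΔT = 4200 K; ten walkers
   share a single hills log.  The free energy surface is recovered as
   `F = -(T+ΔT)/ΔT V_bias`.
4. **Contact-map CVs**: each contact contributes the rational switching
   term `(1-x^6)/(1-x^12)` with `x = (r-d0)/r0` and `r0 = 8` Å, evaluated
   through the singularity-free equivalent `1/(1+x^6)`.  Contacts are
   selected between two reference conformers when the pair distance
   crosses 8 Å between states and the larger distance is at least 1.5
   times the smaller.
5. **Ensemble analysis**: pairwise RMSD (with Kabsch superposition),
   complete-linkage agglomerative clustering bounded by a 3.0 Å cluster
   diameter, cluster networks linked at 3.8 Å, geometric state classifiers
   (strict "more than 50 % of frames within 8 Å" style criteria), density
   maps contoured at 0.005 intervals, and RMSF profiles.
6. **Reaction-coordinate driving**: successive restrained minimizations of
   `U + k/2 (RC - target)^2` along `RC = d1 - d2 - d3`, the classic
   bond-breaking-minus-bond-forming combination of a phosphotransfer
   reaction.

All stages run end-to-end on two kinds of synthetic systems: analytic
multi-basin potentials with known minima and saddles (harmonic wells, 1D/2D
quartic double wells, and the Mueller–Brown surface in its standard
reduced-unit parameterization) and a two-state bead-chain "loop" whose two
reference conformers plant a known set of contact-crossing pairs.

## Units and integrator

One unit system is used throughout: Å, ps, kcal/mol, amu, K, with
`kB = 0.0019872041` kcal/mol/K and the conversion
1 kcal/mol = 418.4 amu Å²/ps² applied wherever forces update momenta
(`sim_constants()`).  Langevin dynamics uses the BAOAB splitting, which
samples configurations accurately even at high friction; at zero
temperature it reduces to damped (or, at zero friction, Hamiltonian)
dynamics, which the tests use for energy-conservation and descent checks.
Constant-volume Langevin stands in for the barostatted equilibration of
all-atom workflows; there is no solvent, thermostat chain, or pressure
coupling here, deliberately.

## The synthetic systems and what they do (and do not) emulate

The two-state bead-chain (`make_two_state_loop()`) emulates exactly the
features the contact-map machinery needs: two reference conformers (an
extended "inactive" zig-zag and a folded "active" hairpin) whose
inter-bead distances cross the 8 Å contact threshold with at least a 1.5×
ratio — so the selection rule recovers the planted pairs exactly — plus
Boltzmann-weighted basin occupancies and Gaussian thermal noise.  Defaults
(12 beads, 3.8 Å bonds, 0.5 Å noise, 300 K, symmetric basins) are chosen
as the plain-vanilla coarse-grained loop a structural modeller would
sketch.  The generator draws frames about rigid references; it does not
emulate bonded correlations, anisotropic fluctuations, or gradual
interconversion pathways, so passing the clustering and classification
tests shows the bookkeeping and metrics are right, not that real kinase
ensembles would partition this way.

The Mueller–Brown surface is the community-standard MEP benchmark; its
three minima and two saddles are located independently in the tests by
Newton iteration on the analytic gradient (`find_stationary_point()`), and
path quality is measured as the distance from the string polyline to those
saddles.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| CV restraint `k` (string) | 1.0 | kcal/mol/Å² | protein-scale default; see below for steep surfaces |
| evolution friction `gamma` | 125 | ps⁻¹ | overdamped target motion |
| effective mass `m` | 12.011 | amu | carbon |
| update stride | 10 | MD steps | ensemble average window per update |
| evolution `dt` | stride × MD timestep | ps | dimensional consistency with the stride |
| burn-in | 10 × stride | MD steps | re-equilibration after each reparametrization (discarded) |
| hill height `h0` | 0.7 | kcal/mol | well-tempered initial height |
| hill width `sigma` | 0.1 | CV units | per-CV, non-adaptive |
| deposition stride | 500 | MD steps | |
| bias temperature `ΔT` | 4200 | K | bias factor 15 at 300 K |
| bias grid spacing | 0.002 | CV units | |
| walkers | 10 | | shared hills log |
| cluster diameter | 3.0 | Å | complete-linkage cut |
| network link | 3.8 | Å | single-linkage edges by default |
| contour interval | 0.005 | density | |
| switching radius `r0` | 8 | Å | contact threshold |
| contact ratio | 1.5 | | larger/smaller distance |

Two parameters deserve comment because the package's own benchmarks depart
from the protein-scale defaults.  On the Mueller–Brown surface the energy
scale is reduced units where curvatures are O(1000): a CV restraint of
`k = 1` lets the restrained walkers slide to the valley floor, and the
converged string is the MFEP smoothed by a factor `k/(k + H)` (H the local
transverse curvature), which visibly cuts the corner at the upper saddle.
The bundled benchmark therefore uses `k = 2000` and an explicit evolution
step `dt = 5e-4` ps (the default `dt = stride × timestep` moves targets too
far per update on a surface this steep and can throw them onto
exponentially rising walls).  Both are exposed arguments; on soft,
protein-scale landscapes the defaults stand.

## Numerical choices

* **Reparametrization** places images at equal arc length along the
  piecewise-linear polyline through the current images (single pass,
  endpoints untouched).  On a curved polyline, equal *arc* spacing is not
  equal *chord* spacing — the tests therefore verify equal spacing and
  length preservation in the along-polyline metric, using an independent
  projection oracle.
* **ZTS convergence** is schedule-based (fixed iterations per stage,
  doubling 4 → … → final, then extraction of equally spaced images), not
  tolerance-based.  The descent step is a fixed per-surface step size.  A
  discrete string with chord tangents retains a small perpendicular
  gradient component at convergence (discretization, not failure): the MEP
  property is asserted as the *normalized* perpendicular component (relative
  to the local gradient magnitude), with a median around 1 % on the
  benchmark.
* **Doubling bookkeeping**: `double_images()` inserts one midpoint per
  interval; the `middle_double` flag additionally inserts two images in the
  central interval (giving 2n instead of 2n−1 images), exposed as a
  schedule option because either convention is defensible.
* **Mean-force errors** use block averaging with 5 blocks, since restrained
  samples are serially correlated.
* **Hill heights at deposition** are computed from the exact sum over all
  previously logged hills rather than the grid interpolant, so the entire
  well-tempered decay is reproducible from the log alone (the replay
  invariant holds to float tolerance); the grid — 0.002 spacing, hills
  truncated at 6 sigma — only supplies per-step bias forces to the dynamics.
* **Walker synchronization** is deterministic: per round, all walkers
  advance `stride` steps in id order, then deposit in id order, each
  deposit seeing all earlier hills.  Real multiple-walker implementations
  share files asynchronously; determinism was preferred here so every run
  is bit-reproducible under a seed.
* **Bias-temperature convention**: "bias temperature 4200 K" is read as ΔT
  (bias factor `(T+ΔT)/T` = 15 at 300 K); `wt_params(interpretation =
  "total")` switches to the `T+ΔT` reading.
* **Contact-map semantics**: the printed rational form is maximal (√n) at
  the reference — a similarity.  Both that literal variant and a true
  distance variant (root-sum-square of switching-term deviations, 0 at the
  reference) are first-class, because prose ("distances in contact map
  space") and formula disagree; the default is the literal form.
* **Clustering** buys `stats::hclust(method = "complete")`: for complete
  linkage the merge height of a cluster equals its diameter, so cutting the
  tree at the threshold yields exactly the diameter-bounded partition; the
  invariant is still certified post hoc on every call.  Ties in merge order
  follow `hclust`'s deterministic ordering; clusters are renumbered by
  smallest member frame id so shuffling frames permutes labels only.
* **"Graph distance" between clusters** defaults to
  representative-(medoid-)RMSD nearest-neighbor rather than path length
  through the network, since the statistic is reported in Å; a
  single-linkage mode is available.
* **Degenerate inputs** are first-class errors: zero-length paths, empty
  sampling windows, empty selections, non-crossing planted pairs, unknown
  reference states, out-of-range indices, coincident particles in distance
  gradients.

## The restrained-fluctuation experiment

The package reproduces, on beads, the qualitative experiment in which a
"guardian" side chain stabilizes a substrate at the active site: a weakly
anchored substrate bead, a firmly anchored guardian bead 4.5 Å away, and a
stiffly anchored site bead.  Three production conditions differ only in
their restraints — guardian-in (substrate–guardian distance flat-bottomed
above 6 Å at 5 kcal/mol/Å²), intermediate (guardian tethered to the site
bead; the substrate itself unrestrained), and guardian-out (substrate
excluded within 10 Å of the guardian).  The substrate RMSF orders strictly
in < intermediate < out across seeds; only this ordering, not any
magnitude, is asserted.  An earlier design based on a short-range
attractive well between guardian and substrate was discarded: against a
weak anchor such a well is bistable (the substrate is either captured onto
the interaction shell or free), which makes the intermediate condition
statistically indistinguishable from full stabilization.

## Problem sizes

The test-suite and acceptance benchmarks use: ZTS 4 → 64 images (60
iterations per stage, 20 descent steps) with 32 extracted images; string
method 32 images × 80 updates with a 2000-step final sampling pass;
metadynamics 10 walkers × 60 000 steps (1 200 hills); clustering pools of
30–48 frames; RMSF runs of 40 000–120 000 steps; 24-stage reaction
driving.  These sizes give the oracle comparisons comfortable margins
(saddle distances ~0.02 against a 0.05 bound; basin free-energy differences
within ~0.1 kcal/mol against a 0.3 bound) while keeping a full run on one
CPU in minutes.

## Known limitations

* No all-atom force fields, solvent, electrostatics, or constraint
  algorithms; the Langevin sampler is the only dynamics engine.
* The metadynamics module does not implement reweighting estimators or
  adaptive hills; free energies come from the inverted bias only.
* Bias grids support one or two CVs (the use cases here); direct summation
  works in any dimension but scales with the log length.
* PDB I/O (via bio3d) writes beads as CA atoms of sequential residues —
  convenient for visualization, not a claim of chemistry.
* The finite-temperature string assumes the restrained sampler equilibrates
  within the burn-in window; stiff restraints on rugged landscapes may need
  longer burn-in than the default.
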