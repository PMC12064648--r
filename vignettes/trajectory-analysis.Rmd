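---
title: "Quantifying fibril-interface patch exposure and ligand-contact
  reorganization in MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fibril-interface patch exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taupatch)
```

## The analysis in one paragraph

Aggregation cofactors can act by holding a protein in a conformation whose
fibril-interface residues stay solvent-exposed.  For tau K18 (residues
244–372) the readout is the surface area of the three consecutive glycines
333–335 — the GGG patch at the heart of the fibril interface — tracked
frame by frame over a trajectory, classified against a 100 Å² exposure
threshold, summarized per trajectory half, and read jointly with how the
ligand's residue-contact set reorganizes between the same halves.
`taupatch` implements that chain of analyses plus the synthetic
trajectories needed to verify each link without an MD engine.

## Observables and their definitions

**Superposition RMSD.**  For each frame the selected atoms are superposed
onto the reference (by default the first frame) with the Kabsch algorithm:
the weighted covariance `H = Aᵀ W B` of the centred coordinate sets is
decomposed as `H = U S Vᵀ` and the optimal proper rotation is
`R = U diag(1, 1, det(VUᵀ)) Vᵀ`; the determinant factor excludes
reflections.  `kabsch_superpose()` refuses fewer than three points or
collinear sets, where the rotation is not identifiable; `rmsd_series()`
still reports the (well-defined) minimum RMSD for such degenerate
selections through a closed-form axis alignment, so a two-atom bond
stretched by δ gives RMSD = δ/2 exactly.  The default selection is Cα
with uniform weights — the conventional backbone RMSD; mass weighting and
other selections are config knobs because the convention is not universal.

**Radius of gyration.**  `Rg = √(Σ wᵢ ‖rᵢ − r̄‖²/Σ wᵢ)` with the weighted
centroid `r̄`; uniform weights by default, masses optionally.  Rg and RMSD
are invariant under global rigid motion, which the tests enforce at 1e-8 Å.

**Patch exposure.**  Per-atom solvent-accessible surface area is computed
with the Shrake–Rupley construction: each atom's van der Waals sphere is
inflated by the probe radius (default 1.40 Å, a water-sized probe), test
points are placed on it, and a point is accessible when it lies outside
every other atom's inflated sphere; the atom's SASA is the accessible
fraction of `4π(rᵢ + p)²`.  The patch area is the sum over all atoms of
the patch residues, computed in the context of the *full* structure —
every atom occludes, including ligand atoms (a flag excludes them, since
whether a bound cofactor should shadow the patch is a modelling choice,
not a fact of the data).  A frame is *exposed* when the patch area is at
or above the threshold; the tie goes to exposed because the threshold
definition only specifies strict inequalities on either side and the
classifier must be deterministic.  Segment statistics are the per-half
mean, sample SD (n−1 denominator: frames are a finite sample of the
regime) and fraction of exposed frames.

**Contacts.**  A residue is in contact with the ligand in a frame when
the minimum distance between its heavy atoms and the ligand atoms is at
or below the cutoff (default 4.5 Å, the common heavy-atom protein–ligand
convention; the underlying study's cutoff is not stated, so it is an
explicit knob).  The relative contact frequency of a residue within a
segment is the plain fraction of that segment's frames in contact; an
optional max-normalization is provided but off by default, the plain
fraction being the minimal defensible reading.  Residues whose frequency
rises by ≥ 0.25 between the halves are *gained*, falls by ≥ 0.25 *lost*;
no hypothesis test is attached, deliberately — frames are strongly
autocorrelated and a binomial test would be badly miscalibrated.

**Segmentation.**  One shared rule for both analyses (`segment_frames()`):
halves split at `ceiling(n/2)`, the extra frame of an odd count going to
the first half.  Sharing one implementation guarantees the exposure and
contact halves always agree.

## Numerical choices

* **Quadrature.**  Test points are a golden-section spiral — deterministic,
  seed-free, uniform to O(1/n).  Default 960 points puts the per-atom
  quadrature quantum at `4π(r+p)²/960` ≈ 0.13 Å² for carbon, far below the
  effects of interest; the floor of 92 points mirrors the original
  algorithm's coarsest published grid.  An isolated sphere is reproduced
  within one quantum; two overlapping spheres match the spherical-cap
  closed form within 2 % across separations.
* **Neighbour search.**  SASA uses a cell list with edge `2(r_max + p)`,
  which provably contains every occluding pair, with candidates sorted to
  match the all-pairs scan order; the two paths return bit-identical
  areas and the tests assert exactly that up to 500 atoms.
* **Densities.**  Gaussian KDE with Silverman's rule-of-thumb bandwidth
  (`stats::bw.nrd0`), renormalized so the trapezoidal integral over the
  returned grid is 1 within 1 %; a constant series falls back to a narrow
  histogram with a warning rather than failing.
* **Altloc and elements.**  Alternate locations keep the
  highest-occupancy conformer (ties → 'A', then first seen); elements come
  from the PDB element column when present, else from atom-name
  heuristics (left-justified two-letter names are metals/ions; a leading
  digit marks a hydrogen).
* **Units.**  Å and ns everywhere internally; sources storing nm are
  converted once, at read time (`units = "nm"`).

## What the synthetic generators emulate

All three generators build the same coarse-grained chain: one
pseudo-Cα bead per residue (ids 244–372 by default) on a solenoid with
exact 3.8 Å virtual bonds, 9 beads per turn and 6.3 Å per turn — compact
enough that a tucked patch is genuinely occluded, open enough to be
self-avoiding.  Bead radius defaults to 1.70 Å, the Bondi carbon radius,
so radii survive a PDB write/read round trip unchanged; with the 1.4 Å
probe the effective 3.1 Å spheres give a three-bead patch an achievable
area range of roughly 64–362 Å², bracketing the 100 Å² threshold.

* **Two-regime exposure.**  The patch beads slide along their radial
  direction by a common offset d(t): d ≈ −9 tucks them against the far
  solenoid wall (deep burial), positive d pushes them clear.  d(t) follows
  a mean-reverting AR(1) process (lag-1 correlation 0.8) whose per-regime
  stationary mean/SD are calibrated at generation time: the d→area map is
  measured on a pilot grid, and the process parameters are iterated under
  a deterministic Gaussian quadrature until the mapped area distribution
  has the requested mean and SD (defaults 113/24 Å² then 121/11 Å²,
  switching at the midpoint — the study conditions this package is built
  around).  Requested means outside the achievable range raise an
  "unattainable target" error.  Ground truth records the *realized*
  per-half sample statistics recomputed from the coordinates (via the
  all-pairs SASA path), never the requested targets; recovery tests
  compare pipeline output — after a PDB round trip, radii re-assignment
  and the cell-list path — to those realized values.  Both routes share
  the same quadrature rule, so this recovery checks the pipeline, not the
  quadrature; the quadrature itself is checked against the analytic
  sphere and two-sphere closed forms.
* **Compaction.**  The solenoid telescopes axially: the per-frame axial
  scale is solved so the realized Rg tracks an AR(1) around 22 Å then
  15 Å.  Axial (not isotropic) scaling keeps the radial floor explicit:
  targets below `Rg_xy` of the chain are rejected.
* **Ligand switch.**  A five-bead P–O–P–O–P ligand (residue TPP, chain L —
  a tripolyphosphate-sized, −5-charge-class mimic) is placed along the
  segment between the first and last bead of the tethered residue group,
  pushed radially outward by the tether distance (default 3.0 Å, inside
  the 4.5 Å cutoff), with rigid Gaussian jitter (SD 0.3 Å) per frame; at
  the switch frame the tether jumps from group A (default 250–251) to
  group B (default 298 and 307, one solenoid turn apart and hence
  spatially stacked — analogs of the lysine/glutamine pair implicated in
  polyphosphate binding).  The protein stays fixed, so gained contacts are
  exactly B and lost exactly A, and the default geometry keeps every
  non-tethered residue ≥ 1 Å clear of the cutoff (> 3σ of the jitter).

What the generators do **not** emulate: physical dynamics (no force
field, solvent, or thermostat), side chains and real excluded volume,
correlated protein–ligand motion, or the actual K18 ensemble.  Passing
recovery tests therefore demonstrates that the *analysis chain* is
correct and self-consistent at realistic signal sizes — not that the
biological numbers from any specific simulation are reproduced.  In
particular the published per-half area statistics for K18–polyphosphate
trajectories derive from an undeposited microsecond atomistic simulation
and a different (iso-electron-density) surface definition; here they
serve as generator targets, and SASA with a 1.4 Å probe is the standard
reproducible stand-in, with threshold, probe and point count exposed as
configuration so users can recalibrate to other surface definitions.

## Problem sizes and defaults

The canonical fixtures are 2000 frames (exposure; 0.5 ns/frame, i.e. a
1 µs trajectory sampled every 0.5 ns), 500 frames (compaction) and 400
frames (ligand switch) over 129–134 beads — sizes chosen so the realized
regime statistics are estimated to ~1 Å² while a full
generate–write–read–analyse cycle stays desk-scale (tens of seconds).
The acceptance script regenerates all three from scratch at the given
seed on every run.

## Known limitations

* DCD (and other binary trajectory formats) are not read; convert to
  multi-model PDB or XYZ first.
* Hydrogens, when present in the input, occlude and contribute area like
  any atom; there is no united-atom correction.
* The contact analysis reports frequency changes, not significance;
  autocorrelation-aware testing is out of scope.
* PDB fixed-width fields cap residue ids at 4 digits and serials at 5;
  inputs beyond that need XYZ.
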