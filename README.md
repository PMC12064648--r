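# taupatch

Trajectory analysis of fibril-interface patch exposure and residue–ligand
contact reorganization, for molecular-dynamics studies of aggregation-prone
proteins such as the tau microtubule-binding fragment K18 (residues 244–372,
0N4R numbering).

Tau aggregation cofactors such as short-chain polyphosphates are thought to
act by stabilizing conformations in which the fibril-interface residues —
for tau, the three consecutive glycines 333–335 (the *GGG patch*, central to
the 5O3L fibril interface) — stay solvent-exposed, while the cofactor
reorganizes its residue contacts between phases of the trajectory.
`taupatch` turns that mechanistic readout into a reproducible pipeline:

* **Structure/trajectory I/O** — fixed-width PDB (including multi-model
  `MODEL`/`ENDMDL` trajectories) and XYZ, with one-shot nm→Å conversion,
  altloc resolution and element inference.
* **Superposition RMSD** — Kabsch: the proper rotation `R` minimizing
  `Σᵢ wᵢ ‖R aᵢ + t − bᵢ‖²`, via SVD of the weighted covariance with
  determinant correction; per-frame minimum RMSD series.
* **Radius of gyration** — `Rg = √( Σᵢ wᵢ ‖rᵢ − r̄‖² / Σᵢ wᵢ )` per frame,
  with Gaussian-KDE (Silverman bandwidth) density summaries.
* **Patch solvent exposure** — Shrake–Rupley SASA on a deterministic
  golden-spiral quadrature (default 960 points, probe 1.40 Å); per-frame
  patch area `A(t) = Σ_{i∈patch} SASAᵢ(t)` computed in the context of the
  full structure; frames labelled *exposed* when `A(t) ≥ 100 Å²`; per-half
  mean, sample SD and fraction exposed.
* **Contact analysis** — a residue is in contact with the ligand in a frame
  when its minimum heavy-atom distance is ≤ 4.5 Å; per-half relative
  contact frequencies `fᵣ ∈ [0,1]`; residues with `f₂ − f₁ ≥ 0.25` are
  *gained*, `f₁ − f₂ ≥ 0.25` *lost*.
* **Synthetic trajectories with ground truth** — seeded coarse-grained
  generators for compaction, two-regime patch exposure and a mid-trajectory
  ligand-binding switch, so every stage is verifiable without an MD engine.

## Worked example

Generate a two-regime exposure trajectory (first half variable around
113 Å², second half stable around 121 Å², switching at the midpoint), write
it to a multi-model PDB, and analyse it back:

```r
library(taupatch)

res <- simulate_exposure_trajectory(generator_params(n_frames = 600, seed = 7))
write_trajectory(res$trajectory, "exposure.pdb")

traj <- read_trajectory("exposure.pdb")
es   <- exposure_series(traj, patch_definition(333:335), threshold = 100)
print(es)
#> exposure_series 'GGG': 600 frames, mean 120.2 A^2, 88.3% exposed (>= 100 A^2)
segment_stats(es)
#>       segment frame_start frame_end n_frames mean_area   sd_area fraction_exposed
#> 1  first_half           1       301      300  118.9115 27.755263        0.7933333
#> 2 second_half         301       601      300  121.5440  9.599111        0.9733333
```

The second half is both less variable (SD 9.6 vs 27.8 Å²) and more
consistently exposed (97 % vs 79 % of frames above the 100 Å² threshold) —
the signature of a stabilized aggregation-prone state.  The generator's
recorded ground truth for the per-half means is 118.9 / 121.5 Å², which the
pipeline recovers through the PDB round trip to < 0.1 Å².

The contact side of the mechanism, on a fixture whose ligand switches
tether groups at the midpoint:

```r
sw <- simulate_ligand_switch_trajectory(generator_params(n_frames = 200, seed = 7))
write_trajectory(sw$trajectory, "switch.pdb")
report <- run_analysis(list(trajectory = "switch.pdb",
                            ligand = "resname TPP"), "out")
print(report)
#> analysis_report (taupatch 0.1.0): 200 frames x 134 atoms
#>   blocks: rmsd, rg, exposure, contacts
#>   ...
#>   gained: G298, G307
#>   lost:   G250, G251
```

`run_analysis()` writes `rmsd.tsv`, `rg.tsv`, `exposure.tsv`, per-half
contact-frequency TSVs, `contacts_differential.json` and a `report.json`
whose config echo reproduces the run bit-for-bit.  The same pipeline runs
from a shell via the thin wrapper in `inst/cli/taupatch.R`
(`analyze --config FILE`, `simulate`, `fixtures`).

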