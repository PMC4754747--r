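# dimerdyn

Trajectory analysis of protein dimer-interface dynamics in R.

Many homodimeric enzymes — the creatine kinase isoforms are the motivating
case — lose activity when heat drives the two subunits apart. Direct
observation of dissociation is beyond routine molecular-dynamics timescales,
but its *tendency* can be read out of an equilibrium ensemble: the collective
motion that loosens the interface leaves signatures in the covariance of the
coordinates, in the solvent exposure of interface residues, and in the
residue-interaction network that couples distant sites to the interface.
`dimerdyn` implements that readout as a reusable, tested pipeline for people
who have a dimer structure, a coordinate ensemble, and (optionally)
per-residue binding-energy decompositions, and want quantitative,
reproducible answers.

## What it computes

- **Interface detection by SASA loss.** Shrake–Rupley solvent-accessible
  surface area with a deterministic golden-spiral point set; an interface
  residue is one whose per-residue SASA drops when the two rigid chains are
  associated, `ΔSASA_i = SASA_i(isolated) − SASA_i(complex) > τ`.
- **Essential dynamics.** PCA of the aligned Cα coordinates: the 3N×3N
  covariance `C = ⟨(x−⟨x⟩)(x−⟨x⟩)ᵀ⟩` is diagonalised into orthonormal modes
  with variances `λ₁ ≥ λ₂ ≥ …`.
- **Functional mode analysis (FMA).** Partial-least-squares regression of a
  scalar functional quantity — here the total interface SASA per frame,
  a proxy for the degree of dissociation — on the frame projections onto the
  leading PC modes. The functional mode is the collective motion maximally
  correlated with the function; the fit is trained on the first half of the
  frames and scored by the Pearson correlation on the held-out second half.
- **Per-residue mode anatomy.** Amplitudes (3-block norms of a unit mode,
  `Σᵢ aᵢ² = 1` over the dimer) and motion directions, with cosines between
  the directions of two systems' modes.
- **Dynamic residue-interaction networks.** An edge between two residues
  requires *both* correlated motion in a chosen mode (direction angle < 45°)
  *and* persistent contact (minimum heavy-atom distance < 4.5 Å in ≥ 75% of
  frames). Topology summaries (degree, clustering coefficient), shortest
  paths with geodesic counts, and a bootstrap over frame subsamples.
- **Energetics.** Windowed statistics and Welch comparison of per-frame
  binding-energy series, and key-residue selection by the per-residue
  difference `ΔΔG = ΔG(mutant) − ΔG(wild type)` past ±1 kcal/mol.
- **Conformational clustering.** GROMOS-style greedy clustering on the
  pairwise Cα RMSD matrix, with the cutoff chosen as the smallest value
  whose top 8 clusters cover > 90% of the snapshots.
- **Synthetic study system.** A seeded generator for a toy two-chain
  ensemble with planted orthonormal collective modes, a dissociation mode
  that rigidly separates the chains (and therefore modulates interface
  SASA), controllable residue-contact occupancies, and Gaussian noise — so
  every stage above is testable against known ground truth.

## Worked example

```r
library(dimerdyn)

spec  <- synthetic_spec(n_residues_per_chain = 8, n_frames = 500, seed = 42)
model <- build_toy_dimer(spec)
ens   <- generate_ensemble(model, spec)

iface <- detect_interface(model, n_points = 240)
head(iface, 3)
#>   chain_id residue_index delta_sasa
#> 1 A                    1       20.6
#> 2 A                    2       19.1
#> 3 A                    3       19.1

series  <- interface_sasa_series(ens$traj, iface, n_points = 240)
aligned <- align_ensemble(ens$traj)
modes   <- pca_modes(aligned)
glance(modes)
#>   n_modes n_atoms total_variance top_variance_fraction
#> 1      42      16           1.05                 0.902

fmode <- fma(aligned, modes, series)
glance(fmode)
#>   n_components train_pcc validation_pcc
#> 1           10     0.989          0.987
```

Every chain-A/B residue faces a partner 4 Å across the interface, so all of
them are detected as interface residues with ~20 Å² of buried area each. The
planted dissociation mode carries 90% of the ensemble variance, and the FMA
mode predicts the interface-SASA series on held-out frames with PCC 0.987.
The fit really is the planted motion:

```r
truth <- internal_component(
  field_on_atoms(model, ens$fields[[1]], modes$atom_indices),
  modes$mean_structure)
abs(sum(fmode$mode * truth))
#> [1] 1
```

Networks chain on directly:

```r
occ  <- contact_occupancy(ens$traj)       # heavy atoms, < 4.5 A
nets <- build_network(modes, 1, occ)      # angle < 45 deg AND occupancy >= 0.75
glance(summarize_network(nets[[1]]))
#>   chain_id n_nodes n_edges average_degree average_clustering
#> 1 A              8       7           1.75                  0
```

`run_pipeline(pipeline_config(out_dir = "run1"))` executes all stages on the
bundled synthetic system and writes CSV/JSON artifacts plus per-stage
manifests with parameter echoes and checksums; a rerun with the same seed is
byte-identical.

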