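---
title: "Quantifying dimer-dissociation tendency from coordinate ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dimer-dissociation tendency from coordinate ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerdyn)
```

## The problem and the model

Homodimeric enzymes such as the cytosolic creatine kinases are inactivated
when their subunits separate. The dissociation event itself is far slower
than the nanosecond-to-microsecond ensembles one can afford to simulate, so
this package quantifies the *tendency* to dissociate from equilibrium
fluctuations instead, through four linked readouts:

1. **Interface definition.** From the static structure, the interface is
   the set of residues whose solvent-accessible surface area (SASA) shrinks
   when the two rigid chains are associated rather than isolated. The
   interface is fixed once from the reference coordinates and never
   redefined per frame; the total SASA of those residues along the
   trajectory is the scalar "degree of dissociation".
2. **Collective motions.** PCA of the superposed Cα coordinates decomposes
   the ensemble into orthonormal modes. Functional mode analysis (FMA) then
   finds the linear combination of leading PC modes whose per-frame
   projection best predicts the interface-SASA series, by partial least
   squares (PLS1). A dimer with a strong, cross-validated functional mode
   has a well-defined dissociation motion.
3. **Mechanism.** Per-residue amplitudes and directions within a mode say
   *which* residues carry the motion; a dynamic residue-interaction network
   — edges requiring simultaneously correlated motion direction and
   persistent physical contact — says how a remote perturbation site is
   coupled to the interface, via shortest paths and their counts.
4. **Energetics and conformers.** Per-residue binding-energy decompositions
   (consumed as tables; the package never computes them) rank residues by
   ΔΔG between two systems, and pairwise-RMSD clustering with a
   coverage-based cutoff characterises what conformations the ensemble
   actually visited.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `probe` | 1.4 Å | water-probe radius for SASA |
| `n_points` | 960 | sphere points per atom (golden spiral, deterministic) |
| `tolerance` | 0.1 Å² | minimum per-residue SASA loss to call a residue interfacial |
| `distance` | 4.5 Å | heavy-atom contact threshold (strict `<`) |
| `occupancy_threshold` | 0.75 | minimum contact occupancy (inclusive `>=`) |
| `angle_threshold` | 45° | maximum angle between residue motion directions |
| `top_k` | 20 | PC-mode pool for FMA and mode projection |
| `n_components` | 10 | PLS latent components in FMA |
| `fraction`, `repeats` | 0.8, 10 | bootstrap subsample fraction and replicate count |
| `top_n`, `coverage` | 8, 0.90 | clustering cutoff rule: smallest cutoff whose top 8 clusters cover > 90% |

The contact criteria deliberately mix a strict and an inclusive comparison:
a contact exists *below* 4.5 Å, and persistence requires *at least* 75% of
frames. Residues whose mode amplitude falls below 1e-6 have no defined
direction and fail the motion criterion, so they can never be network nodes.

## Numerical choices

- **SASA** uses Shrake–Rupley with a deterministic golden-spiral point set,
  so results are exactly reproducible for a fixed `n_points`; fewer than 32
  points is refused. Hydrogens are excluded by default (heavy-atom SASA is
  the reproducible convention across force fields and crystal structures);
  radii come from a fixed element table (C 1.70, N 1.55, O 1.52, S 1.80,
  H 1.20, P 1.80 Å, 1.70 otherwise).
- **Superposition** is unweighted Kabsch over Cα atoms; a reflection is
  corrected by flipping the smallest singular vector. The default alignment
  reference is the iterative mean structure (align, recompute mean, repeat
  to 1e-6 Å); RMSF is measured about the ensemble mean.
- **PCA sign convention:** the largest-magnitude component of each mode is
  made positive, so outputs are identical across linear-algebra backends.
- **FMA cross-validation** is a contiguous half split (first half trains,
  second half validates) rather than a random split, because frames are
  temporally autocorrelated and a random split would leak information.
  The reported *functional mode* is the ensemble-weighted back-projection
  (per-PC variances times the PLS regression coefficients): it is the
  motion that actually moves the functional quantity. The raw regression
  direction divides by small variances and is dominated by noise PCs; both
  give identical fitted values and correlations.
- **Planted rigid modes and alignment.** A planted dissociation mode that
  rigidly translates one chain is partially absorbed by the superposition
  step. Recovered modes are therefore compared against the planted field's
  *internal component* (`internal_component()`): its projection onto the
  orthogonal complement of the six rigid-body motions of the reference
  structure. This is exact, not a tolerance trick.
- **Network tie-breaks:** mode projection ties resolve toward the lower PC
  index; GROMOS clustering seeds ties toward the lowest frame label, making
  both fully deterministic. Geodesic counts come from breadth-first search
  (via igraph), verified in the tests against exhaustive path enumeration.
- **Degenerate inputs** fail loudly: constant ensembles refuse PCA
  ("degenerate covariance"), constant function series refuse FMA, empty
  interfaces warn and return empty sets, single-frame RMSF warns and
  returns zeros.

## Design decisions where the design was open

- **Residue identity** is (chain, author residue number); insertion codes
  are rejected rather than silently reindexed.
- **Networks are per chain with intra-chain edges** by default (an
  inter-chain variant sits behind `scope = "all"`), and sequential
  neighbours are *not* excluded — an exclusion window is available but off,
  since backbone-adjacent contacts are genuine interactions.
- **Nodes are residues with at least one edge**; isolated residues drop
  out, which is why node counts can sit below the chain length.
- **Bootstrap resamples frames without replacement** (a fraction of the
  frames is "chosen", not redrawn), and the mode is deliberately *not*
  recomputed per replicate: the bootstrap probes the stability of the
  contact criterion, not of the PCA.
- **Welch's t-test** backs the two-system energy comparison; the choice is
  documented and swappable, and block averaging is available for
  autocorrelated series (`block` argument).
- **Clustering** uses the greedy neighbour-count (GROMOS-style) scheme, and
  the cutoff rule picks the *smallest* cutoff satisfying the coverage
  requirement, the conservative reading of "optimal".
- The command-line surface is `run_pipeline()` / `simulate_dataset()` plus
  the thin wrapper in `inst/cli/dimerdyn.R`; the R functions are the
  primary interface.

## What the synthetic generator emulates — and what it does not

`build_toy_dimer()` lays out two facing extended strands, 3.8 Å Cα spacing,
4.0 Å apart across the interface, one pseudo side-chain atom stack per
residue. `generate_ensemble()` adds, per frame: Gaussian-weighted planted
collective modes (Gram–Schmidt re-orthonormalized, near-degenerate fields
rejected), a dissociation coefficient `d ~ N(0, σ_d)` along a rigid chain-B
translation of the interface normal, i.i.d. coordinate noise, and
Bernoulli-scheduled contact jitter that places selected residue pairs below
(3.5 Å) or above (6.5 Å) the contact threshold at a target rate. A single
seeded RNG stream is consumed in a fixed, documented order (mode
coefficients, dissociation, noise, contact schedules), so adding frames or
targets never silently shifts earlier draws.

This gives exact ground truth for every downstream stage: the dissociation
coefficient correlates with measured interface SASA above 0.9 at the
default noise level, planted occupancies are recovered within ±0.05 at
2000 frames, and planted edge sets are recovered exactly under the default
thresholds. What the toy does *not* have: secondary structure, realistic
packing or chemistry, force-field energetics, anharmonic or multi-basin
dynamics, and temporal autocorrelation (frames are i.i.d. draws). Passing
tests therefore demonstrate correctness of the machinery, not that a real
protein's dissociation mode is linear or that FMA correlations on real MD
will be this strong — on real trajectories they are typically far weaker.

## Problem sizes

The test-suite and acceptance runs use 8–24 residues per chain, 1–2 atoms
per residue, 40–5000 frames, SASA at 240–960 sphere points, and 10⁶-point
sampling oracles; the bundled pipeline configuration runs 12 residues per
chain over 300 frames with 240-point SASA. These sizes give sampling errors
well inside the asserted tolerances (e.g. binomial error on an occupancy at
2000 frames is ~0.01) while keeping a full run in seconds to minutes on one
core; all of them scale up through the same public interfaces.

## Known limitations

- FMA is linear; strongly non-linear couplings between motion and function
  (mutual-information variants) are out of scope.
- Cross-system mode comparison requires a user-supplied residue
  correspondence; no sequence alignment is attempted.
- The pairwise-RMSD matrix is O(F²) Kabsch fits; subsample frames
  (`cluster_max_frames` in the pipeline) for long trajectories.
- mmCIF, altloc, and hydrogen placement are unsupported; binary trajectory
  formats enter only through a user-supplied `reader` adapter.
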