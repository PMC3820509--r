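# motordyn

Structural-ensemble and dynamics analysis of protein motor domains in R.

Kinesin motor domains convert ATP turnover into directed movement along
microtubules through conformational changes that couple the nucleotide
pocket, the microtubule-binding interface and the neck-linker. Mapping those
changes quantitatively requires the same small set of analyses whether the
input is a pile of crystal structures or a molecular-dynamics trajectory:
superpose everything on a structurally invariant core, diagonalize the
Cartesian covariance to find the dominant collective motions, measure which
residues move together, and reduce the trajectory to interpretable order
parameters and conformational segments. `motordyn` implements that pipeline
end to end for structural biologists and simulators, and ships
seed-deterministic synthetic-data generators so every stage can be exercised
and validated without downloading a single structure.

## What it computes

Given F superposed conformations of N equivalent Cα positions
(x ∈ ℝ^{3N} per frame):

- **Interconformer PCA.** The covariance
  C_ij = ⟨(x_i − ⟨x_i⟩)(x_j − ⟨x_j⟩)⟩ (population convention) is
  diagonalized; eigenvectors are collective displacement modes, eigenvalues
  their variances (Å²), reported as percent and cumulative percent of the
  total mean-square fluctuation. Structures and snapshots are projected into
  the leading-PC subspace ("conformer plots"), per-residue mode
  contributions localize each motion, and complete-linkage clustering of
  PC1–PC5 distances groups conformers.
- **Invariant core.** Iterated superposition excluding, each round, the
  positions with the largest interconformer scatter (measured as an
  ellipsoid of variance, (4π/3)·σ₁σ₂σ₃ per position) until all remaining
  volumes fall below a threshold; the surviving positions define the
  reference frame for all fits.
- **Dynamical cross-correlation.** C_ij = ⟨Δr_i·Δr_j⟩ /
  √(⟨|Δr_i|²⟩⟨|Δr_j|²⟩) over Cα displacement vectors.
- **Dynamical network.** Residues in persistent contact (closest heavy atoms
  within 4.5 Å in ≥ 75 % of frames) are joined by edges weighted
  w_ij = −log|C_ij|; Girvan–Newman edge-betweenness removal with modularity
  scored on |C| affinities yields communities; weighted betweenness,
  inter-community junctions, critical nodes and optimal/suboptimal paths
  identify allosteric routes.
- **Contact-event activity.** Side-chain contacts tracked with 6.5/7.5 Å
  hysteresis, median-filtered (14 ns half-width by default), transition
  counts smoothed into an activity curve whose peaks segment the trajectory
  into conformational epochs.
- **Order parameters.** Subdomain protrusion (COM distance and
  principal-axis angle between α4 and β3 selections), neck-linker docking
  calls from monitored Cβ–Cβ pairs, latch/salt-bridge interaction traces,
  and per-region secondary-structure content.

## Worked example

Recover a known 9:3:1 mode-variance structure from a synthetic conformer
ensemble, then detect correlated blocks in a trajectory:

```r
library(motordyn)

ens   <- gaussian_ensemble(n_frames = 2000, variances = c(9, 3, 1), seed = 1)
model <- ens_pca(ens)
model
#> <ens_pca> 70 positions, 2000 frames
#>   PC1:  69.9% (cum  69.9%)
#>   PC2:  22.9% (cum  92.8%)
#>   PC3:   7.2% (cum 100.0%)
```

The three generator modes carry 9/13 = 69.2 %, 3/13 = 23.1 % and
1/13 = 7.7 % of the variance; the recovered spectrum matches to sampling
error and nothing beyond rank 3 survives.

```r
bt  <- block_correlated_trajectory(n_frames = 2000, seed = 1)
net <- build_network(dccm(bt), contact_adjacency(bt))
detect_communities(net)
#> <community_partition> 3 communities (modularity 0.663)
```

The trajectory was generated with three residue blocks moving coherently
(intra-block correlation 0.8, inter-block 0); the contact-filtered network
recovers exactly that partition. Order parameters behave the same way on the
labeled toy motor domain:

```r
st <- toy_two_state()
protrusion(st$up,   "a4", "b3")$distance   # 16.0  (subdomain "up")
protrusion(st$down, "a4", "b3")$distance   # 12.7  (subdomain "down")
```

Every result type has `tidy()`/`glance()` accessors and an `autoplot()`
method (scree plot, conformer plot, DCCM map, activity curve). The two
end-to-end recipes are `run_conformer_analysis()` and
`run_trajectory_analysis()`; `inst/extdata/kinesin_recipe.yaml` holds the
motor-domain parameter set, and real structures enter through
`read_structure()`, `build_equivalences()`, `filter_structures()` and
`read_trajectory()` (multi-model PDB or DCD).

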