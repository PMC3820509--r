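---
title: "Methods: ensemble PCA, dynamical networks and contact-event analysis in motordyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble PCA, dynamical networks and contact-event analysis in motordyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motordyn)
```

`motordyn` analyses conformational ensembles of protein motor domains:
collections of crystal structures of homologous chains, and molecular
dynamics trajectories of a single chain. This vignette is the package's own
account of the models it implements, the conventions and tunables behind
them, what the synthetic-data generators do and do not emulate, and the
design choices made where the methods literature leaves the details open.

## Coordinate ensembles and residue equivalence

Everything operates on a `coord_ensemble`: F frames × N equivalent Cα
positions, flattened to an F × 3N matrix. For heterogeneous crystal chains
the equivalence comes from a multiple sequence alignment of the Cα-bearing
residues (`build_equivalences()`, delegated to the `mafft` executable with
an identity fast path); only alignment columns occupied in *every* chain
enter the analysis, because a covariance over positions missing in some
structures is undefined. Chains below 30 % identity to all others are
flagged for manual curation rather than silently aligned. A completeness
filter (`filter_structures()`) additionally drops chains lacking resolved
residues in user-named required regions — for motor domains, the
nucleotide-site elements (P-loop, switch loops) whose absence makes a chain
uninterpretable for this analysis. Author residue numbering is preserved for
reporting; all internal computation uses alignment-column indices, since
kinesin subfamilies number residues differently.

Trajectories enter through `read_trajectory()` (multi-model PDB always; DCD
through `bio3d::read.dcd`). Each residue also carries one representative
side-chain atom (Cβ, Cα for glycine) used by the contact-based operators.

## Superposition and the invariant core

Rigid-body fits use the SVD-based least-squares (Kabsch) solution with a
reflection guard. Because every comparison depends on the reference frame,
the package identifies a *structurally invariant core*
(`find_invariant_core()`): iterated rounds in which all frames are fitted on
the current candidate set, each position's interconformer scatter is
summarized as an ellipsoid volume — (4π/3)·σ₁σ₂σ₃ from the principal axes of
its 3 × 3 positional covariance, population convention — and the
largest-volume positions are excluded before the next round.

Two details are deliberate choices rather than forced by the method:

- **Exclusion schedule.** A fixed fraction (default 5 %) of the candidate
  set is dropped per round, but never a position already below the stop
  volume. This coarse-to-fine ladder converges in few rounds and cannot
  overshoot into compliant positions.
- **Stop criterion.** Iteration stops when every remaining volume is below
  `stop_volume` (default 0.5 Å³, i.e. sub-Ångström scatter on every axis),
  or at a requested core size. The appropriate threshold is
  ensemble-dependent; both knobs are exposed and the per-iteration history
  (candidate count, max volume) is returned so the trade-off is inspectable.

With only two conformers an invariant core is unconstrained; the conformer
pipeline then fits on all positions and records that explicitly.

## Principal component analysis

`ens_pca()` diagonalizes the 3N × 3N Cartesian covariance of the superposed
ensemble. Conventions:

- **Population covariance** (divide by F). Variance *fractions* — the
  quantities usually compared across studies — are convention-invariant;
  absolute eigenvalues are not, so the convention is stated once and tested
  (two frames differing by d in one coordinate give a single d²/4 entry).
- **Eigenvector sign** is fixed by making each vector's largest-magnitude
  component positive. Overlaps and conformer plots are sign-invariant, but
  projections must be deterministic across runs and platforms.
- Eigenvalues are clipped at zero below −10⁻⁸ relative; a static ensemble
  (zero total variance) reports zero fractions instead of NaN so degenerate
  trajectories flow through the pipeline.

Derived quantities: projections (`project_frames()`, whose training-score
population variance equals the eigenvalue — an internal consistency check),
per-residue mode contributions (squared norm of each position's three
eigenvector components; sums to one), complete-linkage clustering of
Euclidean distances in the first `n_pcs = 5` PCs with a user-chosen cut
`k` (default 3 — cluster number is a judgment call made on the dendrogram,
not automated), RMSF profiles, and the average cumulative squared inner
product between two models' leading subspaces (`subspace_overlap()`), the
standard measure of whether two ensembles explore the same essential space.
B-factor agreement is assessed on the linear B versus RMSF² scale, since
B = (8π²/3)⟨u²⟩.

## Dynamical cross-correlation and the network

`dccm()` computes C_ij = ⟨Δr_i·Δr_j⟩/√(⟨|Δr_i|²⟩⟨|Δr_j|²⟩) over Cα
displacement vectors. Zero-variance positions are marked NA with a warning
and excluded downstream rather than producing silent 0/0s.

`build_network()` draws an edge for every persistent contact — closest
heavy-atom distance within 4.5 Å in at least 75 % of frames, boundary
inclusive — and weights it w_ij = −log|C_ij|, the standard conversion of
correlation into a communication "distance". |C| is floored at 10⁻⁶
(w_max ≈ 13.8) and capped edges are flagged. Sequence neighbours (|i−j| ≤ 1
by default, optionally ≤ 2) are excluded from contact edges; otherwise
covalently forced backbone correlations dominate every path.

Community detection (`detect_communities()`) is Girvan–Newman with one
deliberate split of weight conventions: edge betweenness (the removal
criterion) treats w as a path length, while modularity (the selection
criterion over the partition sequence) uses |C| as edge affinity. Both
quantities then mean what they should — paths are short where correlation is
strong, and a good partition concentrates correlation inside communities.
Ties in edge betweenness are broken by lowest edge index, making the
partition reproducible. Betweenness, inter-community junction widths,
critical nodes (boundary nodes at or above a configurable betweenness
quantile, default the median — the "majority of shortest paths" reading) and
optimal/suboptimal paths (`network_paths()`, exact bounded depth-first
enumeration with distance-to-sink pruning) complete the module. The
betweenness quantile is exposed because no standard threshold exists for
"critical"; the default is the weakest defensible reading.

## Contact-event activity and segmentation

`hysteretic_contacts()` tracks each residue pair's representative-atom
distance with a dual cutoff: formed below 6.5 Å, broken above 7.5 Å, state
persisting inside the band. The phrase "between 6.5 and 7.5 Å" admits both a
hysteresis and a band reading; hysteresis is the default (it is what makes
event counting noise-robust) and the band reading is available via
`mode = "band"`. A series that *starts* inside the band starts "broken" —
some initial state must be declared, and requiring the on-cutoff to be
crossed before counting a formation is the conservative choice.

`event_activity()` median-filters each pair's state series (half-width in
frames; 14 ns = 700 frames at 20 ps sampling, both exposed in the config),
counts transitions of the *filtered* series per frame, and smooths the total
with a Gaussian kernel whose bandwidth defaults to half the filter
half-width (unstated in the method literature; half the half-width smooths
within-transition scatter without merging distinct transitions).
`segment_by_activity()` places boundaries at activity peaks above a
`prominence` parameter; segments are the inter-peak basins and tile the
trajectory. Prominence is a genuine tunable: borderline contacts whose
distances hover near a cutoff produce late, isolated filtered transitions
(an inherent property of hysteresis, visible in the tests), so the default
recipe uses half the maximum activity, and an absolute prominence of a few
near-simultaneous transitions is the right choice when transition magnitudes
differ strongly.

## Geometric order parameters

- **Protrusion** (`protrusion()`): distance between the Cα centers of mass
  of two selections, and the angle between their dominant principal axes
  folded to [0°, 90°]. "The angle between two subdomains" does not define
  itself; the principal-axis convention is declared here, is rigid-motion
  invariant, and reduces to the intuitive axis angle for helices and
  strands. Region selections default to labeled `regions` of the ensemble
  and are always configurable.
- **Docking** (`docking_state()`): a frame is docked iff *every* monitored
  pair distance (Cβ–Cβ by default) is below the cutoff (default 8 Å,
  configurable); calls are therefore monotone in the cutoff and the first
  undocking frame is reported.
- **Interaction traces** (`interaction_trace()`): per-frame minimum
  representative-atom distances between residue groups with formed fractions
  at a 4.5 Å default.
- **Secondary structure** (`secondary_structure_trace()`): the built-in
  assigner works from Cα geometry alone, using the characteristic
  Cα(i,i+2)/(i,i+3)/(i,i+4) distances of helices and strands — chosen
  because the package's ensembles (and its synthetic toys) are Cα-based, so
  a φ/ψ assigner would be inapplicable to most inputs. Any external
  assigner can be plugged in as a function over an N × 3 frame, which is the
  intended route when full-backbone structures and an assignment binary are
  at hand.

## Synthetic data: what it emulates, and what it does not

Three generators produce data with exactly the statistical structure each
analysis stage assumes, with ground truth attached
machine-readably (`ground_truth()`, `write_ground_truth()`):

- `gaussian_ensemble()`: frames = mean + Σ z_k·mode_k + isotropic noise,
  z_k ~ N(0, var_k), modes orthonormalized. True covariance known; defaults
  (variances 9:3:1, F = 2000) give a spectrum dominated by a few collective
  modes, the regime interconformer PCA is designed for.
- `switching_trajectory()`: piecewise-constant state sequence between toy
  conformations plus isotropic noise (default σ = 0.3 Å, small against the
  3–4 Å state displacements, as in a stable fold); transition frames exact.
- `block_correlated_trajectory()`: residues on a compact lattice (3 Å
  spacing, one slab per block, slabs touching) displaced by a shared
  per-block latent 3-vector plus independent noise, calibrated so the
  expected pairwise correlation equals the intra-block target
  (ρ = τ²/(τ²+σ²)); a latent fraction `inter/intra` is shared across blocks.
  The lattice spacing is chosen so blocks are densely intraconnected at the
  4.5 Å contact cutoff — at sparser packings, modularity legitimately
  prefers to split a block, which is a property of modularity, not of the
  detector.

The toy motor domain (`toy_structure()`, 70 residues) uses ideal helix,
strand and arc geometry with labeled regions named after the motor-domain
elements (`b1`, `b3`, `loop8`, `a4`, `loop13`, `a6`, `neck_linker`), so
recipes written for real structures run unchanged; `toy_two_state()` places
the α4 subdomain so the up/down protrusion distances sit at 16 Å and
~13 Å, the scale on which this order parameter separates motor
conformations.

What the generators do *not* emulate: physical energetics, anisotropic or
sequence-dependent fluctuations, realistic side-chain packing (one pseudo-Cβ
per residue), solvent, or the fat-tailed kinetics of real transitions.
Passing tests therefore demonstrate that the estimators recover known
statistical structure at realistic sizes and noise — not that any biological
conclusion about a specific protein follows.

## Numerical choices and problem sizes

- Superposition tolerance: refitting a fitted ensemble moves no coordinate
  by more than 10⁻⁶ Å (tested).
- PCA symmetry tolerance 10⁻⁸; eigenvalue clipping at −10⁻⁸ relative.
- Degenerate inputs: static ensembles give zero RMSF/fractions; frozen
  positions give NA DCCM rows; empty networks give singleton communities;
  flat activity gives one whole-trajectory segment; disconnected path
  queries return an explicit no-path result.
- Determinism: generators are seed-deterministic; eigenvector signs, tree
  cuts, and Girvan–Newman tie-breaks are fixed; repeated pipeline runs with
  one config and seed produce byte-identical summary JSON (tested).
- The test-suite and acceptance problem sizes — F = 2000 for spectrum
  recovery, F = 5000 × N = 60 for correlation-block recovery, 1000-frame
  switching trajectories with a 40-frame filter half-width, ≤ 12-node graphs
  for exhaustive network oracles — are chosen so sampling error sits well
  inside the tested tolerances while each stage's cost stays in seconds.

## Known limitations

- The MSA step shells out to `mafft`; without it only identical-sequence
  ensembles can be equivalenced.
- Contact operators use one representative side-chain atom per residue, not
  all heavy atoms; with full atom records the minimum heavy-atom distance is
  approximated by the Cα/Cβ minimum.
- Suboptimal-path enumeration is exact and therefore exponential in the
  worst case; it is intended for tolerance windows and graph sizes where the
  admissible path set is modest.
- Girvan–Newman recomputes edge betweenness after every removal (O(E²V) per
  component), appropriate for residue-level networks (hundreds of nodes),
  not for arbitrary large graphs.
- The Cα secondary-structure heuristic classifies ideal geometry perfectly
  but is a coarse instrument on distorted conformations; plug in a
  full-backbone assigner for publication-grade content traces.
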