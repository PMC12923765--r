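---
title: "Methods behind pi3kdyn: latches, landscapes, paths, membranes and doublets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind pi3kdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pi3kdyn)
```

`pi3kdyn` packages the analysis layer of a molecular-dynamics study of
PI3Kα variants: everything that happens *after* the trajectories exist.
This vignette explains the models and conventions each stage uses, the
parameters that matter, what the synthetic generators do and do not
emulate, and the numerical choices made where the design was genuinely
open.

## Trajectory model and residue selection

A trajectory is a frame-invariant topology (atom name, residue name, chain,
author residue number, element) plus an ordered list of `n_atoms x 3`
coordinate matrices in Angstroms, with optional frame times (ns) and an
orthorhombic box. Author residue numbering is authoritative and never
rewritten: the community refers to these positions by name (K379, E545,
H1047) and renumbering would silently break every downstream selection.
Multi-model PDB files are read through `bio3d`; atom counts per MODEL are
validated up front so a mismatch names the offending model. Alternate
locations other than blank/'A' are dropped with a warning count, and a
missing element column is inferred from the atom name.

Selections map a (chain, residue) pair to atoms through a small rule set.
The `sidechain-charge-group` rule resolves to the atoms that actually carry
the charge (Lys NZ; Arg NH1/NH2/NE; Asp OD1/OD2; Glu OE1/OE2; His ND1/NE2),
which is what a salt-bridge distance should measure; `centroid` produces a
virtual site at the unweighted heavy-atom mean. Resolution is deterministic
(topology order) and failures are loud, listing the atoms that were
available.

## Interface latches

A latch is a named residue-pair reaction coordinate with a formation
cutoff. The per-frame value is the *minimum* pairwise distance between the
two resolved atom sets: for charged pairs this is the conventional
salt-bridge distance, robust to which oxygen/nitrogen happens to point
inward. Backbone-type pairs (e.g. F934–K942) default to Cα atoms. The
default formation cutoff is 4.0 Å — a standard salt-bridge criterion; no
numeric definition is inherited from upstream, so it is explicit and
configurable. No periodic imaging is applied to protein-internal distances.

Statistics are computed after excluding an initial transient, by default
the first 20% of frames — mirroring the convention of discarding the first
200 ns of a 1 µs production run. `occupancy_summary()` reports mean, SD,
5/50/95 percentiles, the formed fraction at the cutoff, and the frame-1
(starting structure) value, which is the "initial value" line one draws on
a violin plot.

Buried interface area between two residue groups is
(SASA(A) + SASA(B) − SASA(A∪B))/2 with SASA from a Shrake–Rupley
quadrature: probe 1.4 Å, 960 Fibonacci sphere points per atom, Bondi radii.
The quadrature count keeps single-atom relative errors well under 1%
(an isolated carbon's area is reproduced to ~0.002%), and the two-sphere
overlap case agrees with the closed-form spherical-cap area to well within
3%.

## Free-energy landscapes

`compute_pmf2d()` histograms two aligned distance series on a regular grid
(default bin width 0.5 Å on both axes — fine enough to resolve Å-scale well
structure, coarse enough that typical wells collect thousands of samples)
and Boltzmann-inverts: ΔG(i,j) = −kT ln(count/n), shifted so the occupied
minimum is exactly 0. kT is computed from k_B = 0.0019872041 kcal/(mol·K);
at the default 310 K this is 0.61603 kcal/mol. Unoccupied bins are
undefined (`NA`), not capped at an arbitrary ceiling, and export as empty
fields; capping would fabricate a plateau that plots faithfully reproduce.
The surface over (D1, D2) is the "three-dimensional" PMF one draws; no
third reaction coordinate exists. Marginals re-normalize over the
remaining axis and re-shift. Because the transform is a pure function of
bin probabilities, ΔG is invariant to frame order and to scaling all
counts, and exp(−ΔG/kT) renormalized over occupied bins recovers the
empirical probabilities to machine precision — both are tested.

## Superposition, RMSF, clustering

Superposition is the Kabsch least-squares fit with reflection correction
(determinant forced to +1); collinear fit sets are rejected. The test suite
checks the resulting RMSD against an independent quaternion (Horn)
eigenvalue oracle to 1e-8 Å. `rmsd_series()` separates the fit set from
the measure set, enabling "superpose on p110α, measure p85α". RMSF uses
the standard iterative scheme — superpose all frames on the running mean
until the mean moves less than 1e-6 Å (at most 20 iterations, warning on
non-convergence) — or, with `fit_indices = NULL`, treats the input as
pre-aligned. Under isotropic per-coordinate jitter of SD σ the expected
RMSF is σ√3, which the suite verifies to 5% at 10,000 frames.

Clustering computes the all-pairs optimally-superposed RMSD matrix,
applies average-linkage agglomeration, and cuts at an RMSD height
(default 2.0 Å, a conventional backbone-scale threshold). The
representative conformation is the *medoid* of the most populated cluster
(minimum summed RMSD to cluster members, ties to the lowest frame index),
so the representative is always an actual frame. The O(n²) matrix bounds
the clustered frames at 500 by striding, with the stride recorded.

## Correlation networks and suboptimal paths

Dynamic cross-correlation uses one node per residue (Cα by default) on
pre-superposed frames: C_ij is the frame-averaged dot product of the
displacement 3-vectors, normalized by the per-node displacement variances.
Zero-variance nodes are excluded with a warning rather than propagating
NaNs. The allosteric graph keeps an edge only when the two residues are in
contact in the frame-averaged structure (minimum heavy-atom distance
≤ 4.5 Å, a common heavy-atom contact cutoff) and |C_ij| ≥ 1e-6 (avoiding
unbounded weights); the edge weight is −ln|C_ij|, so perfectly correlated
contacts are free to traverse and uncorrelated ones are expensive.

`shortest_path()` is Dijkstra with a deterministic lexicographic tie-break
(igraph supplies the distance computations; the tie-broken reconstruction
is done here). An unreachable sink is a first-class "no path" result — the
model of a broken allosteric signal — not an error.
`suboptimal_paths()` enumerates *every* simple path within `delta`
(default 1.0 weight units) of the optimum, up to `max_paths` (default 50),
by best-first search whose admissible bound is the accumulated weight plus
the exact Dijkstra distance to the sink; completed paths therefore pop in
weight order and truncation keeps the best ones. The suite proves set
equality against exhaustive brute-force enumeration on random graphs of up
to 8 nodes. Node degeneracy (how many returned paths traverse each node)
identifies the signalling bottlenecks. Simple paths only; variants that
revisit nodes are deliberately out of scope.

## Membrane metrics

The bilayer normal is fixed to z (both the study bilayer and the synthetic
one are planar; no director fitting). Per frame, the midplane is the mean
phosphate z; leaflets are assigned by side; each leaflet's reference
phosphate plane averages *PC and PS phosphates only* — PIP2 is excluded
because its protrusion is precisely the quantity measured against that
plane. The holo leaflet is the one nearer the protein's mean z position.

Anchor depth is the signed deviation of a residue's most membrane-ward
sidechain heavy atom from the holo plane, sign-corrected so positive always
points toward water. The shipped anchor-point defaults are the three
catalytic-subunit anchors: C2 loops (R349/R412/K413), the kα1-kα2 loop
(K723/K724/D725) and the kα12 WIF motif (W1057/I1058/F1059). PIP2
protrusion is the elevation of each holo-leaflet PIP2 phosphate above that
same plane, pooled over post-transient frames.

The RDF normalizes minimum-image pair distances by shell volume 4πr²Δr and
ideal-gas pair density N_aN_b/V (defaults: 0.1 Å bins to 12 Å), and an
ideal gas reproduces g(r) = 1 within 5% in the tested regime. The
PIP2–ATP coordination distance is measured between the 3-position inositol
hydroxyl oxygen and the ATP γ-phosphate, per PIP2 and as the per-frame
minimum.

## Pocket screening

Candidate pockets arrive from an external druggability predictor as
records (id, probability, lining residues, volume). The screen retains a
pocket iff probability *strictly* exceeds 0.5, it has at least 14 lining
residues, and a single domain contributes at least half of the lining.
"Spanning the gaps between domains" has no formula upstream, so it is
operationalized as no-dominant-domain (< 50% share), with the share
threshold configurable; an optional exclusion list drops pockets whose
dominant domain is a known internal cavity (ABD, C2, nSH2). Every removal
carries explicit reasons, and unmappable linings are flagged rather than
silently dropped. The filter is monotone under threshold tightening —
a property the suite checks.

## Double-mutation statistics

Prefiltering removes records below a VAF floor (default 0.05; the upstream
convention states a VAF prefilter without a value, so it is explicit and
configurable) and, per gene, excludes samples carrying a nonsense mutation
in that gene from doublet counting — a truncating co-mutation voids a
same-allele activation hypothesis. For every position pair co-mutated in at
least one sample, the 2×2 table over *gene-mutant* samples (the
denominator for all frequencies and tiers) is tested with a two-sided
Fisher exact test; odds ratios use the Haldane–Anscombe +0.5 correction
when any cell is zero; Benjamini–Hochberg q-values control FDR across the
tested pairs (the upstream procedure is unnamed, so the standard choice is
declared). Calls: co-occurring (q < α, OR > 1), mutually exclusive
(q < α, OR < 1), else null. Driver tiers: validated positions are strong
drivers at ≥ 10% of gene-mutant tumors and weak drivers below; unvalidated
positions are strong latent drivers at ≥ 1% and weak latent drivers below,
with boundary behaviour exactly at the ≥ thresholds.

## What the synthetic generators emulate — and what they do not

The generators produce data with the *statistical structure* each stage
assumes, not physical simulations: no force field, energetics, water or
ions anywhere.

- **Latch**: a continuous-time two-state Markov (telegraph) process —
  exponential waiting times between switches, Gaussian wells (defaults:
  bound 3.5 Å, released 12 Å, SD 0.5 Å, matching a formed salt bridge
  versus a released interface) — sampled at the frame times and clipped
  positive. The truth record carries the per-frame state, so occupancy
  recovery is checked against the *realized* state sequence. Real latch
  distances are autocorrelated within wells and have asymmetric well
  shapes; passing tests show correct estimation, not realism of the wells.
- **Correlated motion**: per-frame scalar node displacements from a
  multivariate normal built via the symmetric matrix square root of the
  target correlation, with the same scalar added to all three coordinates
  of a node. This isotropic scalar model is sufficient to validate the
  correlation estimator and the path machinery; it does not emulate
  anisotropic or rotational protein motion, and test fixtures use AR(1)
  chain structure (ρ^|i−j|), the canonical positive-definite decaying
  model.
- **Bilayer**: 3-bead pseudo-lipids (phosphate head + two tail beads) on a
  per-leaflet lattice, species split by largest-remainder apportionment so
  700 lipids at 28:6:1 give exactly 560/120/20. Anchor beads and PIP2
  phosphates are planted at known offsets from the leaflet plane, with
  per-frame Gaussian z-jitter (SD 0.7 Å) over `n_frames` (default 100) —
  two fields the generator adds because multi-frame recovery tests need
  them. No lateral diffusion, undulations or leaflet asymmetry are
  modelled.
- **Mutation catalog**: per-sample Bernoulli draws at configured marginal
  frequencies; planted pairs are drawn from a 2×2 joint distribution with
  the marginals preserved and the joint probability moved toward
  min(p_A, p_B) (co-occurrence) or 0 (exclusivity) by a strength in [0,1].
  VAFs are normal truncated to (0,1] — no upstream VAF distribution exists,
  so the floor is simply exercised explicitly. Recovery fixtures use
  strength 0.8 at n = 1500, chosen by a power calculation (implied OR ≈ 8,
  z ≈ 8) so that a correct pipeline recovers the plant essentially always
  and a failure indicates a defect rather than sampling noise.
- **Pockets**: the first six records are constructed on both sides of each
  screening boundary (probability exactly 0.5 versus above; 13 versus 14
  residues; single-domain versus 50/50 interdomain lining), guaranteeing
  boundary coverage for any n ≥ 6.

All generators are bit-reproducible under a fixed seed.

## Numerical choices and degenerate inputs

- Ties: path enumeration orders by weight then lexicographic node
  sequence; cluster representatives break ties toward the lowest frame
  index; largest-cluster ties go to the cluster containing the earliest
  frame.
- Degenerate geometry: superposition requires ≥ 3 non-collinear fit atoms;
  planar (rank-2) sets are fine. A single-frame trajectory clusters to one
  singleton. Zero-variance correlation nodes are excluded, not NaN'd.
- The occupancy-versus-truth checks use a cutoff at the midpoint of the
  two well means: at well SD 0.5 Å the misclassification probability is
  ~10⁻¹⁷, so the formed fraction measures state occupancy rather than the
  within-well tail mass that the 4.0 Å salt-bridge cutoff deliberately
  clips.
- Stationarity checks of the telegraph generator sample at dt = 10 ns for
  rates of 0.01/ns, chosen from the occupancy-variance formula
  2p(1−p)τ_c/T so the ±0.02 band sits at ~3σ.
- Problem sizes used by the suite and the acceptance script (200,000 PMF
  samples, 10,000-frame RMSF, 50,000-frame occupancy, 300-frame membranes,
  100 random graphs / Fisher tables / catalog replicates) are the package's
  reference scales: large enough that every statistical tolerance sits at
  ≥ 3σ by design, small enough to run on a laptop in minutes.

## Known limitations

- The PMF is unbiased Boltzmann inversion only; no umbrella-sampling/WHAM
  reweighting, so barriers above the sampling range are invisible.
- Pairwise-RMSD clustering is not intended to reproduce any specific
  desktop tool's output; only the contract documented here is guaranteed.
- The membrane module assumes a planar bilayer with its normal along z.
- Binary trajectory formats (DCD/XTC) and mmCIF are not supported; the
  interchange format is multi-model PDB.
- Whether replicas are pooled before histogramming a PMF is the caller's
  choice: `compute_pmf2d` accepts any aligned pair of series, and the
  pipeline manifest records which inputs were used.
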