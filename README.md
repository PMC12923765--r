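# pi3kdyn

Trajectory analytics for PI3Kα variant dynamics.

PI3Kα is a lipid kinase whose catalytic subunit (p110α) is held autoinhibited
by the nSH2/iSH2 domains of its regulatory subunit (p85α). Oncogenic
mutations such as E545K and H1047R act by breaking inter-domain salt-bridge
"latches", releasing nSH2, rewiring allosteric communication, and changing
how the enzyme engages the membrane and its PIP2 substrate. `pi3kdyn`
implements the downstream analysis machinery such a study needs, as a
tested, reusable R package:

- **Trajectory I/O** — multi-model PDB frames into a shared trajectory data
  model (via `bio3d`), domain annotations (ABD 16–105, RBD 187–289,
  C2 330–487, helical 517–694, kinase 695–1068 on p110α), and a residue
  selection language (`all-heavy`, `backbone`, `sidechain-charge-group`,
  `single-atom:<NAME>`, `centroid`).
- **Latch analysis** — per-frame residue-pair distances with
  minimum-distance aggregation over charged-group atoms, transient
  exclusion, occupancy summaries, and buried interface area by
  Shrake–Rupley quadrature.
- **Free-energy landscapes** — 2D potentials of mean force over two
  distance reaction coordinates (e.g. D1 = K379–E/K545, D2 = F934–K942) by
  Boltzmann inversion, ΔG(i,j) = −kT ln P(i,j), plus 1D marginals.
- **Ensemble statistics** — Kabsch superposition, RMSD series with separate
  fit/measure sets, iterative-mean RMSF profiles, and average-linkage
  RMSD clustering with a medoid representative conformation.
- **Allosteric paths** — dynamic cross-correlation matrices
  C_ij = ⟨Δr_i·Δr_j⟩ / √(⟨|Δr_i|²⟩⟨|Δr_j|²⟩), contact-filtered graphs with
  edge weights −ln|C_ij|, and exhaustive bounded-suboptimal simple-path
  enumeration (WISP-style) between a source and a sink residue.
- **Membrane metrics** — leaflet assignment, anchor-residue depth relative
  to the PC/PS phosphate plane, PIP2 head-group protrusion, radial
  distribution functions, and PIP2–ATP coordination distances.
- **Cryptic-pocket screening** — druggability probability > 0.5, at least
  14 lining residues, non-interdomain lining.
- **Double-mutation statistics** — VAF/nonsense prefilters, Fisher exact
  tests with Haldane–Anscombe odds ratios and BH correction over same-gene
  position pairs, and driver tiers (validated + ≥10% → strong driver;
  unvalidated + ≥1% → strong latent driver).
- **Synthetic generators** — telegraph-process latches, trajectories with
  planted correlation structure, a planar DOPC/DOPS/PIP2 pseudo-bilayer
  (700 lipids at 28:6:1 → 560/120/20 by construction), mutation catalogs
  with planted co-occurring/exclusive doublets, and pocket records that
  straddle every screening boundary — so the entire pipeline is testable
  without any external download.

## Worked example

Simulate a two-state latch (bound well 3.5 Å, released well 12 Å, switching
at 0.005/0.01 per ns), drop the first 20% as equilibration, and summarise:

```r
library(pi3kdyn)
sim <- gen_latch_trajectory(latch_sim_config(n_frames = 10000, dt = 1,
        switch_rate_on = 0.005, switch_rate_off = 0.01, seed = 42))
latch <- latch_definition("K379(nSH2)-E545(HD)",
  residue_selector("A", 1, "single-atom:CA"),
  residue_selector("A", 2, "single-atom:CA"), contact_cutoff = 4.0)
s <- exclude_transient(distance_series(sim$trajectory, latch), fraction = 0.2)
occupancy_summary(s)
#>                 latch mean   sd median  q05  q95 formed_fraction initial_value n_frames
#> 1 K379(nSH2)-E545(HD) 9.17 4.03   11.6 2.99 12.7           0.279          3.81     8000
```

The latch is formed (≤ 4 Å) in 27.9% of the analysed frames — close to the
stationary occupancy 0.005/(0.005+0.01) = 1/3 of the planted switching
process — and the bimodal q05/q95 spread reflects the two wells. Boltzmann
inversion of the same series gives the free-energy surface:

```r
g <- compute_pmf2d(s, s, bin_width = 0.5, temperature = 310)
#> kT = 0.61603 kcal/mol; occupied bins: 16; max dG = 3.96 kcal/mol
```

A YAML-driven multi-stage run (simulation, latches, PMF, RMSF, allosteric
paths, membrane metrics, pockets, doublets) is available through
`run_pipeline()`; see `inst/scripts/run_pipeline.R` for the command-line
wrapper and `vignettes/pi3kdyn-methods.Rmd` for the methods account.

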