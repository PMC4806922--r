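# rcugdyn

Elastic-network and ensemble dynamics of CUG trinucleotide-repeat RNA
duplexes, in R.

Expanded (CUG)n repeats fold into near-A-form duplexes whose every third
base pair is a non-canonical U-U 1×1 internal loop. `rcugdyn` provides the
machinery to study the collective dynamics of such duplexes at coarse-grained
resolution:

* **Structures and ensembles** — PDB input/output (multi-model, altloc- and
  solvent-aware), coarse-grained node selection (`CG1` = P/C2'/C4',
  `CG2` = P/C2'/C4/N3, or all heavy atoms), in-phase (CUG)n duplex fragment
  extraction, and iterative Kabsch superposition into aligned ensembles.
* **Anisotropic network model (ANM)** — Hessian assembly with uniform or
  exponentially distance-weighted springs, rigid-body-verified mode solving,
  and the pseudo-inverse covariance.
* **Ensemble statistics** — PCA of aligned ensembles, essential dynamics of
  evenly subsampled trajectories, per-node RMSF profiles, and conformer
  projections onto principal components.
* **Mode comparison** — overlap, cumulative overlap, essential subspace
  overlap, collectivity, fluctuation correlations, and cutoff/scheme scans.
* **Conformer generation** — ensembles sampled along the softest ANM modes
  with equipartition (1/λ) amplitudes.
* **U-U pair geometry** — hydrogen-bond detection, C1'-C1' distance, groove
  inclination, type I–VI classification, targeted perturbation into any
  type, and average-linkage clustering of pair conformations over
  trajectories.
* **Synthetic data** — an idealized A-form (CUG)n duplex builder and
  Gaussian generative models with prescribed variance spectra, for oracle
  tests and benchmarks.

## Worked example

Build an idealized GC-capped (CUG)3 duplex, solve its CG2 elastic network,
sample conformers along the three softest modes, and check that PCA of the
sample recovers the generating modes:

```r
library(rcugdyn)

duplex <- build_cug_duplex(3, cap = "GC")
duplex
#> rna_structure: 22 residues in 2 chain(s) [A,B], 286 atoms, model 1

nodes <- select_nodes(duplex, cg_scheme("CG2"))
nodes
#> node_set: 86 nodes, scheme CG2

modes <- solve_modes(build_hessian(nodes, force_constant("exponential",
                                                         cutoff = 9)))
modes
#> mode_set (ANM): 252 modes over 86 nodes (6 dropped)
signif(modes$values[1:3], 3)
#> [1] 0.143 0.252 0.375
collectivity(modes$vectors[, 1])
#> [1] 0.714                      # the softest mode is highly collective

conf <- sample_conformers(nodes, modes, n = 2000, target_rmsd = 2, seed = 1)
pc <- pca_modes(conf)
round(pc$spectrum$fraction[1:3], 3)
#> [1] 0.525 0.298 0.177
mode_overlap(pc$modes$vectors[, 1], modes$vectors[, 1])
#> [1] 0.998
subspace_overlap(pc$modes, modes, K = 3)
#> [1] 1

scan_parameters(pc, duplex, cutoffs = 5:15)
#> scan_result: 11 cells; best CG2 / 9 A / exponential (|overlap| = 0.998 at mode 1)
```

Classify and manipulate a U-U pair on the two-repeat capped duplex:

```r
s <- build_cug_duplex(2, cap = "GC")
pair <- find_uu_pairs(s)[[1]]
classify_uu(perturb_uu(s, "IV"), pair)
#> U-U type IV: 1 H-bond(s), major inclination (+1.50 A), C1'-C1' 10.17 A
```

## Command-line pipeline

Every stage is also reachable through a deterministic CLI with TSV/PDB
artifacts and a JSON manifest (inputs, parameters, MD5 checksums) per run:

```sh
TOOLS=$(Rscript -e 'cat(system.file("scripts", "rcug-tools.R", package = "rcugdyn"))')
Rscript $TOOLS synth --kind duplex --repeats 3 --out-dir run
Rscript $TOOLS anm --input run/duplex.pdb --cutoff 9 --out-dir run
Rscript $TOOLS classify-uu --input run/duplex.pdb --out-dir run
```

Subcommands: `synth`, `build-ensemble`, `pca`, `eda`, `anm`, `compare`,
`scan`, `conformers`, `projections`, `classify-uu`, `cluster-uu`. See
`?rcug_cli` for flags and defaults.

## Verification

`tests/testthat/` contains property and oracle tests for every module
(central-difference Hessian oracle, brute-force metric summations,
parameter-recovery on Gaussian synthetic data, U-U perturbation round
trips). `scripts/acceptance.R --seed <int> --out <path>` recomputes the
headline quantities against the installed package and writes them as JSON.

A methods vignette (`vignettes/rcugdyn-methods.Rmd`) documents the model
definitions, conventions, and estimators.
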