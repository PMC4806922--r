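---
title: "Methods: elastic networks and ensemble dynamics of CUG-repeat duplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elastic networks and ensemble dynamics of CUG-repeat duplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(rcugdyn)
```

This vignette states the mathematical conventions `rcugdyn` implements and
walks through them on synthetic structures, so every number shown here is
reproducible offline.

## 1. Structures, coarse-graining, ensembles

An `rna_structure` is an ordered atom table (chain, residue, atom name,
coordinates) restricted to the four RNA bases; modified-residue aliases can
be normalized at read time (`read_rna_pdb(path, aliases = c("5MC" = "C"))`).
Coarse-grained `node_set`s keep a fixed atom subset per residue:

* `CG1`: P, C2', C4' (3 nodes per residue),
* `CG2`: P, C2', C4, N3 (4 nodes per residue; the base-facing N3/C4 make
  this the preferred scheme for pairing-sensitive motions),
* `ALL`: all heavy atoms.

5'-terminal residues lack a phosphate, so an n-residue strand contributes
one node fewer than the nominal count per scheme.

```{r}
duplex <- build_cug_duplex(3, cap = "GC")   # GCUGCUGCUGC duplex
nodes <- select_nodes(duplex, cg_scheme("CG2"))
nodes
```

An `rna_ensemble` stores m aligned conformers as an m x 3N matrix plus the
node labels. `align_ensemble()` iterates Kabsch superposition against a
converging mean (tolerance 1e-6 A RMSD) so that the mean structure is a
fixed point of superposition; PCA refuses unaligned ensembles.

## 2. The anisotropic network model

Nodes within a cutoff `r_c` are joined by harmonic springs:

$$V = \frac{1}{2}\sum_{ij,\; s^0_{ij} < r_c} \gamma(s^0_{ij})
      \left(s_{ij} - s^0_{ij}\right)^2,$$

with either a uniform force constant or the exponential distance weighting
$\gamma(r) = \gamma_0 \exp\left(-(r - r_\mathrm{contact})/\ell\right)$
(defaults $\gamma_0 = 12$ at 3 A contact, decay length $\ell = 4.6$ A, so
the weight falls to about 0.1 by 25 A; hard cutoff 9 A by default). The
3N x 3N Hessian has off-diagonal super-elements
$-(\gamma_{ij}/s^{0\,2}_{ij})\, \mathbf{d}_{ij}\mathbf{d}_{ij}^T$ and
diagonal blocks equal to minus the row sums. `solve_modes()` verifies that
exactly six near-zero eigenvalues span the analytic rigid-body subspace
before dropping them; the retained 3N - 6 modes come back in ascending
stiffness.

```{r}
modes <- solve_modes(build_hessian(nodes,
                                   force_constant("exponential", cutoff = 9)))
modes
signif(modes$values[1:5], 3)
```

The model covariance is the Hessian pseudo-inverse over retained modes,
$C_\mathrm{ANM} = \sum_i \lambda_i^{-1} \mathbf{u}_i \mathbf{u}_i^T$, and
satisfies $H\,C_\mathrm{ANM} = I - P_\mathrm{rigid}$:

```{r}
C <- anm_covariance(modes)
max(abs(build_hessian(nodes, force_constant("exponential", cutoff = 9))$values
        %*% C %*% modes$vectors[, 1] - modes$vectors[, 1]))
```

## 3. PCA, essential dynamics, fluctuation profiles

`pca_modes()` decomposes the covariance of mean-centered aligned conformers
(divisor m - 1, computed through SVD). Essential dynamics is the same
decomposition applied to `subsample_frames()` output: n equally spaced
snapshots (endpoints included) of a trajectory, aligned first. RMSF per
node is $\sqrt{\langle \|\Delta \mathbf{r}_i\|^2 \rangle}$ about the
ensemble mean, optionally restricted to P or N3 beads.

## 4. Mode-comparison metrics

For unit eigenvectors $\mathbf{p}$ (reference) and $\mathbf{u}_j$
(candidate set):

* overlap $O_j = |\mathbf{p} \cdot \mathbf{u}_j|$;
* cumulative overlap $CO(J) = \left(\sum_{j \le J} O_j^2\right)^{1/2}$;
* essential subspace overlap
  $SO_K = \left(\frac{1}{K}\sum_{i \le K}\sum_{j \le K} O_{ij}^2\right)^{1/2}$,
  symmetric, 1 for identical K-subspaces;
* collectivity $\kappa = N^{-1} \exp\left(-\sum_i m_i \ln m_i\right)$ with
  $m_i$ the normalized per-node squared displacement — 1/N when one node
  moves, 1 for uniform motion.

`scan_parameters()` grids coarse-graining scheme, cutoff and force-constant
law, scoring each cell by the best soft-mode overlap with the ensemble's
first PC (disconnected networks are marked failed; ties prefer the sparser
network).

## 5. Conformer generation and Gaussian benchmarks

`sample_conformers()` draws $\mathbf{x} = \mathbf{x}_0 + \sum_k c_k
\mathbf{u}_k$ with $c_k \sim N(0, s^2/\lambda_k)$ over the chosen soft
modes; $s$ is set so the expected RMSD from the reference equals the
target. PCA of such a sample must (and does) return the generating modes:

```{r}
conf <- sample_conformers(nodes, modes, n = 500, target_rmsd = 2, seed = 1)
pc <- pca_modes(conf)
round(sapply(1:3, function(k)
  mode_overlap(pc$modes$vectors[, k], modes$vectors[, k])), 3)
```

For controlled parameter-recovery experiments, `model_from_fractions()`
builds a Gaussian model whose population PCA spectrum has prescribed
leading fractions $f_k$: with total variance $T$ and dimension $D = 3N$,
the isotropic noise eigenvalue is $\tau^2 = T(1 - \sum f)/(D - K)$ and each
signal variance is $\sigma_k = T f_k - \tau^2$. `synthetic_trajectory()`
writes such samples as multi-model PDBs, optionally with a sinusoidal drift
along the first direction.

## 6. U-U pair geometry and types I–VI

`find_uu_pairs()` locates uracils at complementary duplex positions flanked
by canonical pairs. For each pair:

* **hydrogen bonds** (`detect_uu_hbonds()`): candidates are each N3 imino
  donor against the partner's O2/O4 carbonyls; a candidate passes at
  heavy-atom distance <= 3.5 A (plus an N3-H...O angle >= 135 degrees when
  hydrogens exist); each donor contributes at most one bond, so counts are
  0–2;
* **C1'-C1' distance**;
* **groove inclination** (`uu_inclination()`): the local helix axis runs
  between the flanking pairs' C1'-C1' midpoints, the pair long axis from
  C1'(a) to C1'(b); their cross product — sign-calibrated so canonical base
  centroids project negative — is the groove axis. The displacement of the
  uracil base-centroid midpoint along it, relative to the ideal builder
  geometry, is labeled `major` beyond +0.5 A and `minor` beyond -0.5 A.

The type table is exact: (2, minor) = I, (1, minor) = II, (0, none) = III,
(1, major) = IV, (2, major) = V, (0, major) = VI; off-table combinations
keep the bond count, coerce the inclination by displacement sign, and carry
an `atypical` flag. `perturb_uu()` inverts the classification: an in-plane
pose optimization of the two base moieties sets the bond pattern, then a
common groove translation sets the inclination:

```{r}
s <- build_cug_duplex(2, cap = "GC")
pair <- find_uu_pairs(s)[[1]]
classify_uu(perturb_uu(s, "I"), pair)
classify_uu(perturb_uu(s, "VI"), pair)
```

`cluster_uu_trajectory()` clusters one pair's conformations across frames:
pairwise heavy-atom RMSD after superposing each frame on the flanking
canonical pairs, average-linkage agglomeration cut at 3.0 A, populations
sorted and a centroid frame reported per cluster.

## 7. Determinism and the pipeline

All stochastic operations take explicit integer seeds and reproduce
byte-identically. The `rcug_cli()` dispatcher (installed script
`inst/scripts/rcug-tools.R`) chains the stages with TSV outputs whose `#`
headers echo the parameters, and writes a JSON manifest with MD5 checksums
of all inputs and outputs.
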