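# Conformer generation by deformation along ANM modes.

#' Deform a structure along one mode
#'
#' Adds `amplitude * mode` (reshaped to N x 3) to the reference coordinates.
#' For a unit-norm mode the RMSD from the reference is exactly
#' `amplitude / sqrt(N)`.
#'
#' @param reference a `node_set`.
#' @param mode unit-norm 3N mode vector.
#' @param amplitude displacement amplitude, Angstrom.
#' @return A `node_set` with displaced coordinates.
#' @export
deform_along_mode <- function(reference, mode, amplitude) {
  n <- nrow(reference$xyz)
  if (length(mode) != 3 * n)
    stop("mode length ", length(mode), " does not match ", n, " nodes")
  out <- reference
  out$xyz <- reference$xyz + amplitude * .row_to_coords(mode)
  out
}

#' Sample conformers along the softest ANM modes
#'
#' Generates `n` conformers `reference + sum_k c_k u_k` with independent
#' `c_k ~ Normal(0, s^2 / lambda_k)` over the selected modes -- the softest
#' modes receive the largest amplitudes, mirroring the equipartition
#' weighting of the network model. The global scale `s` is set so the
#' root-mean expected squared RMSD from the reference equals `target_rmsd`.
#' Pure mode displacements add no rigid-body motion, so the ensemble is
#' returned flagged aligned.
#'
#' @param reference a `node_set` (the ANM equilibrium structure).
#' @param modes a `mode_set` of kind ANM.
#' @param mode_indices which retained modes to deform along (default softest 3).
#' @param n number of conformers.
#' @param target_rmsd target expected RMSD from the reference, Angstrom.
#' @param seed integer seed; the same seed reproduces the ensemble exactly.
#' @return An `rna_ensemble` (aligned, source `"anm-conformers"`).
#' @export
sample_conformers <- function(reference, modes, mode_indices = 1:3, n = 2000,
                              target_rmsd = 2.0, seed = 1) {
  if (modes$kind != "ANM") stop("sample_conformers needs ANM modes")
  if (any(mode_indices < 1 | mode_indices > ncol(modes$vectors)))
    stop("mode indices out of range")
  lam <- modes$values[mode_indices]
  if (any(lam <= 0)) stop("selected mode has zero eigenvalue")
  stopifnot(n >= 1, target_rmsd > 0)
  N <- nrow(reference$xyz)
  # E[RMSD^2] = E[sum c_k^2]/N = s^2 sum(1/lambda)/N
  s <- target_rmsd * sqrt(N / sum(1 / lam))
  U <- modes$vectors[, mode_indices, drop = FALSE]
  set.seed(seed)
  coef <- matrix(stats::rnorm(n * length(lam)), n) %*% diag(s / sqrt(lam),
                                                            length(lam))
  base <- .coords_to_row(reference$xyz)
  xyz <- sweep(coef %*% t(U), 2, base, `+`)
  rna_ensemble(xyz, reference$labels, aligned = TRUE,
               source = "anm-conformers")
}
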