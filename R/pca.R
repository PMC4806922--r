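#' Principal component analysis of an aligned ensemble
#'
#' Decomposes the covariance of the mean-centered 3N coordinate vectors
#' (divisor m-1). At most `min(3N, m-1)` components carry variance; components
#' with negligible variance (below `1e-12` of the total) are dropped and
#' counted in `n_dropped`.
#'
#' @param ensemble an aligned `rna_ensemble` with at least 3 conformers.
#' @return A list with `modes` (a `mode_set` of kind PCA, eigenvectors in
#'   descending variance order, sign fixed like ANM modes) and `spectrum`
#'   (data frame: `mode`, `variance`, `fraction`), plus `mean` (the reference
#'   mean structure, N x 3).
#' @export
pca_modes <- function(ensemble) {
  if (!inherits(ensemble, "rna_ensemble")) stop("need an rna_ensemble")
  if (!ensemble$aligned)
    stop("ensemble is not aligned; run align_ensemble() first")
  m <- n_conformers(ensemble)
  if (m < 3) stop("PCA needs at least 3 conformers, got ", m)
  X <- sweep(ensemble$xyz, 2, colMeans(ensemble$xyz))
  # eigen through SVD of the centered data (stable for 3N >> m)
  sv <- svd(X)
  vars <- sv$d^2 / (m - 1)
  keep <- vars > 1e-12 * sum(vars)
  vars <- vars[keep]
  vecs <- sv$v[, keep, drop = FALSE]
  for (k in seq_len(ncol(vecs))) {
    imax <- which.max(abs(vecs[, k]))
    if (vecs[imax, k] < 0) vecs[, k] <- -vecs[, k]
  }
  md <- mode_set(vars, vecs, kind = "PCA",
                 n_dropped = sum(!keep), labels = ensemble$labels)
  spectrum <- data.frame(mode = seq_along(vars), variance = vars,
                         fraction = vars / sum(vars))
  list(modes = md, spectrum = spectrum,
       mean = ensemble_mean(ensemble), n_conformers = m)
}

#' Per-node fluctuation profile (RMSF)
#'
#' Root-mean-square fluctuation of each node about the ensemble mean,
#' restricted to a bead subset: `"CG"` keeps every node, `"P"` or `"N3"`
#' keep only nodes with that atom name.
#'
#' @param ensemble an aligned `rna_ensemble`.
#' @param subset `"CG"`, `"P"` or `"N3"`.
#' @return Data frame of class `fluct_profile`: node labels plus `rmsf` (A)
#'   and the subset tag.
#' @export
rmsf_profile <- function(ensemble, subset = c("CG", "P", "N3")) {
  subset <- match.arg(subset)
  if (!ensemble$aligned) stop("ensemble is not aligned")
  dev2 <- sweep(ensemble$xyz, 2, colMeans(ensemble$xyz))^2
  msf3 <- colMeans(dev2)
  per_node <- rowSums(matrix(msf3, ncol = 3, byrow = TRUE))
  out <- cbind(ensemble$labels, rmsf = sqrt(per_node))
  if (subset != "CG") out <- out[out$elety == subset, , drop = FALSE]
  if (nrow(out) == 0) stop("subset ", subset, " selects zero nodes")
  rownames(out) <- NULL
  out$subset <- subset
  class(out) <- c("fluct_profile", "data.frame")
  out
}

#' Evenly subsample trajectory frames and align them
#'
#' Takes `n` frames at equally spaced indices (first and last always
#' included; index k of n is `round((k-1) * (L-1) / (n-1)) + 1`), then runs
#' [align_ensemble()]. If fewer than `n` frames are available, all are kept
#' with a warning.
#'
#' @param trajectory list of `node_set` frames, or an (unaligned) `rna_ensemble`.
#' @param n number of snapshots to keep.
#' @return An aligned `rna_ensemble`.
#' @export
subsample_frames <- function(trajectory, n = 2000) {
  if (inherits(trajectory, "rna_ensemble")) {
    L <- n_conformers(trajectory)
    pick_row <- function(idx) rna_ensemble(trajectory$xyz[idx, , drop = FALSE],
                                           trajectory$labels,
                                           source = trajectory$source)
  } else {
    L <- length(trajectory)
    pick_row <- function(idx) {
      labels <- trajectory[[1]]$labels
      xyz <- do.call(rbind, lapply(trajectory[idx],
                                   function(f) .coords_to_row(f$xyz)))
      rna_ensemble(xyz, labels)
    }
  }
  if (L < n) {
    warning("trajectory has ", L, " frames < n = ", n, "; keeping all")
    idx <- seq_len(L)
  } else if (n == 1) {
    idx <- 1L
  } else {
    idx <- round((seq_len(n) - 1) * (L - 1) / (n - 1)) + 1L
  }
  align_ensemble(pick_row(idx))
}

#' Project conformers onto principal components
#'
#' Each conformer is superposed onto the PCA reference mean (removing
#' rigid-body contamination of cross-ensemble projections), mean-subtracted
#' and dotted with the first `k` eigenvectors.
#'
#' @param ensemble an `rna_ensemble` sharing node labels with `pcs`.
#' @param pcs result of [pca_modes()] (or a `mode_set` plus `mean` via the
#'   `mean` argument).
#' @param k number of components.
#' @param mean reference mean (N x 3) if `pcs` is a bare `mode_set`.
#' @param superpose superpose conformers onto the reference mean first
#'   (default TRUE).
#' @return m x k matrix of projection coordinates (columns pc1..pck).
#' @export
project_ensemble <- function(ensemble, pcs, k = 3, mean = NULL,
                             superpose = TRUE) {
  if (is.list(pcs) && !inherits(pcs, "mode_set")) {
    mean <- pcs$mean
    pcs <- pcs$modes
  }
  if (is.null(mean)) stop("reference mean required")
  .check_labels(ensemble$labels, pcs$labels)
  k <- min(k, ncol(pcs$vectors))
  mu <- .coords_to_row(mean)
  proj <- matrix(0, n_conformers(ensemble), k)
  for (i in seq_len(n_conformers(ensemble))) {
    xi <- .row_to_coords(ensemble$xyz[i, ])
    if (superpose) xi <- kabsch_superpose(xi, mean)$xyz
    proj[i, ] <- crossprod(pcs$vectors[, seq_len(k), drop = FALSE],
                           .coords_to_row(xi) - mu)
  }
  colnames(proj) <- paste0("pc", seq_len(k))
  proj
}
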