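#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' coordinate sets with known index correspondence.
#'
#' @param mobile N x 3 coordinate matrix to be moved.
#' @param reference N x 3 coordinate matrix to superpose onto.
#' @return A list with `rotation` (3x3, determinant +1), `translation`
#'   (length 3), `rmsd` (Angstrom) and `xyz` (the transformed mobile
#'   coordinates). The transform maps `mobile` as
#'   `mobile %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("coordinate dimensions differ: ", nrow(mobile), " vs ",
         nrow(reference), " atoms")
  if (nrow(mobile) < 3) stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  s <- svd(crossprod(X, Y)) # t(X) %*% Y
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- X %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  # column-vector convention on output: v' = rotation %*% v + translation,
  # equivalently xyz %*% t(rotation) for row-wise coordinates
  list(rotation = t(R), translation = as.numeric(cr - cm %*% R),
       rmsd = rmsd, xyz = sweep(fitted, 2, cr, `+`))
}

#' RMSD between two coordinate sets (no fitting)
#' @param a,b N x 3 matrices.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b) {
  sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
}

.label_key <- function(labels) {
  paste(labels$chain, labels$resno, labels$resname, labels$elety, sep = "|")
}

.check_labels <- function(la, lb, what = "node labels") {
  ka <- .label_key(la); kb <- .label_key(lb)
  if (length(ka) != length(kb) || any(ka != kb)) {
    bad <- which(ka != kb)[1]
    if (is.na(bad)) bad <- min(length(ka), length(kb)) + 1
    stop(what, " mismatch at node ", bad, ": '",
         if (bad <= length(ka)) ka[bad] else "<absent>", "' vs '",
         if (bad <= length(kb)) kb[bad] else "<absent>", "'")
  }
  invisible(TRUE)
}

#' Conformer ensemble objects
#'
#' An `rna_ensemble` stores m conformers over a common set of N nodes as an
#' m x 3N coordinate matrix (each row is x1,y1,z1,x2,...), the shared node
#' labels, an `aligned` flag and a free-text provenance tag.
#'
#' @param xyz m x 3N matrix of conformer coordinates.
#' @param labels node label data frame (`chain`, `resno`, `resname`, `elety`).
#' @param aligned logical; TRUE once the ensemble has been superposed onto its
#'   converged mean.
#' @param source free-text provenance.
#' @return An object of class `rna_ensemble`.
#' @export
rna_ensemble <- function(xyz, labels, aligned = FALSE, source = "") {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * nrow(labels))
    stop("xyz has ", ncol(xyz), " columns but labels describe ",
         nrow(labels), " nodes")
  structure(list(xyz = xyz, labels = labels, aligned = aligned,
                 source = source),
            class = "rna_ensemble")
}

#' @export
print.rna_ensemble <- function(x, ...) {
  cat("rna_ensemble: ", nrow(x$xyz), " conformers x ", nrow(x$labels),
      " nodes", if (x$aligned) " (aligned)" else " (unaligned)",
      if (nzchar(x$source)) paste0(" [", x$source, "]") else "", "\n", sep = "")
  invisible(x)
}

# m x 3N row -> N x 3
.row_to_coords <- function(row) matrix(row, ncol = 3, byrow = TRUE)
.coords_to_row <- function(xyz) as.numeric(t(xyz))

#' Number of conformers / nodes of an ensemble
#' @param ensemble an `rna_ensemble`.
#' @return Integer count.
#' @export
n_conformers <- function(ensemble) nrow(ensemble$xyz)

#' @rdname n_conformers
#' @export
n_nodes <- function(ensemble) nrow(ensemble$labels)

#' Iteratively superpose conformers onto their evolving mean
#'
#' All conformers are superposed onto the running mean structure, the mean is
#' recomputed, and the cycle repeats until the mean moves by less than `tol`
#' RMSD (or `max_iter` cycles). With two conformers the mean is a fixed point
#' after the first recentering, so convergence takes at most two iterations.
#'
#' @param conformers a list of `node_set` objects with identical labels, or an
#'   `rna_ensemble`.
#' @param tol convergence threshold on the mean shift, Angstrom RMSD.
#' @param max_iter maximum number of refinement cycles.
#' @param source provenance tag for the returned ensemble.
#' @return An aligned `rna_ensemble`.
#' @export
align_ensemble <- function(conformers, tol = 1e-6, max_iter = 100,
                           source = "") {
  if (inherits(conformers, "rna_ensemble")) {
    labels <- conformers$labels
    xyz <- conformers$xyz
    if (!nzchar(source)) source <- conformers$source
  } else {
    labels <- conformers[[1]]$labels
    for (cf in conformers[-1]) .check_labels(labels, cf$labels)
    xyz <- do.call(rbind, lapply(conformers, function(cf) .coords_to_row(cf$xyz)))
  }
  m <- nrow(xyz)
  if (m < 1) stop("empty ensemble")
  mean_xyz <- .row_to_coords(xyz[1, ])
  for (it in seq_len(max_iter)) {
    for (i in seq_len(m)) {
      fit <- kabsch_superpose(.row_to_coords(xyz[i, ]), mean_xyz)
      xyz[i, ] <- .coords_to_row(fit$xyz)
    }
    new_mean <- .row_to_coords(colMeans(xyz))
    shift <- coord_rmsd(new_mean, mean_xyz)
    mean_xyz <- new_mean
    if (shift < tol) break
  }
  rna_ensemble(xyz, labels, aligned = TRUE, source = source)
}

#' Mean structure of an ensemble
#' @param ensemble an `rna_ensemble`.
#' @return N x 3 matrix of mean node coordinates.
#' @export
ensemble_mean <- function(ensemble) .row_to_coords(colMeans(ensemble$xyz))
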