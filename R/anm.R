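#' Spring force-constant laws
#'
#' The elastic network potential is `V = 1/2 * sum_ij gamma(s0_ij) *
#' (s_ij - s0_ij)^2` over node pairs within the cutoff. Two laws for
#' `gamma(r)` are supported:
#' * `uniform`: `gamma0` inside the cutoff, 0 beyond;
#' * `exponential`: `gamma0 * exp(-(r - r_contact) / decay_length)` inside the
#'   cutoff -- contacts at `r_contact` (3 A) are weighted `gamma0` (default 12,
#'   arbitrary units) and the weighting decays to about 0.1 by 25 A with the
#'   default 4.6 A decay length.
#'
#' @param law `"uniform"` or `"exponential"`.
#' @param gamma0 force constant at contact, arbitrary units.
#' @param r_contact contact distance, Angstrom.
#' @param decay_length exponential decay length, Angstrom.
#' @param cutoff hard interaction cutoff `r_c`, Angstrom.
#' @return A list of class `force_constant`.
#' @export
force_constant <- function(law = c("exponential", "uniform"), gamma0 = 12,
                           r_contact = 3.0, decay_length = 4.6, cutoff = 9) {
  law <- match.arg(law)
  stopifnot(gamma0 > 0, decay_length > 0, cutoff > r_contact)
  structure(list(law = law, gamma0 = gamma0, r_contact = r_contact,
                 decay_length = decay_length, cutoff = cutoff),
            class = "force_constant")
}

#' Evaluate the force-constant law
#'
#' @param r pairwise distance(s), Angstrom; must be positive.
#' @param fc a [force_constant()].
#' @return gamma(r), zero beyond the cutoff; never negative.
#' @export
gamma_of_r <- function(r, fc = force_constant()) {
  if (any(r <= 0)) stop("gamma_of_r: distances must be positive")
  g <- switch(fc$law,
    uniform = rep(fc$gamma0, length(r)),
    exponential = fc$gamma0 * exp(-(r - fc$r_contact) / fc$decay_length))
  g[r > fc$cutoff] <- 0
  g
}

#' Elastic network potential energy
#'
#' Evaluates `V = 1/2 sum gamma_ij (s_ij - s0_ij)^2` for displaced
#' coordinates, with the contact set and spring constants fixed at the
#' equilibrium geometry (so V is smooth in the displaced coordinates).
#'
#' @param xyz displaced N x 3 coordinates.
#' @param xyz0 equilibrium N x 3 coordinates.
#' @param fc a [force_constant()].
#' @return Potential energy (arbitrary units).
#' @export
anm_potential <- function(xyz, xyz0, fc = force_constant()) {
  d0 <- as.matrix(stats::dist(xyz0))
  g <- matrix(0, nrow(d0), ncol(d0))
  up <- upper.tri(d0)
  g[up] <- gamma_of_r(d0[up], fc)
  d <- as.matrix(stats::dist(xyz))
  sum(0.5 * g[up] * (d[up] - d0[up])^2)
}

#' Build the ANM Hessian
#'
#' Assembles the 3N x 3N second-derivative matrix of the network potential at
#' the equilibrium geometry: the off-diagonal super-element of a connected
#' pair (i,j) is `-(gamma_ij / s0_ij^2) d_ij d_ij^T` with `d_ij` the
#' equilibrium displacement vector, and diagonal super-elements are minus the
#' row sums (translational invariance).
#'
#' @param nodes a `node_set` (or bare N x 3 matrix).
#' @param fc a [force_constant()].
#' @return A list of class `hessian_matrix` with `values` (3N x 3N),
#'   `labels`, `fc`.
#' @export
build_hessian <- function(nodes, fc = force_constant()) {
  xyz <- if (inherits(nodes, "node_set")) nodes$xyz else as.matrix(nodes)
  labels <- if (inherits(nodes, "node_set")) nodes$labels else NULL
  n <- nrow(xyz)
  if (n < 2) stop("need at least 2 nodes")
  dmat <- as.matrix(stats::dist(xyz))
  gmat <- matrix(0, n, n)
  off <- dmat > 0
  gmat[off] <- gamma_of_r(dmat[off], fc)
  diag(gmat) <- 0
  if (all(gmat == 0))
    stop("fully disconnected network: no node pair within cutoff ",
         fc$cutoff, " A; try a larger cutoff")
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) {
    ii <- (3 * i - 2):(3 * i)
    for (j in (i + 1):n) {
      if (gmat[i, j] == 0) next
      jj <- (3 * j - 2):(3 * j)
      d <- xyz[j, ] - xyz[i, ]
      blk <- -(gmat[i, j] / dmat[i, j]^2) * tcrossprod(d)
      H[ii, jj] <- blk
      H[jj, ii] <- blk
      H[ii, ii] <- H[ii, ii] - blk
      H[jj, jj] <- H[jj, jj] - blk
    }
  }
  structure(list(values = H, labels = labels, fc = fc, xyz = xyz),
            class = "hessian_matrix")
}

# orthonormal basis of the 6 rigid-body motions (3 translations, 3 rotations
# about the centroid) for N x 3 equilibrium coordinates
.rigid_body_basis <- function(xyz) {
  n <- nrow(xyz)
  ctr <- sweep(xyz, 2, colMeans(xyz))
  basis <- matrix(0, 3 * n, 6)
  for (k in 1:3) basis[seq(k, 3 * n, by = 3), k] <- 1
  axes <- diag(3)
  for (k in 1:3) {
    v <- t(apply(ctr, 1, function(p) c(axes[k, 2] * p[3] - axes[k, 3] * p[2],
                                       axes[k, 3] * p[1] - axes[k, 1] * p[3],
                                       axes[k, 1] * p[2] - axes[k, 2] * p[1])))
    basis[, 3 + k] <- as.numeric(t(v))
  }
  qr.Q(qr(basis))[, 1:6, drop = FALSE]
}

#' Mode sets (ANM or PCA)
#'
#' @param values eigenvalues: ascending stiffnesses (lambda) for ANM, or
#'   descending variances (sigma) for PCA.
#' @param vectors 3N x k matrix of orthonormal eigenvectors (columns).
#' @param kind `"ANM"` or `"PCA"`.
#' @param n_dropped number of removed rigid-body (ANM) or null (PCA) modes.
#' @param labels node labels.
#' @return A list of class `mode_set`.
#' @export
mode_set <- function(values, vectors, kind = c("ANM", "PCA"), n_dropped = 0L,
                     labels = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(values) == ncol(vectors))
  structure(list(values = values, vectors = vectors, kind = kind,
                 n_dropped = as.integer(n_dropped), labels = labels),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat("mode_set (", x$kind, "): ", length(x$values), " modes over ",
      nrow(x$vectors) / 3, " nodes (", x$n_dropped, " dropped)\n", sep = "")
  invisible(x)
}

#' Normal modes of an ANM Hessian
#'
#' Diagonalizes the Hessian, verifies that the near-zero eigenvalues span the
#' analytic rigid-body subspace, drops them, and returns the remaining 3N-6
#' modes in ascending stiffness with sign fixed so each mode's
#' largest-magnitude component is positive.
#'
#' @param h a `hessian_matrix`.
#' @param zero_tol eigenvalues below `zero_tol * max(lambda)` are treated as
#'   rigid-body zeros.
#' @return A `mode_set` of kind ANM.
#' @export
solve_modes <- function(h, zero_tol = 1e-8) {
  H <- h$values
  eg <- eigen((H + t(H)) / 2, symmetric = TRUE)
  vals <- rev(eg$values)
  vecs <- eg$vectors[, rev(seq_along(eg$values)), drop = FALSE]
  thr <- zero_tol * max(abs(vals))
  nzero <- sum(abs(vals) < thr)
  if (nzero > 6)
    stop("found ", nzero, " near-zero modes: the network has disconnected ",
         "components; increase the cutoff")
  if (nzero < 6)
    stop("only ", nzero, " near-zero modes found; Hessian is inconsistent")
  rb <- .rigid_body_basis(h$xyz)
  ov2 <- crossprod(rb, vecs[, 1:6, drop = FALSE])
  so <- sqrt(sum(ov2^2) / 6)
  if (so < 0.99)
    stop("near-zero modes do not span the rigid-body subspace (overlap ",
         round(so, 4), "); internal inconsistency")
  keep <- seq.int(7, length(vals))
  vecs <- vecs[, keep, drop = FALSE]
  for (k in seq_len(ncol(vecs))) {
    imax <- which.max(abs(vecs[, k]))
    if (vecs[imax, k] < 0) vecs[, k] <- -vecs[, k]
  }
  mode_set(vals[keep], vecs, kind = "ANM", n_dropped = 6L, labels = h$labels)
}

#' ANM covariance (pseudo-inverse of the Hessian)
#'
#' `C = sum_i (1/lambda_i) u_i u_i^T` over the retained modes: the model's
#' prediction of the coordinate covariance, proportional to the pseudo-inverse
#' of the Hessian.
#'
#' @param modes a `mode_set` of kind ANM.
#' @return Symmetric positive semi-definite 3N x 3N matrix.
#' @export
anm_covariance <- function(modes) {
  if (modes$kind != "ANM") stop("anm_covariance needs ANM modes")
  if (any(modes$values <= 0))
    stop("retained ANM modes include a zero eigenvalue")
  V <- modes$vectors
  V %*% (t(V) / modes$values)
}
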