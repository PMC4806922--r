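# Mode- and fluctuation-comparison statistics.

.unitize <- function(v, what = "mode vector") {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop(what, " is the zero vector")
  if (abs(nv - 1) > 1e-6) {
    warning(what, " renormalized (norm was ", format(nv), ")")
    v <- v / nv
  } else v <- v / nv
  v
}

#' Overlap between two mode vectors
#'
#' Absolute dot product of two unit eigenvectors: 1 for identical directions,
#' 0 for orthogonal ones. Sign is discarded because eigenvector sign is
#' arbitrary.
#'
#' @param p,u mode vectors of equal length (renormalized with a warning if
#'   off unit norm by more than 1e-6).
#' @return Overlap in `[0, 1]`.
#' @export
mode_overlap <- function(p, u) {
  if (length(p) != length(u))
    stop("mode vectors differ in length: ", length(p), " vs ", length(u))
  abs(sum(.unitize(p) * .unitize(u)))
}

#' Overlap table between two mode sets
#'
#' @param setA,setB `mode_set` objects over the same nodes.
#' @param kA,kB number of modes kept from each set.
#' @return kA x kB matrix of absolute overlaps.
#' @export
overlap_table <- function(setA, setB, kA = 6, kB = 6) {
  if (!is.null(setA$labels) && !is.null(setB$labels))
    .check_labels(setA$labels, setB$labels)
  kA <- min(kA, ncol(setA$vectors)); kB <- min(kB, ncol(setB$vectors))
  ot <- abs(crossprod(setA$vectors[, seq_len(kA), drop = FALSE],
                      setB$vectors[, seq_len(kB), drop = FALSE]))
  dimnames(ot) <- list(paste0(setA$kind, seq_len(kA)),
                       paste0(setB$kind, seq_len(kB)))
  ot
}

#' Cumulative overlap of a mode against a mode set
#'
#' `CO(J) = sqrt(sum_{j<=J} O_j^2)`: how well the J softest (or largest-
#' variance) modes of a set span one target mode. Monotone in J, reaching 1
#' for a complete basis.
#'
#' @param target a mode vector (e.g. one PC).
#' @param modes a `mode_set`.
#' @param J number of modes to accumulate.
#' @return Cumulative overlap in `[0, 1]` (clipped at 1 against rounding).
#' @export
cumulative_overlap <- function(target, modes, J = 20) {
  if (J < 1) stop("J must be >= 1")
  J <- min(J, ncol(modes$vectors))
  p <- .unitize(target)
  ov <- crossprod(modes$vectors[, seq_len(J), drop = FALSE], p)
  min(1, sqrt(sum(ov^2)))
}

#' Essential subspace overlap
#'
#' `SO_K = sqrt( (1/K) sum_{i<=K} sum_{j<=K} O_ij^2 )`: a normalized
#' Frobenius measure of agreement between the subspaces spanned by the top K
#' modes of two sets. 1 for identical subspaces, 0 for orthogonal ones;
#' symmetric in its arguments.
#'
#' @param setA,setB `mode_set` objects over the same nodes.
#' @param K subspace dimension.
#' @return Subspace overlap in `[0, 1]`.
#' @export
subspace_overlap <- function(setA, setB, K = 3) {
  if (!is.null(setA$labels) && !is.null(setB$labels))
    .check_labels(setA$labels, setB$labels)
  if (K > min(ncol(setA$vectors), ncol(setB$vectors)))
    stop("K exceeds the available mode count")
  O <- crossprod(setA$vectors[, seq_len(K), drop = FALSE],
                 setB$vectors[, seq_len(K), drop = FALSE])
  min(1, sqrt(sum(O^2) / K))
}

#' Degree of collectivity of a mode
#'
#' Entropy-based measure of how many nodes a mode displaces
#' (Brueschweiler): `kappa = (1/N) exp(-sum_i m_i log m_i)` with `m_i` the
#' normalized per-node squared displacement (summed over the node's three
#' components; natural logarithm; `0 log 0 := 0`). Ranges from 1/N (a single
#' node moves) to 1 (uniform motion).
#'
#' @param u a 3N mode vector.
#' @param n_nodes N; defaults to `length(u) / 3`.
#' @return Collectivity in `[1/N, 1]`.
#' @export
collectivity <- function(u, n_nodes = length(u) / 3) {
  if (length(u) != 3 * n_nodes) stop("length(u) must be 3 * n_nodes")
  if (all(u == 0)) stop("zero mode vector")
  m <- rowSums(matrix(u^2, ncol = 3, byrow = TRUE))
  m <- m / sum(m)
  ent <- -sum(ifelse(m > 0, m * log(m), 0))
  exp(ent) / n_nodes
}

#' Pearson correlation between two fluctuation profiles
#'
#' @param a,b `fluct_profile` data frames with the same subset tag and node
#'   labels, or bare numeric RMSF vectors of equal length.
#' @return Pearson r in `[-1, 1]`.
#' @export
fluctuation_correlation <- function(a, b) {
  if (inherits(a, "fluct_profile") && inherits(b, "fluct_profile")) {
    if (!identical(a$subset[1], b$subset[1]))
      stop("profiles use different subsets: ", a$subset[1], " vs ", b$subset[1])
    .check_labels(a, b)
    a <- a$rmsf; b <- b$rmsf
  }
  if (length(a) != length(b)) stop("profiles differ in length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: a profile has zero variance")
  stats::cor(a, b)
}

#' Scan coarse-graining schemes and cutoffs against a PC
#'
#' For every (scheme, cutoff, force-constant law) cell, builds an ANM on the
#' reference structure, and records the best absolute overlap between any of
#' the `n_soft` softest ANM modes and the ensemble's first PC. Cells whose
#' network is disconnected are marked failed and skipped. The best model is
#' the arg-max cell; ties go to the smaller cutoff (sparser network).
#'
#' @param pcs PCA result ([pca_modes()] output) or a named list of such
#'   results keyed by scheme name when multiple schemes are scanned.
#' @param reference `rna_structure` sharing topology with the ensemble.
#' @param schemes character vector of scheme names.
#' @param cutoffs numeric vector of cutoffs, Angstrom.
#' @param laws force-constant laws to scan.
#' @param n_soft how many soft modes compete for the best overlap.
#' @param gamma0,r_contact,decay_length force-constant parameters.
#' @return A list of class `scan_result`: `grid` (data frame with columns
#'   scheme, cutoff, law, best_overlap, best_mode, failed) and `best` (the
#'   arg-max row).
#' @export
scan_parameters <- function(pcs, reference, schemes = "CG2",
                            cutoffs = 5:15,
                            laws = "exponential", n_soft = 6,
                            gamma0 = 12, r_contact = 3.0,
                            decay_length = 4.6) {
  if (!is.null(pcs$modes)) pcs <- stats::setNames(list(pcs), schemes[1])
  rows <- list()
  for (sc in schemes) {
    if (is.null(pcs[[sc]]))
      stop("no PCA result supplied for scheme ", sc)
    pc1 <- pcs[[sc]]$modes$vectors[, 1]
    nodes <- select_nodes(reference, sc)
    .check_labels(nodes$labels, pcs[[sc]]$modes$labels)
    for (law in laws) for (rc in cutoffs) {
      row <- data.frame(scheme = sc, cutoff = rc, law = law,
                        best_overlap = NA_real_, best_mode = NA_integer_,
                        failed = FALSE)
      md <- tryCatch(
        solve_modes(build_hessian(nodes,
          force_constant(law, gamma0 = gamma0, r_contact = r_contact,
                         decay_length = decay_length, cutoff = rc))),
        error = function(e) NULL)
      if (is.null(md)) {
        row$failed <- TRUE
      } else {
        k <- min(n_soft, ncol(md$vectors))
        ov <- abs(crossprod(md$vectors[, seq_len(k), drop = FALSE], pc1))
        row$best_overlap <- max(ov)
        row$best_mode <- which.max(ov)
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  grid <- do.call(rbind, rows)
  ok <- grid[!grid$failed, , drop = FALSE]
  if (nrow(ok) == 0) stop("every scan cell failed (disconnected networks)")
  ok <- ok[order(-ok$best_overlap, ok$cutoff), , drop = FALSE]
  structure(list(grid = grid, best = ok[1, ]), class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  b <- x$best
  cat("scan_result: ", nrow(x$grid), " cells; best ", b$scheme, " / ",
      b$cutoff, " A / ", b$law, " (|overlap| = ", round(b$best_overlap, 3),
      " at mode ", b$best_mode, ")\n", sep = "")
  invisible(x)
}
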