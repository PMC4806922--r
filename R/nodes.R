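#' Coarse-graining schemes
#'
#' Three node-selection schemes for building elastic networks and ensemble
#' covariances from RNA structures:
#' * `CG1`: backbone-only beads P, C2', C4' (three per residue);
#' * `CG2`: backbone plus base probes P, C2', C4, N3 (four per residue), which
#'   carries hydrogen-bonding and U-U mobility information through the base
#'   N3/C4 atoms;
#' * `ALL`: every heavy atom.
#'
#' @param name one of `"ALL"`, `"CG1"`, `"CG2"`.
#' @return A list of class `cg_scheme` with elements `name` and `atoms`
#'   (character vector of atom names, or `NULL` for ALL).
#' @export
cg_scheme <- function(name = c("CG2", "CG1", "ALL")) {
  name <- match.arg(toupper(name[1]), c("CG2", "CG1", "ALL"))
  atoms <- switch(name,
    CG1 = c("P", "C2'", "C4'"),
    CG2 = c("P", "C2'", "C4", "N3"),
    ALL = NULL)
  structure(list(name = name, atoms = atoms), class = "cg_scheme")
}

.as_scheme <- function(scheme) {
  if (inherits(scheme, "cg_scheme")) scheme else cg_scheme(scheme)
}

#' Select coarse-grained nodes from a structure
#'
#' Walks residues in chain/residue order and keeps the scheme's atoms. For
#' CG1/CG2, residues missing a scheme atom (5'-terminal residues lack P)
#' contribute only the atoms present; the omissions are reported via
#' `message()`.
#'
#' @param structure an `rna_structure`.
#' @param scheme a `cg_scheme` or scheme name.
#' @return A `node_set`: list with `xyz` (N x 3), `labels` (data frame with
#'   `chain`, `resno`, `resname`, `elety`) and `scheme`.
#' @export
select_nodes <- function(structure, scheme = cg_scheme("CG2")) {
  scheme <- .as_scheme(scheme)
  a <- structure$atoms
  if (is.null(scheme$atoms)) {
    keep <- a[.element_of(a$elety) != "H", , drop = FALSE]
  } else {
    keep <- a[a$elety %in% scheme$atoms, , drop = FALSE]
    # preserve residue order, scheme-atom order within a residue
    keep <- keep[order(match(keep$chain, unique(a$chain)), keep$resno,
                       match(keep$elety, scheme$atoms)), , drop = FALSE]
    res <- residue_table(structure)
    n_expect <- nrow(res) * length(scheme$atoms)
    if (nrow(keep) < n_expect)
      message("select_nodes(", scheme$name, "): ", n_expect - nrow(keep),
              " scheme atom(s) absent (e.g. 5'-terminal P); using atoms present")
  }
  if (nrow(keep) == 0)
    stop("scheme ", scheme$name, " selects zero nodes from this structure")
  labels <- keep[, c("chain", "resno", "resname", "elety")]
  rownames(labels) <- NULL
  structure(list(xyz = unname(as.matrix(keep[, c("x", "y", "z")])),
                 labels = labels, scheme = scheme$name),
            class = "node_set")
}

#' @export
print.node_set <- function(x, ...) {
  cat("node_set: ", nrow(x$xyz), " nodes, scheme ", x$scheme, "\n", sep = "")
  invisible(x)
}

#' Restrict node sets to their common labels
#'
#' @param node_sets list of `node_set` objects.
#' @return The list with every member subset (in the first member's order) to
#'   the labels present in all of them.
#' @export
common_nodes <- function(node_sets) {
  keys <- lapply(node_sets, function(ns) .label_key(ns$labels))
  shared <- Reduce(intersect, keys)
  if (length(shared) < 2) stop("fewer than 2 nodes shared across conformers")
  shared <- keys[[1]][keys[[1]] %in% shared] # first member's order
  lapply(node_sets, function(ns) {
    idx <- match(shared, .label_key(ns$labels))
    structure(list(xyz = ns$xyz[idx, , drop = FALSE],
                   labels = ns$labels[idx, ],
                   scheme = ns$scheme),
              class = "node_set")
  })
}
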