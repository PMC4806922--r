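#' RNA structure objects
#'
#' An `rna_structure` holds the ordered atoms of one model of an RNA molecule:
#' a data frame with one row per atom (columns `chain`, `resno`, `resname`,
#' `elety`, `x`, `y`, `z`, `o`, `b`) plus a model id. Residues within a chain
#' are strictly ordered by `resno` and every residue has at least one atom.
#'
#' @param atoms data frame of atom records (see Details).
#' @param model integer model id (1 for single-model structures).
#' @return An object of class `rna_structure`.
#' @export
rna_structure <- function(atoms, model = 1L) {
  need <- c("chain", "resno", "resname", "elety", "x", "y", "z")
  missing <- setdiff(need, names(atoms))
  if (length(missing) > 0)
    stop("atoms is missing columns: ", paste(missing, collapse = ", "))
  if (nrow(atoms) == 0) stop("structure contains no RNA atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  bad <- !atoms$resname %in% c("A", "C", "G", "U")
  if (any(bad))
    stop("unsupported residue name(s): ",
         paste(unique(atoms$resname[bad]), collapse = ", "),
         " (supply an alias map to normalize modified residues)")
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)), atoms$resno), ]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, model = as.integer(model)),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  nres <- sum(!duplicated(x$atoms[, c("chain", "resno")]))
  cat("rna_structure: ", nres, " residues in ", length(ch), " chain(s) [",
      paste(ch, collapse = ","), "], ", nrow(x$atoms), " atoms, model ",
      x$model, "\n", sep = "")
  invisible(x)
}

#' Per-chain residue table of a structure
#'
#' @param structure an `rna_structure`.
#' @return Data frame with one row per residue: `chain`, `resno`, `resname`.
#' @export
residue_table <- function(structure) {
  a <- structure$atoms
  r <- a[!duplicated(a[, c("chain", "resno")]), c("chain", "resno", "resname")]
  rownames(r) <- NULL
  r
}

#' Chain sequences of a structure
#'
#' @param structure an `rna_structure`.
#' @return Named character vector, one single-letter sequence per chain,
#'   5' to 3' in residue order.
#' @export
chain_sequences <- function(structure) {
  r <- residue_table(structure)
  vapply(split(r, factor(r$chain, levels = unique(r$chain))),
         function(d) paste(d$resname, collapse = ""), character(1))
}

# coordinates of one named atom of one residue (or NULL if absent)
.atom_xyz <- function(structure, chain, resno, elety) {
  a <- structure$atoms
  i <- which(a$chain == chain & a$resno == resno & a$elety == elety)
  if (length(i) == 0) return(NULL)
  as.numeric(a[i[1], c("x", "y", "z")])
}

# all atoms of one residue
.residue_atoms <- function(structure, chain, resno) {
  a <- structure$atoms
  a[a$chain == chain & a$resno == resno, , drop = FALSE]
}

#' Apply a rigid transform to a structure
#'
#' @param structure an `rna_structure`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector, applied after rotation.
#' @return The transformed `rna_structure`.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, `+`)
  structure$atoms[, c("x", "y", "z")] <- xyz
  structure
}

# element symbol from an atom name
.element_of <- function(elety) {
  substr(gsub("[^A-Za-z].*$", "", elety), 1, 1)
}
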