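# PDB reading (via bio3d) and multi-model writing.

.SOLVENT_RESIDUES <- c("HOH", "WAT", "DOD", "H2O", "NA", "K", "MG", "CL",
                       "ZN", "MN", "CA", "SO4", "PO4", "GOL", "EDO", "SPM",
                       "SPD", "BR", "IOD", "CS", "SR", "NH4", "ACT")

#' Read RNA structures from a PDB file
#'
#' Parses ATOM/HETATM records with `bio3d::read.pdb()`, returning one
#' `rna_structure` per MODEL (a single-model file yields a list of length 1).
#' Alternate locations are resolved to the highest occupancy (ties broken
#' alphabetically, so 'A' wins). Solvent and ion residues are dropped with a
#' reported count. Modified residues are rejected unless `aliases` maps them
#' to a parent base (e.g. `c("5BU" = "U")`), because silently substituting a
#' base would corrupt U-U classification.
#'
#' @param path PDB file path.
#' @param aliases named character vector mapping modified residue names to
#'   A/C/G/U.
#' @return List of `rna_structure` objects.
#' @export
read_rna_pdb <- function(path, aliases = character(0)) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("unreadable PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  resname <- trimws(at$resid)
  # normalize aliases before the RNA filter
  hit <- resname %in% names(aliases)
  resname[hit] <- unname(aliases[resname[hit]])
  is_rna <- resname %in% c("A", "C", "G", "U")
  is_solvent <- resname %in% .SOLVENT_RESIDUES
  unknown <- unique(resname[!is_rna & !is_solvent])
  if (length(unknown) > 0)
    stop("unrecognized residue(s) in '", path, "': ",
         paste(unknown, collapse = ", "),
         " -- supply an alias map to normalize modified residues")
  n_drop <- sum(!is_rna)
  if (n_drop > 0)
    message("read_rna_pdb: dropped ", n_drop, " non-RNA atom(s) (",
            paste(unique(resname[is_solvent]), collapse = ", "), ")")
  if (!any(is_rna)) stop("no RNA residues found in '", path, "'")

  at <- at[is_rna, , drop = FALSE]
  resname <- resname[is_rna]
  alt <- trimws(at$alt); alt[is.na(alt)] <- ""
  occ <- suppressWarnings(as.numeric(at$o)); occ[is.na(occ)] <- 1
  # altloc: per (chain, resno, atom), keep highest occupancy, then 'A' first
  key <- paste(at$chain, at$resno, trimws(at$elety))
  ord <- order(key, -occ, alt)
  keep_first <- !duplicated(key[ord])
  sel <- sort(seq_along(key)[ord][keep_first])
  n_alt <- length(key) - length(sel)
  if (n_alt > 0)
    message("read_rna_pdb: pruned ", n_alt, " alternate location(s)")

  xyz_rows <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1)
  # column indices of selected atoms in the xyz rows
  ci <- as.vector(t(outer(sel, c(2, 1, 0), function(i, o) 3 * i - o)))
  b <- suppressWarnings(as.numeric(at$b)); b[is.na(b)] <- 0
  lapply(seq_len(nrow(xyz_rows)), function(mi) {
    xyz <- matrix(xyz_rows[mi, ci], ncol = 3, byrow = TRUE)
    rna_structure(data.frame(
      chain = at$chain[sel], resno = at$resno[sel],
      resname = resname[sel], elety = trimws(at$elety)[sel],
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      o = occ[sel], b = b[sel], stringsAsFactors = FALSE), model = mi)
  })
}

# one fixed-width ATOM record
.pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                           o = 1, b = 0) {
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000, nm, resname, chain, resno %% 10000, x, y, z, o, b,
          .element_of(name))
}

.structure_lines <- function(s) {
  a <- s$atoms
  c(vapply(seq_len(nrow(a)), function(i)
      .pdb_atom_line(i, a$elety[i], a$resname[i], a$chain[i], a$resno[i],
                     a$x[i], a$y[i], a$z[i], a$o[i], a$b[i]),
      character(1)),
    "TER")
}

#' Write structures or an ensemble to a (multi-model) PDB file
#'
#' A single `rna_structure` is written as plain ATOM records; a list of
#' structures or an `rna_ensemble` as MODEL/ENDMDL blocks. Coordinates are
#' stored at the PDB's 1e-3 A precision.
#'
#' @param x an `rna_structure`, a list of them, or an `rna_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rna_pdb <- function(x, path) {
  if (inherits(x, "rna_ensemble")) x <- ensemble_to_structures(x)
  if (inherits(x, "rna_structure")) {
    lines <- c(.structure_lines(x), "END")
  } else {
    lines <- unlist(lapply(seq_along(x), function(i)
      c(sprintf("MODEL %8d", i), .structure_lines(x[[i]]), "ENDMDL")))
    lines <- c(lines, "END")
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write PDB file: ", path)
  invisible(path)
}

#' Expand an ensemble into per-conformer structures
#'
#' @param ensemble an `rna_ensemble`.
#' @return List of `rna_structure` objects built from the ensemble's node
#'   labels and coordinates.
#' @export
ensemble_to_structures <- function(ensemble) {
  lab <- ensemble$labels
  lapply(seq_len(n_conformers(ensemble)), function(i) {
    xyz <- .row_to_coords(ensemble$xyz[i, ])
    rna_structure(data.frame(
      chain = lab$chain, resno = lab$resno, resname = lab$resname,
      elety = lab$elety, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      o = 1, b = 0, stringsAsFactors = FALSE), model = i)
  })
}

#' Write an ensemble's node-label table as TSV
#'
#' @param ensemble an `rna_ensemble`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_node_labels <- function(ensemble, path) {
  utils::write.table(ensemble$labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
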