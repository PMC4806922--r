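#' A-form helix parameters
#'
#' Helical step parameters for the idealized A-form duplex builder. Defaults
#' follow fiber-diffraction A-RNA canon: 32.7 degrees twist and 2.81 A rise
#' per step, base pairs displaced -4.4 A from the helix axis and inclined by
#' 19 degrees.
#'
#' @param twist helical twist per step, degrees; must lie in (0, 360).
#' @param rise rise per step, Angstrom; must be positive.
#' @param x_disp displacement of the base-pair frame from the helix axis, A.
#' @param inclination base-pair inclination about the pair long axis, degrees.
#' @return A list of class `helix_params`.
#' @export
aform_params <- function(twist = 32.7, rise = 2.81, x_disp = -4.4,
                         inclination = 19) {
  stopifnot(twist > 0, twist < 360, rise > 0)
  structure(list(twist = twist, rise = rise, x_disp = x_disp,
                 inclination = inclination),
            class = "helix_params")
}

# complement under the U.U rule used throughout: A-U, C-G, G-C and U-U
.cug_complement <- function(base) {
  c(A = "U", C = "G", G = "C", U = "U")[[base]]
}

# memoized 2D pair placements (deterministic optimizer output)
.pair_cache <- new.env(parent = emptyenv())

.paired_bases_2d <- function(baseA, baseB) {
  key <- paste0(baseA, baseB)
  if (!is.null(.pair_cache[[key]])) return(.pair_cache[[key]])
  A <- .place_base_A(baseA)
  avoid <- if (baseA == "U" && baseB == "U") .uu_wobble_avoid else NULL
  B <- .place_base_B(A, baseB, .pair_anchors(baseA, baseB), avoid = avoid)
  # normalize the pair frame: C1'-C1' midpoint at the origin, C1'(A)->C1'(B)
  # along +x, so the helical transform sees a consistent local frame
  c1a <- A[rownames(A) == "C1'", ]
  c1b <- B[rownames(B) == "C1'", ]
  mid <- (c1a + c1b) / 2
  theta <- -atan2(c1b[2] - c1a[2], c1b[1] - c1a[1])
  fix <- function(p) {
    out <- .rot2(sweep(unclass(p), 2, mid), theta)
    rownames(out) <- rownames(p)
    structure(out, ring = attr(p, "ring"), glyco = attr(p, "glyco"))
  }
  out <- list(A = fix(A), B = fix(B))
  .pair_cache[[key]] <- out
  out
}

# backbone offsets relative to C1', strand A residue, in the pair-local frame;
# P is mostly tangential/axial so the P radius (and hence P-P spacing) stays
# near the C1' radius
.BACKBONE_OFFSETS_A <- rbind(
  `C2'` = c(-1.0, -0.8, 0.8),
  `C4'` = c(-1.4,  0.8, 1.5),
  P     = c(-0.9,  2.9, 2.6))

.rx <- function(deg) {
  t <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
}
.rz <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

#' Build an idealized A-form RNA duplex
#'
#' Constructs a double-stranded A-form helix from the sequence of one strand.
#' The complementary strand is derived with U paired to U (so any `(CUG)n`
#' tract yields one non-canonical U-U pair per repeat, and self-complementary
#' sequences such as `GCUGCUGC` close into a duplex). Canonical pairs are
#' placed as Watson-Crick geometry; U-U pairs adopt the stretched wobble
#' conformation with a single N3(imino)...O4(carbonyl) hydrogen bond.
#'
#' Each residue carries P (absent on 5'-terminal residues), C1', C2', C4' and
#' all base ring plus exocyclic heavy atoms -- a superset of the CG1/CG2
#' coarse-graining schemes and of the atoms needed for U-U classification.
#' The geometry is idealized (regular rings, pseudo-sugar backbone), not
#' chemically refined.
#'
#' @param sequence strand-A sequence, 5' to 3', letters A/C/G/U.
#' @param params helix parameters from [aform_params()].
#' @return An `rna_structure` with chains "A" and "B".
#' @export
build_aform_duplex <- function(sequence, params = aform_params()) {
  seqA <- strsplit(toupper(sequence), "")[[1]]
  if (length(seqA) < 2) stop("sequence must have at least 2 residues")
  bad <- !seqA %in% c("A", "C", "G", "U")
  if (any(bad)) stop("invalid sequence character(s): ",
                     paste(unique(seqA[bad]), collapse = ", "))
  n <- length(seqA)
  seqB_pair <- vapply(seqA, .cug_complement, character(1)) # by pair index

  dyad <- diag(c(-1, 1, -1)) # strand-B backbone via the pair pseudo-dyad
  rows <- vector("list", 2 * n)

  residue_atoms <- function(base, strand, k) {
    pl <- .paired_bases_2d(seqA[k + 1], seqB_pair[k + 1])
    pts2 <- if (strand == "A") pl$A else pl$B
    base_xyz <- cbind(unclass(pts2), 0)
    c1 <- base_xyz[rownames(pts2) == "C1'", ]
    off <- if (strand == "A") .BACKBONE_OFFSETS_A else .BACKBONE_OFFSETS_A %*% dyad
    bb <- sweep(off, 2, c1, `+`)
    xyz <- rbind(bb, base_xyz)
    nm <- c(rownames(off), rownames(pts2))
    # helical placement of pair k; the axis displacement acts along the pair
    # pseudo-dyad (local y), keeping the two strands at equal helical radius
    xyz <- xyz %*% t(.rx(params$inclination))
    xyz[, 2] <- xyz[, 2] + params$x_disp
    xyz <- xyz %*% t(.rz(k * params$twist))
    xyz[, 3] <- xyz[, 3] + k * params$rise
    data.frame(elety = nm, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  }

  out <- list()
  for (i in seq_len(n)) { # strand A, residue i pairs at step k = i - 1
    at <- residue_atoms(seqA[i], "A", i - 1)
    if (i == 1) at <- at[at$elety != "P", , drop = FALSE] # 5' terminus
    at$chain <- "A"; at$resno <- i; at$resname <- seqA[i]
    out[[length(out) + 1]] <- at
  }
  for (j in seq_len(n)) { # strand B 5'->3': residue j pairs with A residue n+1-j
    k <- n - j
    at <- residue_atoms(seqB_pair[k + 1], "B", k)
    if (j == 1) at <- at[at$elety != "P", , drop = FALSE]
    at$chain <- "B"; at$resno <- j; at$resname <- seqB_pair[k + 1]
    out[[length(out) + 1]] <- at
  }
  atoms <- do.call(rbind, out)
  atoms$o <- 1; atoms$b <- 0
  rna_structure(atoms[, c("chain", "resno", "resname", "elety",
                          "x", "y", "z", "o", "b")])
}

#' Convenience (CUG)n duplex
#'
#' @param n_repeats number of CUG repeats per strand.
#' @param cap optional two-letter cap, e.g. `"GC"` prepends G and appends C
#'   (the capped two-repeat construct is `"GCUGCUGC"`); `""` for none.
#' @param params helix parameters.
#' @return An `rna_structure`.
#' @export
build_cug_duplex <- function(n_repeats, cap = "", params = aform_params()) {
  stopifnot(n_repeats >= 1)
  seqA <- paste(rep("CUG", n_repeats), collapse = "")
  if (nzchar(cap)) {
    if (nchar(cap) != 2) stop("cap must be two letters, e.g. \"GC\"")
    seqA <- paste0(substr(cap, 1, 1), seqA, substr(cap, 2, 2))
  }
  build_aform_duplex(seqA, params)
}
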