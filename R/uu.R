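# Non-canonical U-U pair location, measurement and classification.

.CANONICAL_PAIRS <- c("AU", "UA", "CG", "GC")

#' Locate non-canonical U-U pairs in a duplex
#'
#' Finds uracils at complementary positions flanked on both sides by
#' canonical pairs (the 1x1 internal-loop motif of CUG repeats).
#'
#' @param structure an `rna_structure` duplex.
#' @return List of `uu_pair` records: chain/resno of the two uracils (`a` on
#'   the reference strand, `b` on the complementary strand) and of the 5'-
#'   and 3'-flanking canonical pairs. Empty list if no U-U pair qualifies.
#' @export
find_uu_pairs <- function(structure) {
  ch <- tryCatch(duplex_chains(structure), error = function(e) NULL)
  if (is.null(ch)) return(list())
  seqs <- chain_sequences(structure)
  sa <- strsplit(seqs[[ch[1]]], "")[[1]]
  sb <- strsplit(seqs[[ch[2]]], "")[[1]]
  res <- residue_table(structure)
  ra <- res$resno[res$chain == ch[1]]
  rb <- res$resno[res$chain == ch[2]]
  L <- length(sa)
  pair_of <- function(i) paste0(sa[i], sb[L + 1 - i])
  out <- list()
  for (i in seq_len(L)) {
    if (pair_of(i) != "UU") next
    if (i == 1 || i == L) next # terminal U-U has no flanks
    if (!pair_of(i - 1) %in% .CANONICAL_PAIRS) next
    if (!pair_of(i + 1) %in% .CANONICAL_PAIRS) next
    out[[length(out) + 1]] <- structure(list(
      chain_a = ch[1], resno_a = ra[i],
      chain_b = ch[2], resno_b = rb[L + 1 - i],
      flank5 = list(chain_a = ch[1], resno_a = ra[i - 1],
                    chain_b = ch[2], resno_b = rb[L + 1 - (i - 1)]),
      flank3 = list(chain_a = ch[1], resno_a = ra[i + 1],
                    chain_b = ch[2], resno_b = rb[L + 1 - (i + 1)]),
      position = i), class = "uu_pair")
  }
  out
}

.need_atom <- function(structure, chain, resno, elety) {
  p <- .atom_xyz(structure, chain, resno, elety)
  if (is.null(p))
    stop("residue ", chain, ":", resno, " is missing atom ", elety)
  p
}

#' Detect direct hydrogen bonds of a U-U pair
#'
#' Candidates are the imino donor N3 of each uracil against the carbonyl
#' acceptors O2/O4 of its partner. A candidate forms a bond if the heavy-atom
#' distance is within `dist_cutoff`; when the imino hydrogen (atom `H3`) is
#' present the N3-H...O angle must also reach `angle_cutoff` (crystal models
#' without hydrogens are judged on distance alone). Each donor contributes at
#' most one bond (the closest acceptor wins), so the count is 0, 1 or 2.
#'
#' @param structure an `rna_structure`.
#' @param pair a `uu_pair`.
#' @param dist_cutoff heavy-atom donor-acceptor cutoff, Angstrom.
#' @param angle_cutoff minimum N3-H...O angle, degrees (only with H present).
#' @return Data frame with one row per bond: donor residue/atom, acceptor
#'   residue/atom, distance (and angle if measurable).
#' @export
detect_uu_hbonds <- function(structure, pair, dist_cutoff = 3.5,
                             angle_cutoff = 135) {
  res <- list(a = c(pair$chain_a, pair$resno_a),
              b = c(pair$chain_b, pair$resno_b))
  atoms <- list()
  for (r in names(res))
    for (el in c("N3", "O2", "O4"))
      atoms[[paste0(r, el)]] <-
        .need_atom(structure, res[[r]][1], as.integer(res[[r]][2]), el)
  bonds <- list()
  for (donor in names(res)) {
    partner <- setdiff(names(res), donor)
    h <- .atom_xyz(structure, res[[donor]][1],
                   as.integer(res[[donor]][2]), "H3")
    best <- NULL
    for (acc in c("O2", "O4")) {
      d <- sqrt(sum((atoms[[paste0(donor, "N3")]] -
                       atoms[[paste0(partner, acc)]])^2))
      if (d > dist_cutoff) next
      ang <- NA_real_
      if (!is.null(h)) {
        v1 <- atoms[[paste0(donor, "N3")]] - h
        v2 <- atoms[[paste0(partner, acc)]] - h
        ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
        if (ang < angle_cutoff) next
      }
      if (is.null(best) || d < best$distance)
        best <- data.frame(donor_res = donor, donor = "N3",
                           acceptor_res = partner, acceptor = acc,
                           distance = d, angle = ang)
    }
    if (!is.null(best)) bonds[[length(bonds) + 1]] <- best
  }
  if (length(bonds) == 0)
    return(data.frame(donor_res = character(0), donor = character(0),
                      acceptor_res = character(0), acceptor = character(0),
                      distance = numeric(0), angle = numeric(0)))
  do.call(rbind, bonds)
}

#' C1'-C1' distance of a pair
#'
#' @param structure an `rna_structure`.
#' @param pair a `uu_pair` (or any list with chain/resno fields `chain_a`,
#'   `resno_a`, `chain_b`, `resno_b`).
#' @return Euclidean distance, Angstrom.
#' @export
c1c1_distance <- function(structure, pair) {
  a <- .need_atom(structure, pair$chain_a, pair$resno_a, "C1'")
  b <- .need_atom(structure, pair$chain_b, pair$resno_b, "C1'")
  sqrt(sum((a - b)^2))
}

.pair_c1_mid <- function(structure, p) {
  (.need_atom(structure, p$chain_a, p$resno_a, "C1'") +
     .need_atom(structure, p$chain_b, p$resno_b, "C1'")) / 2
}

.base_centroid <- function(structure, chain, resno) {
  at <- .residue_atoms(structure, chain, resno)
  ring <- .base_ring_atoms(at$resname[1])
  at <- at[at$elety %in% ring, , drop = FALSE]
  if (nrow(at) == 0) stop("no base ring atoms for ", chain, ":", resno)
  colMeans(as.matrix(at[, c("x", "y", "z")]))
}

.pair_base_centroid_mid <- function(structure, p) {
  (.base_centroid(structure, p$chain_a, p$resno_a) +
     .base_centroid(structure, p$chain_b, p$resno_b)) / 2
}

# groove axis of a U-U pair: g = h x l, sign calibrated so the flanking
# canonical-pair base centroids project negative (minor-groove side)
.uu_groove_axis <- function(structure, pair) {
  if (is.null(pair$flank5) || is.null(pair$flank3))
    stop("flanking pair missing: terminal U-U pairs have no groove frame")
  m5 <- .pair_c1_mid(structure, pair$flank5)
  m3 <- .pair_c1_mid(structure, pair$flank3)
  h <- m3 - m5; h <- h / sqrt(sum(h^2))
  a <- .need_atom(structure, pair$chain_a, pair$resno_a, "C1'")
  b <- .need_atom(structure, pair$chain_b, pair$resno_b, "C1'")
  l <- b - a; l <- l / sqrt(sum(l^2))
  g <- c(h[2] * l[3] - h[3] * l[2],
         h[3] * l[1] - h[1] * l[3],
         h[1] * l[2] - h[2] * l[1])
  g <- g / sqrt(sum(g^2))
  cal <- mean(vapply(list(pair$flank5, pair$flank3), function(fp) {
    sum(g * (.pair_base_centroid_mid(structure, fp) -
               .pair_c1_mid(structure, fp)))
  }, numeric(1)))
  if (cal > 0) g <- -g
  g
}

# raw groove projection of the U-U base centroid midpoint
.uu_groove_raw <- function(structure, pair) {
  g <- .uu_groove_axis(structure, pair)
  sum(g * (.pair_base_centroid_mid(structure, pair) -
             .pair_c1_mid(structure, pair)))
}

.ideal_cache <- new.env(parent = emptyenv())

# reference groove projection on the ideal builder geometry (memoized)
.ideal_uu_offset <- function() {
  if (is.null(.ideal_cache$offset)) {
    s <- build_cug_duplex(2, cap = "GC")
    p <- find_uu_pairs(s)[[1]]
    .ideal_cache$offset <- .uu_groove_raw(s, p)
  }
  .ideal_cache$offset
}

#' Groove inclination of a U-U pair
#'
#' Measures the displacement of the pair's base-ring centroid midpoint along
#' the groove axis (the cross product of the local helix axis, taken between
#' the flanking pairs' C1'-C1' midpoints, and the pair long axis), relative
#' to the same quantity on the ideal A-form builder geometry. Displacements
#' beyond +0.5 A are labeled `major`, beyond -0.5 A `minor`, otherwise
#' `none`.
#'
#' @param structure an `rna_structure`.
#' @param pair a `uu_pair` with resolvable flanking pairs.
#' @param reference_offset baseline groove projection; defaults to the value
#'   measured on the unperturbed builder duplex.
#' @param dead_zone half-width of the `none` band, Angstrom.
#' @return List with `label` (`"minor"`, `"none"`, `"major"`) and
#'   `displacement` (A).
#' @export
uu_inclination <- function(structure, pair, reference_offset = NULL,
                           dead_zone = 0.5) {
  if (is.null(reference_offset)) reference_offset <- .ideal_uu_offset()
  disp <- .uu_groove_raw(structure, pair) - reference_offset
  label <- if (disp > dead_zone) "major" else if (disp < -dead_zone) "minor"
  else "none"
  list(label = label, displacement = disp)
}

.UU_TYPE_TABLE <- data.frame(
  type = c("I", "II", "III", "IV", "V", "VI"),
  n_hbonds = c(2L, 1L, 0L, 1L, 2L, 0L),
  inclination = c("minor", "minor", "none", "major", "major", "major"),
  stringsAsFactors = FALSE)

#' Classify a U-U pair into types I-VI
#'
#' Types are defined by hydrogen-bond count and groove inclination:
#' I = (2, minor), II = (1, minor), III = (0, none), IV = (1, major),
#' V = (2, major), VI = (0, major). Combinations outside the table keep the
#' bond count, coerce the inclination to the nearest tabulated option for
#' that count (by displacement sign) and are flagged atypical.
#'
#' @param structure an `rna_structure`.
#' @param pair a `uu_pair`.
#' @param dist_cutoff,angle_cutoff hydrogen-bond criteria, see
#'   [detect_uu_hbonds()].
#' @param reference_offset see [uu_inclination()].
#' @return A list of class `uu_class`: `type`, `n_hbonds`, `inclination`,
#'   `displacement`, `c1c1_distance`, `atypical`.
#' @export
classify_uu <- function(structure, pair, dist_cutoff = 3.5,
                        angle_cutoff = 135, reference_offset = NULL) {
  hb <- detect_uu_hbonds(structure, pair, dist_cutoff, angle_cutoff)
  nh <- min(nrow(hb), 2L)
  inc <- uu_inclination(structure, pair, reference_offset)
  tab <- .UU_TYPE_TABLE[.UU_TYPE_TABLE$n_hbonds == nh, ]
  hit <- tab[tab$inclination == inc$label, , drop = FALSE]
  atypical <- nrow(hit) == 0
  if (atypical) {
    # coerce toward the tabulated option on the measured displacement's side
    pick <- if (inc$displacement >= 0) {
      tab[tab$inclination %in% c("major", "none"), , drop = FALSE]
    } else {
      tab[tab$inclination %in% c("minor", "none"), , drop = FALSE]
    }
    hit <- pick[1, , drop = FALSE]
  }
  structure(list(type = hit$type, n_hbonds = nh, inclination = inc$label,
                 displacement = inc$displacement,
                 c1c1_distance = c1c1_distance(structure, pair),
                 atypical = atypical),
            class = "uu_class")
}

#' @export
print.uu_class <- function(x, ...) {
  cat("U-U type ", x$type, if (x$atypical) " (atypical)", ": ", x$n_hbonds,
      " H-bond(s), ", x$inclination, " inclination (",
      sprintf("%+.2f", x$displacement), " A), C1'-C1' ",
      round(x$c1c1_distance, 2), " A\n", sep = "")
  invisible(x)
}

#' Classification table of every U-U pair in a structure
#'
#' @param structure an `rna_structure`.
#' @param ... passed to [classify_uu()].
#' @return Data frame: pair id, residues, type, n_hbonds, inclination,
#'   displacement and C1'-C1' distance.
#' @export
classify_uu_table <- function(structure, ...) {
  pairs <- find_uu_pairs(structure)
  if (length(pairs) == 0)
    return(data.frame(pair = integer(0), res_a = character(0),
                      res_b = character(0), type = character(0),
                      n_hbonds = integer(0), inclination = character(0),
                      displacement = numeric(0), c1c1 = numeric(0)))
  do.call(rbind, lapply(seq_along(pairs), function(i) {
    cl <- classify_uu(structure, pairs[[i]], ...)
    data.frame(pair = i,
               res_a = paste0(pairs[[i]]$chain_a, pairs[[i]]$resno_a),
               res_b = paste0(pairs[[i]]$chain_b, pairs[[i]]$resno_b),
               type = cl$type, n_hbonds = cl$n_hbonds,
               inclination = cl$inclination,
               displacement = cl$displacement, c1c1 = cl$c1c1_distance)
  }))
}

# pairwise best-fit RMSD of a U-U pair's heavy atoms across frames, after
# superposing each frame on the flanking canonical pairs
.uu_frame_coords <- function(frame, pair) {
  ra <- .residue_atoms(frame, pair$chain_a, pair$resno_a)
  rb <- .residue_atoms(frame, pair$chain_b, pair$resno_b)
  if (nrow(ra) == 0 || nrow(rb) == 0)
    stop("uracil residue absent")
  uu <- rbind(ra, rb)
  fl <- do.call(rbind, lapply(list(pair$flank5, pair$flank3), function(fp)
    rbind(.residue_atoms(frame, fp$chain_a, fp$resno_a),
          .residue_atoms(frame, fp$chain_b, fp$resno_b))))
  list(uu = as.matrix(uu[, c("x", "y", "z")]),
       flank = as.matrix(fl[, c("x", "y", "z")]),
       uu_n = nrow(uu))
}

#' Cluster U-U conformations across trajectory frames
#'
#' Computes pairwise RMSD of one U-U pair's heavy atoms between all frames
#' (each frame first superposed on the flanking canonical pairs, so internal
#' pair motion rather than global drift drives the distances), then applies
#' average-linkage agglomerative clustering cut at `threshold`: merging stops
#' once the smallest inter-cluster average distance exceeds it.
#'
#' @param frames list of `rna_structure` trajectory frames.
#' @param pair_index which U-U pair (by [find_uu_pairs()] order in frame 1).
#' @param threshold cluster cut distance, Angstrom.
#' @return List of class `uu_clustering`: `labels` (cluster id per frame,
#'   1 = most populated), `populations` (data frame: cluster, n, fraction,
#'   centroid_frame), `distance` (the frame-frame RMSD matrix).
#' @export
cluster_uu_trajectory <- function(frames, pair_index = 1, threshold = 3.0) {
  if (length(frames) < 2) stop("need at least 2 frames")
  pairs <- find_uu_pairs(frames[[1]])
  if (pair_index > length(pairs))
    stop("frame 1 has only ", length(pairs), " U-U pair(s)")
  pair <- pairs[[pair_index]]
  coords <- lapply(seq_along(frames), function(i) {
    tryCatch(.uu_frame_coords(frames[[i]], pair),
             error = function(e)
               stop("U-U pair ", pair_index, " unresolvable in frame ",
                    i, ": ", conditionMessage(e)))
  })
  counts <- vapply(coords, `[[`, integer(1), "uu_n")
  if (length(unique(counts)) != 1)
    stop("U-U pair ", pair_index, " atom count differs across frames")
  m <- length(frames)
  D <- matrix(0, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    fit <- kabsch_superpose(coords[[j]]$flank, coords[[i]]$flank)
    uu_j <- sweep(coords[[j]]$uu %*% t(fit$rotation), 2, fit$translation, `+`)
    D[i, j] <- D[j, i] <- coord_rmsd(uu_j, coords[[i]]$uu)
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  labels <- stats::cutree(hc, h = threshold)
  # renumber by decreasing population
  sizes <- sort(table(labels), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- as.integer(relab[as.character(labels)])
  pops <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    idx <- which(labels == cl)
    cen <- idx[which.min(rowMeans(D[idx, idx, drop = FALSE]))]
    data.frame(cluster = cl, n = length(idx),
               fraction = length(idx) / m, centroid_frame = cen)
  }))
  structure(list(labels = labels, populations = pops, distance = D),
            class = "uu_clustering")
}

#' @export
print.uu_clustering <- function(x, ...) {
  cat("uu_clustering: ", nrow(x$populations), " cluster(s) over ",
      length(x$labels), " frames; fractions ",
      paste(round(x$populations$fraction, 3), collapse = "/"), "\n", sep = "")
  invisible(x)
}
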