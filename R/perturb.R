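# Targeted perturbation of a U-U pair toward one of the six types.

.BACKBONE_ATOMS <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                     "C3'", "O3'", "C2'", "O2'", "C1'")

.UU_TARGET_DISPLACEMENT <- c(minor = -1.5, none = 0, major = 1.5)

# rows of the atom table forming the movable base moiety of a residue
.moiety_rows <- function(structure, chain, resno) {
  which(structure$atoms$chain == chain & structure$atoms$resno == resno &
          !(structure$atoms$elety %in% .BACKBONE_ATOMS))
}

#' Perturb a U-U pair into a target type
#'
#' Rigidly repositions the two uracil base moieties (ring plus exocyclic
#' atoms; sugars and backbone stay fixed) so that the pair classifies as the
#' requested type. Two steps:
#' 1. an in-plane pose optimization of both bases (rotation about each
#'    glycosidic C1' plus a small translation, within the local pair plane)
#'    drives the imino/carbonyl candidate distances to the target
#'    hydrogen-bond pattern -- 2 bonds: both N3...O4 contacts at bond length;
#'    1 bond: the strand-b imino bond only, other candidates pushed out;
#'    0 bonds: every candidate pushed beyond the detection cutoff;
#' 2. a common translation of both moieties along the groove axis sets the
#'    centroid displacement to -1.5 / 0 / +1.5 A for minor / none / major
#'    inclination.
#' The result is re-classified and an error is raised if the target was not
#' reached. Perturbing a pair to the type it already holds is near enough a
#' no-op (sub-0.2 A moiety RMSD).
#'
#' @param structure an `rna_structure` duplex (builder-style idealized
#'   geometry).
#' @param target_type `"I"` ... `"VI"`.
#' @param pair_index which U-U pair (by [find_uu_pairs()] order).
#' @param bond_length target heavy-atom donor-acceptor distance, Angstrom.
#' @param dist_cutoff hydrogen-bond detection cutoff used for verification.
#' @return The perturbed `rna_structure`.
#' @export
perturb_uu <- function(structure, target_type, pair_index = 1,
                       bond_length = 2.85, dist_cutoff = 3.5) {
  target_type <- match.arg(target_type, .UU_TYPE_TABLE$type)
  trg <- .UU_TYPE_TABLE[.UU_TYPE_TABLE$type == target_type, ]
  pairs <- find_uu_pairs(structure)
  if (pair_index > length(pairs))
    stop("structure has only ", length(pairs), " U-U pair(s)")
  pair <- pairs[[pair_index]]

  # local pair frame: x along C1'a -> C1'b, y along the groove axis
  origin <- .pair_c1_mid(structure, pair)
  c1a <- .need_atom(structure, pair$chain_a, pair$resno_a, "C1'")
  c1b <- .need_atom(structure, pair$chain_b, pair$resno_b, "C1'")
  xhat <- (c1b - c1a) / sqrt(sum((c1b - c1a)^2))
  ghat <- .uu_groove_axis(structure, pair)
  ghat <- ghat - sum(ghat * xhat) * xhat
  ghat <- ghat / sqrt(sum(ghat^2))
  zhat <- c(xhat[2] * ghat[3] - xhat[3] * ghat[2],
            xhat[3] * ghat[1] - xhat[1] * ghat[3],
            xhat[1] * ghat[2] - xhat[2] * ghat[1])
  B <- cbind(xhat, ghat, zhat)
  to_local <- function(p) as.numeric(crossprod(B, p - origin))

  rows <- list(a = .moiety_rows(structure, pair$chain_a, pair$resno_a),
               b = .moiety_rows(structure, pair$chain_b, pair$resno_b))
  loc <- lapply(rows, function(r)
    t(apply(as.matrix(structure$atoms[r, c("x", "y", "z")]), 1, to_local)))
  for (side in names(loc))
    rownames(loc[[side]]) <- structure$atoms$elety[rows[[side]]]
  pivot <- list(a = to_local(c1a), b = to_local(c1b))

  # pose (tx, ty, theta): in-plane rotation about the residue's C1'
  apply_pose <- function(pts, pose, piv) {
    ct <- cos(pose[3]); st <- sin(pose[3])
    xy <- sweep(pts[, 1:2, drop = FALSE], 2, piv[1:2])
    xy <- cbind(xy[, 1] * ct - xy[, 2] * st, xy[, 1] * st + xy[, 2] * ct)
    cbind(sweep(xy, 2, piv[1:2] + pose[1:2], `+`), pts[, 3])
  }
  dst <- function(p, q) sqrt(sum((p - q)^2))
  hinge <- function(d, dmin) if (d < dmin) (dmin - d)^2 else 0
  glyco0 <- vapply(names(loc), function(s)
    dst(loc[[s]]["N1", ], pivot[[s]]), numeric(1))

  objective <- function(par) {
    pa <- apply_pose(loc$a, par[1:3], pivot$a)
    pb <- apply_pose(loc$b, par[4:6], pivot$b)
    cand <- c(aO2 = dst(pa["N3", ], pb["O2", ]),
              aO4 = dst(pa["N3", ], pb["O4", ]),
              bO2 = dst(pb["N3", ], pa["O2", ]),
              bO4 = dst(pb["N3", ], pa["O4", ]))
    v <- 0
    if (trg$n_hbonds == 2) {
      v <- v + (cand["aO4"] - bond_length)^2 + (cand["bO4"] - bond_length)^2 +
        hinge(cand["aO2"], 3.9) + hinge(cand["bO2"], 3.9)
    } else if (trg$n_hbonds == 1) {
      v <- v + (cand["bO4"] - bond_length)^2 +
        hinge(cand["aO2"], 3.9) + hinge(cand["aO4"], 3.9) +
        hinge(cand["bO2"], 3.9)
    } else {
      v <- v + sum(vapply(cand, hinge, numeric(1), dmin = 4.2))
    }
    # keep the rings apart (intended bonds sit above this floor)
    dall <- sqrt(outer(rowSums(pa^2), rowSums(pb^2), `+`) -
                   2 * pa %*% t(pb))
    v <- v + sum(vapply(dall[dall < 2.6], function(d) (2.6 - d)^2, numeric(1)))
    # glycosidic-bond and locality priors
    ga <- dst(pa["N1", ], pivot$a); gb <- dst(pb["N1", ], pivot$b)
    v + 5 * (ga - glyco0["a"])^2 + 5 * (gb - glyco0["b"])^2 +
      0.02 * sum(par[c(1, 2, 4, 5)]^2) + 0.01 * sum(par[c(3, 6)]^2)
  }
  fit <- stats::optim(rep(0, 6), objective, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  new_loc <- list(a = apply_pose(loc$a, fit$par[1:3], pivot$a),
                  b = apply_pose(loc$b, fit$par[4:6], pivot$b))

  out <- structure
  for (side in names(rows)) {
    glob <- sweep(new_loc[[side]] %*% t(B), 2, origin, `+`)
    out$atoms[rows[[side]], c("x", "y", "z")] <- glob
  }

  # groove translation of both moieties to the target displacement
  d0 <- uu_inclination(out, pair)$displacement
  shift <- (.UU_TARGET_DISPLACEMENT[[trg$inclination]] - d0) * ghat
  idx <- c(rows$a, rows$b)
  out$atoms[idx, c("x", "y", "z")] <-
    sweep(as.matrix(out$atoms[idx, c("x", "y", "z")]), 2, shift, `+`)

  got <- classify_uu(out, pair, dist_cutoff = dist_cutoff)
  if (got$type != target_type || got$atypical)
    stop("perturbation failed to reach type ", target_type, " (got ",
         got$type, if (got$atypical) ", atypical", "; ", got$n_hbonds,
         " bond(s), ", got$inclination, " inclination)")
  out
}
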