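# Idealized planar nucleobase templates and base-pair placement.
#
# Templates are built from regular-polygon ring geometry (hexagon side 1.38 A,
# pentagon side 1.38 A) with standard-length exocyclic bonds, in a 2D frame
# where the glycosidic nitrogen (N1 pyrimidine / N9 purine) sits at the origin,
# the glycosidic bond points along -y (C1' at (0, -1.47)), and the ring extends
# into +y. This is deliberately non-chemical, idealized geometry: good enough
# for coarse-grained node selection, elastic networks and hydrogen-bond /
# groove-displacement measurements, not for chemistry.

.GLYCOSIDIC_LEN <- 1.47
.RING_SIDE <- 1.38

# Hexagon vertex layout: vertex k at angle -90 + k*60 degrees around the
# centre, counter-clockwise, with vertex 0 at the origin.
.hexagon <- function() {
  r <- .RING_SIDE
  centre <- c(0, r)
  ang <- (-90 + 60 * 0:5) * pi / 180
  t(centre + r * rbind(cos(ang), sin(ang)))
}

.pentagon <- function() {
  s <- .RING_SIDE
  r <- s / (2 * sin(pi / 5))
  centre <- c(0, r)
  ang <- (-90 + 72 * 0:4) * pi / 180
  t(centre + r * rbind(cos(ang), sin(ang)))
}

# Place an exocyclic atom on ring atom `at`, pointing away from `centre`,
# at bond length `len`.
.exo <- function(at, centre, len) {
  d <- at - centre
  at + len * d / sqrt(sum(d^2))
}

# 2D template for one base: matrix with rownames = atom names, plus
# attributes: ring (names of ring atoms used for centroids), glyco (name of
# the glycosidic nitrogen).
.base_template_2d <- function(base) {
  if (base %in% c("U", "C")) {
    hx <- .hexagon()
    rownames(hx) <- c("N1", "C2", "N3", "C4", "C5", "C6")
    centre <- colMeans(hx)
    o2 <- .exo(hx["C2", ], centre, 1.22)
    x4 <- if (base == "U") .exo(hx["C4", ], centre, 1.22) else .exo(hx["C4", ], centre, 1.34)
    tmpl <- rbind(hx, O2 = o2)
    tmpl <- rbind(tmpl, if (base == "U") c(O4 = 1) else c(N4 = 1)) # placeholder
    tmpl[nrow(tmpl), ] <- x4
    rownames(tmpl)[nrow(tmpl)] <- if (base == "U") "O4" else "N4"
    ring <- rownames(hx)
    glyco <- "N1"
  } else if (base %in% c("A", "G")) {
    pent <- .pentagon()
    rownames(pent) <- c("N9", "C4", "C5", "N7", "C8")
    # fused six-ring sharing the C4-C5 edge, on the far side of the pentagon
    c4 <- pent["C4", ]; c5 <- pent["C5", ]
    mid <- (c4 + c5) / 2
    e <- (c5 - c4) / sqrt(sum((c5 - c4)^2))
    nrm <- c(e[2], -e[1])
    pc <- colMeans(pent[c("N9", "C4", "C5", "N7", "C8"), , drop = FALSE])
    if (sum((mid + nrm - pc)^2) < sum((mid - nrm - pc)^2)) nrm <- -nrm
    apothem <- .RING_SIDE * cos(pi / 6)
    o6c <- mid + apothem * nrm
    # six-ring vertices at radius RING_SIDE around o6c; C4 and C5 are two of
    # them; walk 60-degree steps from C4 away from C5
    a4 <- atan2(c4[2] - o6c[2], c4[1] - o6c[1])
    a5 <- atan2(c5[2] - o6c[2], c5[1] - o6c[1])
    step <- if (sin(a5 - a4) > 0) -pi / 3 else pi / 3 # go the other way round
    ang <- a4 + step * 1:4
    six <- t(o6c + .RING_SIDE * rbind(cos(ang), sin(ang)))
    rownames(six) <- c("N3", "C2", "N1", "C6")
    tmpl <- rbind(pent, six)
    if (base == "G") {
      tmpl <- rbind(tmpl,
        O6 = .exo(six["C6", ], o6c, 1.23),
        N2 = .exo(six["C2", ], o6c, 1.34))
    } else {
      tmpl <- rbind(tmpl, N6 = .exo(six["C6", ], o6c, 1.34))
    }
    ring <- c(rownames(pent), rownames(six))
    glyco <- "N9"
  } else {
    stop("unknown base: ", base)
  }
  structure(tmpl, ring = ring, glyco = glyco)
}

.base_ring_atoms <- function(base) {
  attr(.base_template_2d(base), "ring")
}

.glyco_atom <- function(base) {
  if (base %in% c("A", "G")) "N9" else "N1"
}

# rotate 2D points by theta (radians)
.rot2 <- function(pts, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  pts %*% t(R)
}

# Place a base template in the pair plane for strand A: C1' at c1, glycosidic
# bond direction at angle `lambda` (radians, measured from +x toward +y).
# Returns 2D coords incl. C1'.
.place_base_A <- function(base, c1 = c(-5.2, 0), lambda = 54.5 * pi / 180) {
  tmpl <- .base_template_2d(base)
  # template glyco N at origin, C1' direction -y; rotate so C1'->N maps to
  # (cos lambda, sin lambda): template C1'->N is +y, rotate by lambda - 90deg
  pts <- .rot2(rbind(tmpl, `C1'` = c(0, -.GLYCOSIDIC_LEN)), lambda - pi / 2)
  n_glyco <- pts[nrow(pts), ] # rotated C1' position relative to N at origin
  # translate so C1' lands at c1
  shift <- c1 - n_glyco
  pts <- sweep(pts, 2, shift, `+`)
  rownames(pts)[nrow(pts)] <- "C1'"
  structure(pts, ring = attr(tmpl, "ring"), glyco = attr(tmpl, "glyco"))
}

# Strand-B bases are related to a strand-A placement by the pair pseudo-dyad:
# a 180 degree rotation about the in-plane y axis through the pair midpoint,
# which in 2D (z = 0) is the reflection x -> -x (z -> -z is invisible for
# planar templates but makes the transform proper in 3D).
.mirror_x <- function(pts) {
  out <- pts
  out[, 1] <- -out[, 1]
  out
}

# Hydrogen-bond anchor targets (heavy-atom donor-acceptor distances, A) per
# pair type; names are "atomA-atomB".
.pair_anchors <- function(baseA, baseB) {
  key <- paste0(baseA, baseB)
  switch(key,
    GC = c("N1-N3" = 2.93, "O6-N4" = 2.91, "N2-O2" = 2.86),
    CG = c("N3-N1" = 2.93, "N4-O6" = 2.91, "O2-N2" = 2.86),
    AU = c("N1-N3" = 2.82, "N6-O4" = 2.95),
    UA = c("N3-N1" = 2.82, "O4-N6" = 2.95),
    # stretched U-U wobble: single H-bond, imino N3 of the second residue to
    # carbonyl O4 of the first
    UU = c("O4-N3" = 2.85),
    stop("unsupported base pair: ", baseA, "-", baseB)
  )
}

# candidate donor->acceptor contacts that must stay open (> cutoff) for the
# default stretched U-U wobble to carry exactly one hydrogen bond
.uu_wobble_avoid <- c("O2-N3" = 0, "N3-O2" = 0, "N3-O4" = 0)

# Optimize the in-plane pose (tx, ty, theta) of base B against base A so the
# anchor distances are met, the B C1' stays near its canonical backbone
# position, and heavy atoms do not clash. Returns the placed 2D coords of B.
.place_base_B <- function(baseA_pts, baseB, anchors,
                          c1B_target = c(5.2, 0), c1c1 = 10.4,
                          avoid = NULL, avoid_min = 4.0,
                          clash_min = 2.6) {
  tmplB0 <- .place_base_A(baseB, c1 = c(-5.2, 0))
  tmplB0 <- .mirror_x(tmplB0) # canonical start: dyad image of an A placement
  ringB <- attr(tmplB0, "ring")
  heavyA <- baseA_pts[setdiff(rownames(baseA_pts), "C1'"), , drop = FALSE]

  pose <- function(par) {
    ctr <- colMeans(tmplB0)
    pts <- .rot2(sweep(unclass(tmplB0), 2, ctr), par[3])
    sweep(pts, 2, ctr + par[1:2], `+`)
  }
  obj <- function(par) {
    pts <- pose(par)
    rownames(pts) <- rownames(tmplB0)
    val <- 0
    for (nm in names(anchors)) {
      ab <- strsplit(nm, "-", fixed = TRUE)[[1]]
      d <- sqrt(sum((baseA_pts[ab[1], ] - pts[ab[2], ])^2))
      val <- val + (d - anchors[[nm]])^2
    }
    # keep the backbone attachment near its canonical position (soft) and the
    # C1'-C1' separation at the A-form value (firm)
    val <- val + 0.02 * sum((pts["C1'", ] - c1B_target)^2)
    dcc <- sqrt(sum((baseA_pts["C1'", ] - pts["C1'", ])^2))
    val <- val + 0.5 * (dcc - c1c1)^2
    # anchors that must stay broken
    if (!is.null(avoid)) {
      for (nm in names(avoid)) {
        ab <- strsplit(nm, "-", fixed = TRUE)[[1]]
        d <- sqrt(sum((baseA_pts[ab[1], ] - pts[ab[2], ])^2))
        val <- val + max(0, avoid_min - d)^2
      }
    }
    # steric hinge: no inter-base heavy-atom pair below clash_min
    hB <- pts[setdiff(rownames(pts), "C1'"), , drop = FALSE]
    dmat <- sqrt(outer(rowSums(heavyA^2), rowSums(hB^2), `+`) -
                   2 * heavyA %*% t(hB))
    val + sum(pmax(0, clash_min - dmat)^2)
  }
  fit <- stats::optim(c(0, 0, 0), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  pts <- pose(fit$par)
  rownames(pts) <- rownames(tmplB0)
  structure(pts, ring = ringB, glyco = attr(tmplB0, "glyco"),
            objective = fit$value)
}
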