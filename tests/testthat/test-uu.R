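test_that("the capped (CUG)2 duplex has two flanked U-U pairs", {
  s <- build_cug_duplex(2, cap = "GC")
  pairs <- find_uu_pairs(s)
  expect_length(pairs, 2)
  expect_equal(vapply(pairs, `[[`, integer(1), "position"), c(3L, 6L))
})

test_that("a pure Watson-Crick duplex has no U-U pairs", {
  # the builder pairs U with U, so a U-free strand gives pure Watson-Crick
  expect_length(find_uu_pairs(build_aform_duplex("GGCAGCC")), 0)
})

test_that("an uncapped (CUG)6 duplex has six U-U pairs", {
  expect_length(find_uu_pairs(build_cug_duplex(6)), 6)
})

test_that("the builder wobble carries one imino hydrogen bond", {
  s <- build_cug_duplex(2, cap = "GC")
  p <- find_uu_pairs(s)[[1]]
  hb <- detect_uu_hbonds(s, p)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor, "N3")
  expect_equal(hb$acceptor, "O4")
  expect_lt(hb$distance, 3.2)
  # shrinking the cutoff below the bond length removes it
  expect_equal(nrow(detect_uu_hbonds(s, p, dist_cutoff = 2.5)), 0)
})

test_that("hydrogen-bond detection errors on missing base atoms", {
  s <- build_cug_duplex(2, cap = "GC")
  p <- find_uu_pairs(s)[[1]]
  s$atoms <- s$atoms[!(s$atoms$chain == p$chain_a &
                         s$atoms$resno == p$resno_a &
                         s$atoms$elety == "O4"), ]
  expect_error(detect_uu_hbonds(s, p), "O4")
})

test_that("C1'-C1' distances are near-A-form and rigid-invariant", {
  s <- build_cug_duplex(2, cap = "GC")
  p <- find_uu_pairs(s)[[1]]
  d <- c1c1_distance(s, p)
  expect_gt(d, 9.5); expect_lt(d, 11)
  flank <- p$flank5
  expect_equal(c1c1_distance(s, flank), 10.4, tolerance = 0.15)
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- transform_structure(s, rotation = R, translation = c(9, -4, 2))
  expect_equal(c1c1_distance(moved, p), d, tolerance = 1e-10)
})

test_that("inclination is zero on the builder and tracks groove shifts", {
  s <- build_cug_duplex(2, cap = "GC")
  p <- find_uu_pairs(s)[[1]]
  inc <- uu_inclination(s, p)
  expect_equal(inc$label, "none")
  expect_lt(abs(inc$displacement), 1e-9)
  # translate both uracil bases along the measured groove axis
  g <- rcugdyn:::.uu_groove_axis(s, p)
  shift_both <- function(s, delta) {
    idx <- c(rcugdyn:::.moiety_rows(s, p$chain_a, p$resno_a),
             rcugdyn:::.moiety_rows(s, p$chain_b, p$resno_b))
    s$atoms[idx, c("x", "y", "z")] <-
      sweep(as.matrix(s$atoms[idx, c("x", "y", "z")]), 2, delta * g, `+`)
    s
  }
  expect_equal(uu_inclination(shift_both(s, 1.5), p)$label, "major")
  expect_equal(uu_inclination(shift_both(s, -1.5), p)$label, "minor")
  expect_equal(uu_inclination(shift_both(s, 1.5), p)$displacement, 1.5,
               tolerance = 1e-6)
})

test_that("terminal pairs without flanks have no groove frame", {
  s <- build_cug_duplex(2, cap = "GC")
  p <- find_uu_pairs(s)[[1]]
  p$flank5 <- NULL
  expect_error(uu_inclination(s, p), "flank")
})

test_that("the type table maps exactly and off-table input is atypical", {
  tab <- rcugdyn:::.UU_TYPE_TABLE
  expect_equal(tab$type[tab$n_hbonds == 2 & tab$inclination == "minor"], "I")
  expect_equal(tab$type[tab$n_hbonds == 1 & tab$inclination == "minor"], "II")
  expect_equal(tab$type[tab$n_hbonds == 0 & tab$inclination == "none"], "III")
  expect_equal(tab$type[tab$n_hbonds == 1 & tab$inclination == "major"], "IV")
  expect_equal(tab$type[tab$n_hbonds == 2 & tab$inclination == "major"], "V")
  expect_equal(tab$type[tab$n_hbonds == 0 & tab$inclination == "major"], "VI")
  # builder wobble is (1 bond, none): off-table, coerced, flagged
  s <- build_cug_duplex(2, cap = "GC")
  cl <- classify_uu(s, find_uu_pairs(s)[[1]])
  expect_equal(cl$n_hbonds, 1L)
  expect_equal(cl$inclination, "none")
  expect_true(cl$atypical)
  expect_true(cl$type %in% c("II", "IV"))
})

test_that("perturbing to the held type is nearly a no-op", {
  s <- build_cug_duplex(2, cap = "GC")
  r1 <- perturb_uu(s, "IV")
  r2 <- perturb_uu(r1, "IV")
  d <- as.matrix(r1$atoms[, c("x", "y", "z")]) -
    as.matrix(r2$atoms[, c("x", "y", "z")])
  expect_lt(sqrt(mean(rowSums(d^2))), 0.2)
})

test_that("perturbation touches only the chosen pair's bases", {
  s <- build_cug_duplex(2, cap = "GC")
  r <- perturb_uu(s, "I", pair_index = 1)
  pairs <- find_uu_pairs(s)
  moved <- which(rowSums(abs(as.matrix(r$atoms[, c("x", "y", "z")]) -
                               as.matrix(s$atoms[, c("x", "y", "z")]))) > 1e-9)
  allowed <- c(rcugdyn:::.moiety_rows(s, pairs[[1]]$chain_a,
                                      pairs[[1]]$resno_a),
               rcugdyn:::.moiety_rows(s, pairs[[1]]$chain_b,
                                      pairs[[1]]$resno_b))
  expect_true(all(moved %in% allowed))
  cl2 <- classify_uu(r, pairs[[2]])
  expect_equal(cl2$n_hbonds, 1L) # second pair untouched
})

test_that("identical frames collapse to one cluster", {
  s <- build_cug_duplex(2, cap = "GC")
  cl <- cluster_uu_trajectory(rep(list(s), 5), pair_index = 1)
  expect_equal(nrow(cl$populations), 1)
  expect_equal(cl$populations$fraction, 1)
})

test_that("a huge threshold always merges to one cluster", {
  s <- build_cug_duplex(2, cap = "GC")
  frames <- list(s, perturb_uu(s, "I"), perturb_uu(s, "VI"))
  cl <- cluster_uu_trajectory(frames, threshold = 1e6)
  expect_equal(nrow(cl$populations), 1)
})

test_that("clustering errors when the pair is unresolvable in a frame", {
  s <- build_cug_duplex(2, cap = "GC")
  p <- find_uu_pairs(s)[[1]]
  broken <- s
  broken$atoms <- broken$atoms[!(broken$atoms$chain == p$chain_a &
                                   broken$atoms$resno == p$resno_a), ]
  expect_error(cluster_uu_trajectory(list(s, broken)), "frame 2")
})
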