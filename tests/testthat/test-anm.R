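test_that("force-constant laws behave as documented", {
  fc <- force_constant("exponential")
  expect_equal(gamma_of_r(3.0, fc), 12)
  # decays to about 0.1 by 25 A (evaluated without the hard cutoff)
  far <- force_constant("exponential", cutoff = 30)
  expect_equal(gamma_of_r(25, far), 12 * exp(-22 / 4.6), tolerance = 1e-12)
  expect_lt(gamma_of_r(25, far), 0.11)
  expect_equal(gamma_of_r(10, fc), 0) # beyond 9 A cutoff
  fu <- force_constant("uniform", gamma0 = 2, cutoff = 8)
  expect_equal(gamma_of_r(c(1, 7.9, 8.1), fu), c(2, 2, 0))
  expect_error(gamma_of_r(0, fc), "positive")
  expect_true(all(gamma_of_r(seq(0.5, 40, by = 0.5), fc) >= 0))
})

test_that("two-node spring has the textbook spectrum", {
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0))
  fc <- force_constant("uniform", gamma0 = 1, cutoff = 5)
  H <- build_hessian(xyz, fc)
  ev <- eigen(H$values, symmetric = TRUE)$values
  expect_equal(sort(ev)[1:5], rep(0, 5), tolerance = 1e-12)
  expect_equal(max(ev), 2, tolerance = 1e-12) # gamma (m1 + m2)/m1m2 pattern
})

test_that("Hessian rows sum to zero and the matrix is symmetric", {
  for (law in c("uniform", "exponential")) {
    fc <- force_constant(law, cutoff = 9)
    H <- build_hessian(fixture_nodes(), fc)$values
    expect_lt(max(abs(H - t(H))), 1e-12)
    n <- nrow(H) / 3
    rs <- matrix(0, 3, 3)
    for (i in seq_len(n)) # block-row sums vanish by translational invariance
      rs <- rs + H[1:3, (3 * i - 2):(3 * i)]
    expect_lt(max(abs(rs)), 1e-10)
  }
})

test_that("solve_modes drops exactly six rigid-body modes", {
  md <- fixture_modes()
  n <- nrow(fixture_nodes()$xyz)
  expect_equal(md$n_dropped, 6L)
  expect_length(md$values, 3 * n - 6)
  expect_true(all(md$values > 0))
  expect_false(is.unsorted(md$values))
  # orthonormal retained modes
  G <- crossprod(md$vectors[, 1:10])
  expect_lt(max(abs(G - diag(10))), 1e-9)
})

test_that("disconnected networks are rejected with guidance", {
  xyz <- rbind(matrix(rnorm(15), 5, 3),
               matrix(rnorm(15), 5, 3) + 100)
  fc <- force_constant("uniform", cutoff = 9)
  expect_error(solve_modes(build_hessian(xyz, fc)), "cutoff")
  far <- rbind(c(0, 0, 0), c(50, 0, 0))
  expect_error(build_hessian(far, fc), "disconnected")
})

test_that("covariance is the pseudo-inverse of the Hessian", {
  set.seed(8)
  xyz <- random_connected_nodes(12)
  fc <- force_constant("exponential", cutoff = 9)
  h <- build_hessian(xyz, fc)
  md <- solve_modes(h)
  C <- anm_covariance(md)
  # H C = I - P_rigid
  P <- tcrossprod(rcugdyn:::.rigid_body_basis(xyz))
  expect_lt(max(abs(h$values %*% C - (diag(36) - P))), 1e-8)
  expect_equal(sum(diag(C)), sum(1 / md$values), tolerance = 1e-10)
})

test_that("network potential is invariant to rigid motion", {
  nd <- fixture_nodes()
  fc <- force_constant("exponential", cutoff = 9)
  th <- 0.3
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  moved <- sweep(nd$xyz %*% t(R), 2, c(5, 5, 5), `+`)
  expect_equal(anm_potential(moved, nd$xyz, fc), 0, tolerance = 1e-9)
  stretched <- nd$xyz * 1.01
  expect_gt(anm_potential(stretched, nd$xyz, fc), 0)
})
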