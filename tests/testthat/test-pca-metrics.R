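test_that("PCA reproduces a hand-computed covariance eigendecomposition", {
  nd <- fixture_nodes()
  set.seed(9)
  m <- 40
  X <- matrix(rnorm(m * 3 * nrow(nd$xyz), sd = 0.5), m)
  ens <- rna_ensemble(sweep(X, 2, as.numeric(t(nd$xyz)), `+`), nd$labels,
                      aligned = TRUE)
  pc <- pca_modes(ens)
  Cs <- stats::cov(ens$xyz) # divisor m - 1
  ev <- eigen(Cs, symmetric = TRUE)
  k <- length(pc$modes$values)
  expect_equal(pc$modes$values, ev$values[seq_len(k)], tolerance = 1e-8)
  for (j in 1:5)
    expect_equal(abs(sum(pc$modes$vectors[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-8)
  expect_equal(sum(pc$spectrum$fraction), 1, tolerance = 1e-12)
  # at most m - 1 nonzero components from m conformers
  expect_lte(k, m - 1)
})

test_that("PCA refuses unaligned or tiny ensembles", {
  nd <- fixture_nodes()
  X <- matrix(rnorm(4 * 3 * nrow(nd$xyz)), 4)
  expect_error(pca_modes(rna_ensemble(X, nd$labels, aligned = FALSE)),
               "align")
  expect_error(pca_modes(rna_ensemble(X[1:2, ], nd$labels, aligned = TRUE)),
               "at least 3")
})

test_that("RMSF matches the direct per-node formula and subsets filter", {
  nd <- fixture_nodes()
  set.seed(10)
  X <- sweep(matrix(rnorm(20 * 3 * nrow(nd$xyz), sd = 0.4), 20), 2,
             as.numeric(t(nd$xyz)), `+`)
  ens <- rna_ensemble(X, nd$labels, aligned = TRUE)
  prof <- rmsf_profile(ens)
  dev <- sweep(X, 2, colMeans(X))
  msf <- colMeans(dev^2)
  direct <- sqrt(rowSums(matrix(msf, ncol = 3, byrow = TRUE)))
  expect_equal(prof$rmsf, direct, tolerance = 1e-12)
  pp <- rmsf_profile(ens, "P")
  expect_true(all(pp$elety == "P"))
  expect_equal(nrow(pp), sum(nd$labels$elety == "P"))
})

test_that("subsampling picks endpoints and equally spaced frames", {
  nd <- fixture_nodes()
  L <- 11
  X <- sweep(matrix(rnorm(L * 3 * nrow(nd$xyz), sd = 0.1), L), 2,
             as.numeric(t(nd$xyz)), `+`)
  traj <- rna_ensemble(X, nd$labels, aligned = FALSE)
  sub <- subsample_frames(traj, n = 3) # indices 1, 6, 11
  expect_equal(n_conformers(sub), 3)
  expect_true(sub$aligned)
  expect_warning(subsample_frames(traj, n = 50), "keeping all")
})

test_that("overlap metrics match brute-force summation", {
  set.seed(11)
  D <- 30
  A <- qr.Q(qr(matrix(rnorm(D * 6), D)))
  B <- qr.Q(qr(matrix(rnorm(D * 6), D)))
  # cumulative overlap
  target <- A[, 1]
  co_brute <- sqrt(sum(vapply(1:6, function(j) sum(target * B[, j])^2,
                              numeric(1))))
  mb <- mode_set(rep(1, 6), B, kind = "ANM")
  expect_equal(cumulative_overlap(target, mb, J = 6), co_brute,
               tolerance = 1e-12)
  # subspace overlap, symmetric
  ma <- mode_set(rep(1, 6), A, kind = "ANM")
  so_brute <- sqrt(sum(outer(1:3, 1:3, Vectorize(function(i, j)
    sum(A[, i] * B[, j])^2))) / 3)
  expect_equal(subspace_overlap(ma, mb, K = 3), so_brute, tolerance = 1e-12)
  expect_equal(subspace_overlap(ma, mb, K = 3), subspace_overlap(mb, ma, K = 3),
               tolerance = 1e-12)
  # identical subspaces -> 1; orthogonal -> 0
  expect_equal(subspace_overlap(ma, ma, K = 6), 1, tolerance = 1e-12)
  C <- cbind(A[, 1:3], B[, 1:3])
  Q <- qr.Q(qr(C))
  m1 <- mode_set(rep(1, 3), Q[, 1:3], kind = "ANM")
  m2 <- mode_set(rep(1, 3), Q[, 4:6], kind = "ANM")
  expect_equal(subspace_overlap(m1, m2, K = 3), 0, tolerance = 1e-10)
})

test_that("collectivity attains its exact bounds", {
  N <- 25
  uniform <- rep(1 / sqrt(3 * N), 3 * N)
  expect_equal(collectivity(uniform), 1, tolerance = 1e-14)
  single <- c(1, rep(0, 3 * N - 1))
  expect_equal(collectivity(single), 1 / N, tolerance = 1e-14)
  set.seed(12)
  u <- rnorm(3 * N); u <- u / sqrt(sum(u^2))
  k <- collectivity(u)
  expect_gte(k, 1 / N); expect_lte(k, 1)
})

test_that("fluctuation correlation checks subsets and degenerate input", {
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8.5)
  expect_equal(fluctuation_correlation(a, b), stats::cor(a, b))
  expect_error(fluctuation_correlation(a, rep(1, 4)), "variance")
  expect_error(fluctuation_correlation(a, b[1:3]), "length")
})

test_that("projections of the generating ensemble have the PCA variances", {
  nd <- fixture_nodes()
  set.seed(13)
  X <- sweep(matrix(rnorm(50 * 3 * nrow(nd$xyz), sd = 0.3), 50), 2,
             as.numeric(t(nd$xyz)), `+`)
  ens <- rna_ensemble(X, nd$labels, aligned = TRUE)
  pc <- pca_modes(ens)
  proj <- project_ensemble(ens, pc, k = 3, superpose = FALSE)
  expect_equal(apply(proj, 2, stats::var), pc$modes$values[1:3],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(colMeans(proj), c(0, 0, 0), tolerance = 1e-10,
               ignore_attr = TRUE)
})
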