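test_that("deforming along a unit mode gives the exact RMSD", {
  nd <- fixture_nodes()
  md <- fixture_modes()
  N <- nrow(nd$xyz)
  out <- deform_along_mode(nd, md$vectors[, 1], amplitude = 3)
  expect_equal(coord_rmsd(out$xyz, nd$xyz), 3 / sqrt(N), tolerance = 1e-12)
  expect_error(deform_along_mode(nd, md$vectors[1:9, 1], 1), "match")
})

test_that("sampled conformers hit the target RMSD scale and are seeded", {
  nd <- fixture_nodes()
  md <- fixture_modes()
  e1 <- sample_conformers(nd, md, n = 400, target_rmsd = 2, seed = 21)
  e2 <- sample_conformers(nd, md, n = 400, target_rmsd = 2, seed = 21)
  e3 <- sample_conformers(nd, md, n = 400, target_rmsd = 2, seed = 22)
  expect_identical(e1$xyz, e2$xyz)
  expect_gt(max(abs(e1$xyz - e3$xyz)), 0.01)
  ref <- as.numeric(t(nd$xyz))
  rmsd2 <- rowMeans(sweep(e1$xyz, 2, ref)^2) * 3
  expect_equal(sqrt(mean(rmsd2)), 2, tolerance = 0.15)
})

test_that("conformer coefficients follow the 1/lambda amplitude law", {
  nd <- fixture_nodes()
  md <- fixture_modes()
  ens <- sample_conformers(nd, md, mode_indices = 1:3, n = 3000,
                           target_rmsd = 2, seed = 23)
  ref <- as.numeric(t(nd$xyz))
  dev <- sweep(ens$xyz, 2, ref)
  cvar <- apply(dev %*% md$vectors[, 1:3], 2, stats::var)
  expect_equal(cvar[2] / cvar[1], md$values[1] / md$values[2],
               tolerance = 0.1)
  expect_equal(cvar[3] / cvar[1], md$values[1] / md$values[3],
               tolerance = 0.1)
})

test_that("gaussian_model validates its inputs", {
  nd <- fixture_nodes()
  D <- 3 * nrow(nd$xyz)
  set.seed(24)
  Q <- qr.Q(qr(matrix(rnorm(D * 2), D)))
  expect_s3_class(gaussian_model(nd, Q, c(5, 2), noise = 0.1),
                  "gaussian_model")
  expect_error(gaussian_model(nd, Q * 2, c(5, 2)), "orthonormal")
  expect_error(gaussian_model(nd, Q, c(2, 5)), "non-increasing")
  expect_error(gaussian_model(nd, Q, c(5, -1)), "positive")
  expect_error(gaussian_model(nd, Q, c(5, 2), noise = -1), "non-negative")
})

test_that("model_from_fractions reproduces its spectrum in population", {
  nd <- fixture_nodes()
  f <- c(0.4, 0.2, 0.1)
  gm <- model_from_fractions(nd, fractions = f, total_variance = 30)
  D <- 3 * nrow(nd$xyz)
  # population covariance eigenvalues: sigma_k + tau2 on signals, tau2 off
  lead <- gm$variances + gm$noise
  total <- sum(lead) + (D - 3) * gm$noise
  expect_equal(total, 30, tolerance = 1e-10)
  expect_equal(lead / total, f, tolerance = 1e-12)
  expect_error(model_from_fractions(nd, fractions = c(0.5, 0.4, 0.2)),
               "sum")
})

test_that("synthetic trajectories round trip through PDB at format precision", {
  nd <- fixture_nodes()
  gm <- model_from_fractions(nd, total_variance = 20)
  path <- withr::local_tempfile(fileext = ".pdb")
  tr <- synthetic_trajectory(gm, path, n_frames = 12, seed = 25,
                             drift_amplitude = 2)
  frames <- suppressMessages(read_rna_pdb(path))
  expect_length(frames, 12)
  back <- suppressMessages(select_nodes(frames[[5]], cg_scheme("CG2")))
  expect_lt(max(abs(as.numeric(t(back$xyz)) - tr$xyz[5, ])), 5e-4 + 1e-12)
  expect_false(tr$aligned) # drift breaks the aligned flag
})
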