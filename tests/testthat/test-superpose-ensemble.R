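test_that("Kabsch superposition recovers a known rigid transform", {
  set.seed(4)
  ref <- matrix(rnorm(30, sd = 5), 10, 3)
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  mob <- sweep(ref %*% t(R), 2, c(3, -2, 7), `+`)
  fit <- kabsch_superpose(mob, ref)
  expect_lt(fit$rmsd, 1e-10)
  expect_lt(max(abs(fit$xyz - ref)), 1e-10)
  # the returned transform maps mobile onto reference
  expect_lt(max(abs(sweep(mob %*% t(fit$rotation), 2, fit$translation, `+`) -
                      ref)), 1e-10)
})

test_that("superposition never produces a reflection", {
  set.seed(5)
  ref <- matrix(rnorm(24), 8, 3)
  mob <- ref %*% diag(c(-1, 1, 1)) # mirrored copy
  fit <- kabsch_superpose(mob, ref)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0.1)
})

test_that("iterative alignment converges to a superposition fixed point", {
  nd <- fixture_nodes()
  set.seed(6)
  conformers <- lapply(1:8, function(i) {
    out <- nd
    out$xyz <- nd$xyz + matrix(rnorm(length(nd$xyz), sd = 0.3),
                               nrow(nd$xyz), 3)
    # random rigid contamination
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, pi)
    K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]),
               c(-ax[2], ax[1], 0))
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    out$xyz <- sweep(out$xyz %*% t(R), 2, rnorm(3, sd = 10), `+`)
    out
  })
  ens <- align_ensemble(conformers)
  expect_true(ens$aligned)
  mean_xyz <- ensemble_mean(ens)
  for (i in seq_len(n_conformers(ens))) {
    xi <- matrix(ens$xyz[i, ], ncol = 3, byrow = TRUE)
    fit <- kabsch_superpose(xi, mean_xyz)
    expect_lt(coord_rmsd(fit$xyz, xi), 1e-5) # already at the fixed point
  }
})

test_that("aligned ensembles are invariant to rigid pre-transforms", {
  nd <- fixture_nodes()
  set.seed(7)
  conformers <- lapply(1:5, function(i) {
    out <- nd
    out$xyz <- nd$xyz + matrix(rnorm(length(nd$xyz), sd = 0.2),
                               nrow(nd$xyz), 3)
    out
  })
  moved <- lapply(conformers, function(cf) {
    cf$xyz <- sweep(cf$xyz, 2, c(100, -50, 20), `+`)
    cf
  })
  e1 <- align_ensemble(conformers)
  e2 <- align_ensemble(moved)
  # identical up to one global rigid transform of the whole aligned set
  fit <- kabsch_superpose(ensemble_mean(e2), ensemble_mean(e1))
  for (i in seq_len(n_conformers(e1))) {
    xi <- matrix(e2$xyz[i, ], ncol = 3, byrow = TRUE)
    xi <- sweep(xi %*% t(fit$rotation), 2, fit$translation, `+`)
    expect_lt(coord_rmsd(xi, matrix(e1$xyz[i, ], ncol = 3, byrow = TRUE)),
              1e-6)
  }
})

test_that("ensembles reject mismatched node labels", {
  nd <- fixture_nodes()
  other <- nd
  other$labels$resno <- other$labels$resno + 1
  expect_error(align_ensemble(list(nd, other)), "label")
})
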