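# Shared fixtures and independent numeric oracles.

# independent central-difference Hessian of the network potential
numeric_hessian <- function(xyz, fc, h = 1e-4) {
  n3 <- 3 * nrow(xyz)
  H <- matrix(0, n3, n3)
  flat <- as.numeric(t(xyz))
  V <- function(f) anm_potential(matrix(f, ncol = 3, byrow = TRUE), xyz, fc)
  for (i in seq_len(n3)) for (j in i:n3) {
    fpp <- flat; fpp[i] <- fpp[i] + h; fpp[j] <- fpp[j] + h
    fpm <- flat; fpm[i] <- fpm[i] + h; fpm[j] <- fpm[j] - h
    fmp <- flat; fmp[i] <- fmp[i] - h; fmp[j] <- fmp[j] + h
    fmm <- flat; fmm[i] <- fmm[i] - h; fmm[j] <- fmm[j] - h
    H[i, j] <- H[j, i] <- (V(fpp) - V(fpm) - V(fmp) + V(fmm)) / (4 * h^2)
  }
  H
}

# random connected node cloud: each point lands within reach of an earlier one
random_connected_nodes <- function(n, reach = 6) {
  xyz <- matrix(0, n, 3)
  for (i in 2:n) {
    anchor <- xyz[sample.int(i - 1, 1), ]
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    xyz[i, ] <- anchor + stats::runif(1, 2.5, reach * 0.9) * dir
  }
  xyz
}

# memoized standard fixtures (built once per test run)
.fix <- new.env()

fixture_duplex <- function() {
  if (is.null(.fix$duplex))
    .fix$duplex <- build_cug_duplex(3, cap = "GC")
  .fix$duplex
}

fixture_nodes <- function(scheme = "CG2") {
  key <- paste0("nodes_", scheme)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- suppressMessages(
      select_nodes(fixture_duplex(), cg_scheme(scheme)))
  .fix[[key]]
}

fixture_modes <- function() {
  if (is.null(.fix$modes))
    .fix$modes <- solve_modes(build_hessian(
      fixture_nodes(), force_constant("exponential", cutoff = 9)))
  .fix$modes
}
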