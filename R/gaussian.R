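# Gaussian generative models for synthetic ensembles and trajectories.

#' Gaussian generative model over a reference structure
#'
#' Defines a distribution `x = x_ref + sum_k z_k sqrt(sigma_k) d_k + eps`
#' with independent standard normal `z_k`, orthonormal signal directions
#' `d_k`, per-direction variances `sigma_k`, and isotropic noise `eps` of
#' per-coordinate variance `noise`. The population covariance is
#' `sum sigma_k d_k d_k^T + noise * I`, so PCA on a large sample recovers the
#' directions and, through the variance fractions, the prescribed spectrum.
#'
#' @param reference a `node_set` (defines the mean and the labels).
#' @param directions 3N x K matrix of orthonormal columns.
#' @param variances K signal variances (A^2), positive, non-increasing.
#' @param noise isotropic per-coordinate variance (A^2), non-negative.
#' @return A list of class `gaussian_model`.
#' @export
gaussian_model <- function(reference, directions, variances, noise = 0) {
  if (!inherits(reference, "node_set")) stop("reference must be a node_set")
  D <- 3 * nrow(reference$xyz)
  directions <- as.matrix(directions)
  if (nrow(directions) != D)
    stop("directions must have ", D, " rows")
  if (ncol(directions) != length(variances))
    stop("one variance per direction required")
  G <- crossprod(directions)
  if (max(abs(G - diag(ncol(directions)))) > 1e-8)
    stop("direction columns are not orthonormal")
  if (any(variances <= 0)) stop("variances must be positive")
  if (is.unsorted(rev(variances))) stop("variances must be non-increasing")
  if (noise < 0) stop("noise variance must be non-negative")
  structure(list(reference = reference, directions = directions,
                 variances = variances, noise = noise),
            class = "gaussian_model")
}

#' @export
print.gaussian_model <- function(x, ...) {
  cat("gaussian_model: ", ncol(x$directions), " signal direction(s) over ",
      nrow(x$reference$xyz), " nodes; variances ",
      paste(signif(x$variances, 4), collapse = "/"),
      " A^2, noise ", signif(x$noise, 4), " A^2\n", sep = "")
  invisible(x)
}

#' Gaussian model with prescribed leading variance fractions
#'
#' Chooses signal variances and the isotropic noise floor so that the
#' population PCA spectrum has exactly the requested leading fractions.
#' With total variance `T`, dimension `D = 3N` and fractions `f_k`, the
#' noise eigenvalue repeated on the `D - K` residual dimensions is
#' `tau^2 = T (1 - sum f) / (D - K)` and each signal eigenvalue is
#' `T f_k = sigma_k + tau^2`, i.e. `sigma_k = T f_k - tau^2` (which must stay
#' positive, so each fraction must exceed the residual share).
#'
#' @param reference a `node_set`.
#' @param fractions leading variance fractions, in (0, 1), non-increasing,
#'   summing to less than 1.
#' @param directions 3N x K orthonormal signal directions; by default drawn
#'   reproducibly at random (QR of a standard normal matrix) using `seed`.
#' @param total_variance total population variance `T` (A^2).
#' @param seed seed for the default random directions.
#' @return A `gaussian_model`.
#' @export
model_from_fractions <- function(reference, fractions = c(0.432, 0.229, 0.139),
                                 directions = NULL, total_variance = 50,
                                 seed = 20160325) {
  K <- length(fractions)
  D <- 3 * nrow(reference$xyz)
  if (K >= D) stop("more fractions than dimensions")
  if (any(fractions <= 0) || sum(fractions) >= 1)
    stop("fractions must be positive and sum to less than 1")
  if (is.unsorted(rev(fractions))) stop("fractions must be non-increasing")
  tau2 <- total_variance * (1 - sum(fractions)) / (D - K)
  sig <- total_variance * fractions - tau2
  if (any(sig <= 0))
    stop("fractions too close to the residual share: noise eigenvalue ",
         signif(tau2, 4), " exceeds a signal eigenvalue")
  if (is.null(directions)) {
    set.seed(seed)
    directions <- qr.Q(qr(matrix(stats::rnorm(D * K), D, K)))
  }
  gaussian_model(reference, directions, sig, noise = tau2)
}

#' Sample an ensemble from a Gaussian model
#'
#' @param model a `gaussian_model`.
#' @param n number of conformers.
#' @param seed integer seed; the same seed reproduces the sample exactly.
#' @return An `rna_ensemble` flagged aligned (the model adds no rigid-body
#'   motion beyond its isotropic noise), source `"gaussian-model"`.
#' @export
gaussian_ensemble <- function(model, n = 2000, seed = 1) {
  if (!inherits(model, "gaussian_model")) stop("need a gaussian_model")
  stopifnot(n >= 1)
  D <- nrow(model$directions); K <- ncol(model$directions)
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * K), n, K)
  X <- Z %*% (t(model$directions) * sqrt(model$variances))
  if (model$noise > 0)
    X <- X + matrix(stats::rnorm(n * D, sd = sqrt(model$noise)), n, D)
  base <- .coords_to_row(model$reference$xyz)
  rna_ensemble(sweep(X, 2, base, `+`), model$reference$labels,
               aligned = TRUE, source = "gaussian-model")
}

#' Write a synthetic multi-model trajectory
#'
#' Draws `n_frames` frames from a Gaussian model, optionally superimposes a
#' slow sinusoidal drift of amplitude `drift_amplitude` along the first
#' signal direction (one full period over the trajectory), and writes the
#' frames as a multi-model PDB.
#'
#' @param model a `gaussian_model` whose node labels carry real atom names.
#' @param path output PDB path.
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param drift_amplitude drift amplitude, Angstrom (0 disables drift).
#' @return The ensemble that was written (invisibly); frame order is time
#'   order.
#' @export
synthetic_trajectory <- function(model, path, n_frames = 200, seed = 1,
                                 drift_amplitude = 0) {
  ens <- gaussian_ensemble(model, n = n_frames, seed = seed)
  if (drift_amplitude != 0) {
    phase <- sin(2 * pi * (seq_len(n_frames) - 1) / n_frames)
    ens$xyz <- ens$xyz + (drift_amplitude * phase) %o% model$directions[, 1]
    ens$aligned <- FALSE # drift moves the frame means apart
  }
  ens$source <- "synthetic-trajectory"
  write_rna_pdb(ens, path)
  invisible(ens)
}
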