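#' Specification for a correlated Gaussian fluctuation ensemble
#'
#' Ground-truth generator for cross-correlation analysis: nodes fluctuate
#' around reference positions with zero-mean Gaussian displacements whose
#' inter-node correlation is prescribed. The same correlation is applied
#' independently and identically to the x, y and z displacement components,
#' which makes the theoretical dynamic cross-correlation matrix equal the
#' prescribed matrix exactly.
#'
#' @param reference_coords n_nodes x 3 matrix, Angstrom (one representative
#'   position per nucleotide).
#' @param correlation symmetric positive semi-definite matrix in `[-1, 1]`
#'   with unit diagonal.
#' @param sigma per-node fluctuation amplitude, Angstrom, all `> 0`
#'   (recycled).
#' @param n_frames number of frames to draw.
#' @param rng_seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return object of class `fluctuation_spec`.
#' @export
fluctuation_spec <- function(reference_coords, correlation, sigma, n_frames,
                             rng_seed = 20220209L) {
  reference_coords <- as.matrix(reference_coords)
  n <- nrow(reference_coords)
  correlation <- as.matrix(correlation)
  stopifnot(ncol(reference_coords) == 3L, nrow(correlation) == n,
            ncol(correlation) == n, n_frames >= 2L)
  if (max(abs(correlation - t(correlation))) > 1e-12)
    stop("correlation matrix must be symmetric")
  if (max(abs(diag(correlation) - 1)) > 1e-12)
    stop("correlation matrix must have unit diagonal")
  if (max(abs(correlation)) > 1 + 1e-12)
    stop("correlation entries must lie in [-1, 1]")
  sigma <- rep_len(as.numeric(sigma), n)
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("fluctuation amplitudes sigma must all be > 0")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("correlation matrix is not positive semi-definite (most negative eigenvalue %.3g)",
                 min(ev)))
  structure(list(reference_coords = reference_coords, correlation = correlation,
                 sigma = sigma, n_frames = as.integer(n_frames),
                 rng_seed = as.integer(rng_seed)),
            class = "fluctuation_spec")
}

# factor L with L %*% t(L) = S, tolerant of semi-definite S
psd_factor <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S))
}

#' Draw a node-level fluctuation ensemble with prescribed correlation
#'
#' Frames are `reference + displacement`, displacements zero-mean Gaussian
#' with covariance `Sigma_ij = sigma_i sigma_j rho_ij` applied i.i.d. to each
#' Cartesian component. A minimal one-atom-per-node topology (C1'
#' representatives) accompanies the frames so downstream analyses can index
#' them.
#'
#' @param spec a [fluctuation_spec()].
#' @return list with `model` (a `structure_model`, one C1' atom per node) and
#'   `traj` (single-replicate `trajectory_ensemble`).
#' @export
gen_fluctuation_ensemble <- function(spec) {
  stopifnot(inherits(spec, "fluctuation_spec"))
  n <- nrow(spec$reference_coords)
  L <- psd_factor(spec$correlation)
  set.seed(spec$rng_seed)
  frames <- array(NA_real_, dim = c(spec$n_frames, n, 3L))
  for (k in 1:3) {
    z <- matrix(stats::rnorm(spec$n_frames * n), spec$n_frames, n)
    frames[, , k] <- sweep(z %*% t(L), 2L, spec$sigma, `*`) +
      matrix(spec$reference_coords[, k], spec$n_frames, n, byrow = TRUE)
  }
  model <- structure_model(
    atom_name = rep("C1'", n), element = rep("C", n),
    chain = rep("A", n), resnum = seq_len(n), resname = rep("G", n),
    coords = spec$reference_coords
  )
  list(model = model,
       traj = trajectory_ensemble(list(frames), model,
                                  system_id = "fluctuation-ensemble"))
}

#' Draw a full-atom trajectory with residue-level correlated motion
#'
#' Every atom of residue i is displaced rigidly by that residue's correlated
#' Gaussian displacement (covariance `sigma_i sigma_j rho_ij` per axis), plus
#' optional independent per-atom jitter. The representative-atom
#' cross-correlation of the result converges to `correlation` as the jitter
#' vanishes, so a full-atom synthetic system carries a known communication
#' ground truth through the entire pipeline.
#'
#' @param model a `structure_model` (all atoms are displaced).
#' @param correlation n_residues x n_residues target correlation.
#' @param sigma per-residue displacement amplitude, Angstrom (recycled).
#' @param n_frames frames per replicate.
#' @param n_replicates independent replicates (fresh noise each).
#' @param atom_jitter sd of i.i.d. per-atom Gaussian noise, Angstrom.
#' @param rng_seed integer seed.
#' @param system_id system label.
#' @return a `trajectory_ensemble`.
#' @export
gen_system_trajectory <- function(model, correlation, sigma = 0.5,
                                  n_frames = 300L, n_replicates = 1L,
                                  atom_jitter = 0.05, rng_seed = 20220209L,
                                  system_id = "synthetic-system") {
  nres <- n_residues(model)
  spec <- fluctuation_spec(matrix(0, nres, 3L), correlation, sigma,
                           max(n_frames, 2L), rng_seed)
  L <- psd_factor(spec$correlation)
  na <- n_atoms(model)
  ridx <- model$atoms$residue_index
  ref <- model$coords
  set.seed(spec$rng_seed)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    frames <- array(NA_real_, dim = c(n_frames, na, 3L))
    for (k in 1:3) {
      z <- matrix(stats::rnorm(n_frames * nres), n_frames, nres)
      disp <- sweep(z %*% t(L), 2L, spec$sigma, `*`)  # frames x residues
      atom_disp <- disp[, ridx, drop = FALSE]
      if (atom_jitter > 0)
        atom_disp <- atom_disp + matrix(stats::rnorm(n_frames * na, sd = atom_jitter),
                                        n_frames, na)
      frames[, , k] <- atom_disp +
        matrix(ref[, k], n_frames, na, byrow = TRUE)
    }
    reps[[r]] <- frames
  }
  trajectory_ensemble(reps, model, system_id = system_id)
}
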