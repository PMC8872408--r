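#' Kabsch least-squares superposition
#'
#' Proper-rotation (det = +1) least-squares fit of `mobile` onto `target`
#' over `fit_indices`, applied to all atoms of `mobile`.
#'
#' @param mobile,target n x 3 coordinate matrices (same atom order).
#' @param fit_indices atom indices defining the fit; default all atoms.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `coords` (fitted mobile coordinates: `mobile %*% t(R) + t`), and `rmsd`
#'   over the fit atoms.
#' @export
kabsch_superpose <- function(mobile, target, fit_indices = seq_len(nrow(mobile))) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (length(fit_indices) < 3L)
    stop("degenerate fit: need at least 3 fit atoms")
  mf <- mobile[fit_indices, , drop = FALSE]
  tf <- target[fit_indices, , drop = FALSE]
  mc <- colMeans(mf); tc <- colMeans(tf)
  A <- t(sweep(mf, 2L, mc)) %*% sweep(tf, 2L, tc)
  s <- svd(A)
  if (s$d[2L] < 1e-10 * max(s$d[1L], 1))
    stop("degenerate fit: fit atoms are collinear")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- tc - as.vector(R %*% mc)
  fitted <- mobile %*% t(R) + matrix(trans, nrow(mobile), 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted[fit_indices, , drop = FALSE] - tf)^2)))
  list(rotation = R, translation = trans, coords = fitted, rmsd = rmsd)
}

#' Per-frame RMSD of a selection after fitting
#'
#' For every window frame, the frame is superposed onto the reference over
#' `fit_selection` (heavy atoms of the same substructure, in the
#' per-substructure convention) and the RMSD is evaluated over `selection`.
#'
#' @param traj a `trajectory_ensemble`.
#' @param model matching `structure_model`.
#' @param selection atom indices whose deviation is measured.
#' @param fit_selection atom indices used for superposition; default
#'   `selection`.
#' @param reference reference coordinates (n_atoms x 3); default the model's.
#' @param window an `analysis_window`.
#' @return object of class `rmsd_series`: list with `rmsd` (per concatenated
#'   frame, Angstrom), `replicate`, `mean`, `sd`, `sem`.
#' @export
rmsd_series <- function(traj, model, selection, fit_selection = selection,
                        reference = model$coords, window = full_window(traj)) {
  if (!length(selection)) stop("selection resolved to zero atoms")
  frames <- concat_window(traj, window)
  nf <- dim(frames)[1L]
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    fr <- frames[f, , , drop = TRUE]
    fit <- kabsch_superpose(fr, reference, fit_selection)
    d <- fit$coords[selection, , drop = FALSE] -
      reference[selection, , drop = FALSE]
    out[f] <- sqrt(mean(rowSums(d^2)))
  }
  structure(list(rmsd = out, replicate = attr(frames, "replicate"),
                 mean = mean(out), sd = stats::sd(out),
                 sem = stats::sd(out) / sqrt(nf)),
            class = "rmsd_series")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat(sprintf("rmsd_series: %d frames, %.2f +/- %.2f A (sd)\n",
              length(x$rmsd), x$mean, x$sd))
  invisible(x)
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are fitted to the reference over `fit_selection`, averaged, then
#' refitted to that average (two-pass iterative fitting); the per-atom RMSF
#' is the root-mean-square displacement from the time-average position, and
#' a residue's value is the RMS over its heavy atoms in `selection`.
#'
#' @inheritParams rmsd_series
#' @return object of class `rmsf_profile`: data.frame with `residue`,
#'   `label`, `rmsf` (Angstrom); per-atom values in attribute `atom_rmsf`.
#' @export
rmsf_profile <- function(traj, model, selection = select_atoms(model, heavy = TRUE),
                         fit_selection = selection, reference = model$coords,
                         window = full_window(traj)) {
  frames <- concat_window(traj, window)
  nf <- dim(frames)[1L]
  fitted <- array(NA_real_, dim = dim(frames))
  for (f in seq_len(nf))
    fitted[f, , ] <- kabsch_superpose(frames[f, , , drop = TRUE],
                                      reference, fit_selection)$coords
  mean_coords <- apply(fitted, c(2L, 3L), mean)
  for (f in seq_len(nf))
    fitted[f, , ] <- kabsch_superpose(fitted[f, , , drop = TRUE],
                                      mean_coords, fit_selection)$coords
  mean_coords <- apply(fitted, c(2L, 3L), mean)
  dev2 <- array(0, dim = c(nf, dim(frames)[2L]))
  for (k in 1:3)
    dev2 <- dev2 + (fitted[, , k] -
                      matrix(mean_coords[, k], nf, dim(frames)[2L], byrow = TRUE))^2
  atom_rmsf <- sqrt(colMeans(dev2))

  res_of <- model$atoms$residue_index
  res_ids <- sort(unique(res_of[selection]))
  res_rmsf <- vapply(res_ids, function(r) {
    idx <- intersect(selection, which(res_of == r))
    sqrt(mean(atom_rmsf[idx]^2))
  }, numeric(1))
  out <- data.frame(residue = res_ids,
                    label = residue_labels(model)[res_ids],
                    rmsf = res_rmsf, stringsAsFactors = FALSE)
  attr(out, "atom_rmsf") <- atom_rmsf
  class(out) <- c("rmsf_profile", class(out))
  out
}

#' Substructure RMSD table (per-region fit, per-region deviation)
#'
#' One row per region plus the whole RNA: each region's RMSD is computed
#' after fitting that region's own heavy atoms to the reference, so stems and
#' junctions are judged on internal deformation, not global motion. Both the
#' frame-to-frame standard deviation and the standard error of the mean are
#' reported.
#'
#' @param traj a `trajectory_ensemble`.
#' @param model matching `structure_model`.
#' @param map a `substructure_map`.
#' @param reference reference coordinates; default the model's.
#' @param window an `analysis_window`.
#' @return a [tabular_report()] with columns region, n_atoms, mean_rmsd,
#'   sd_rmsd, sem_rmsd.
#' @export
rmsd_table <- function(traj, model, map, reference = model$coords,
                       window = full_window(traj)) {
  rna_res <- which(!model$residues$is_ligand)
  rows <- list()
  add_row <- function(name, sel) {
    s <- rmsd_series(traj, model, sel, sel, reference, window)
    rows[[length(rows) + 1L]] <<- data.frame(
      region = name, n_atoms = length(sel), mean_rmsd = s$mean,
      sd_rmsd = s$sd, sem_rmsd = s$sem, stringsAsFactors = FALSE)
  }
  add_row("RNA", select_atoms(model, residues = rna_res, heavy = TRUE))
  for (nm in names(map))
    add_row(nm, select_atoms(model, region = nm, map = map, heavy = TRUE))
  tabular_report(do.call(rbind, rows),
                 params = list(regions = names(map)), window = window)
}
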