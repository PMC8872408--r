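PUCKER_LABELS <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo", "C2'-endo",
                   "C3'-exo", "C4'-endo", "O4'-exo", "C1'-endo", "C2'-exo")

RING_ATOMS <- c("O4'", "C1'", "C2'", "C3'", "C4'")

#' Dihedral angle of four points
#'
#' IUPAC sign convention, degrees in `(-180, 180]`.
#'
#' @param p1,p2,p3,p4 3-vectors (Angstrom).
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2; b1 <- p3 - p2; b2 <- p4 - p3
  b1n <- b1 / sqrt(sum(b1^2))
  v <- b0 - sum(b0 * b1n) * b1n
  w <- b2 - sum(b2 * b1n) * b1n
  ang <- atan2(sum(cross3(b1n, v) * w), sum(v * w)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Endocyclic torsions of a furanose ring
#'
#' Standard definitions over the ring O4'-C1'-C2'-C3'-C4':
#' `nu0 = C4'-O4'-C1'-C2'`, `nu1 = O4'-C1'-C2'-C3'`, `nu2 = C1'-C2'-C3'-C4'`,
#' `nu3 = C2'-C3'-C4'-O4'`, `nu4 = C3'-C4'-O4'-C1'`.
#'
#' @param coords 5 x 3 matrix of ring-atom coordinates in the order
#'   O4', C1', C2', C3', C4' (rows may be named; missing atoms are reported
#'   by name).
#' @return numeric vector `nu0..nu4`, degrees in `(-180, 180]`.
#' @export
endocyclic_torsions <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != 5L || ncol(coords) != 3L)
    stop("ring coordinates must be a 5 x 3 matrix (O4', C1', C2', C3', C4')")
  bad <- which(!stats::complete.cases(coords) | rowSums(!is.finite(coords)) > 0)
  if (length(bad)) {
    nm <- rownames(coords)[bad[1L]]
    if (is.null(nm)) nm <- RING_ATOMS[bad[1L]]
    stop("missing ring atom: ", nm)
  }
  # ring index sequences for nu0..nu4 (1 = O4', ..., 5 = C4')
  quads <- rbind(c(5, 1, 2, 3), c(1, 2, 3, 4), c(2, 3, 4, 5),
                 c(3, 4, 5, 1), c(4, 5, 1, 2))
  nu <- vapply(1:5, function(j) {
    q <- quads[j, ]
    dihedral(coords[q[1L], ], coords[q[2L], ], coords[q[3L], ], coords[q[4L], ])
  }, numeric(1))
  names(nu) <- paste0("nu", 0:4)
  nu
}

#' Pseudorotation phase, amplitude and conformer class
#'
#' Altona--Sundaralingam analysis of five endocyclic torsions:
#' `P = atan2((nu4 + nu1) - (nu3 + nu0), 2 nu2 (sin 36 + sin 72))` mapped to
#' `[0, 360)`, amplitude `tau_m = nu2 / cos(P)` (switching to the numerator
#' form near P = 90/270 where `cos P` vanishes). Conformer labels are the ten
#' 36-degree twist/envelope sectors starting with C3'-endo at `[0, 36)`.
#' A ring flatter than `tau_threshold` has no defined phase: the state is
#' returned as planar/undefined (`NA` phase and label).
#'
#' @param nu numeric vector `nu0..nu4` (degrees).
#' @param tau_threshold amplitude (degrees) below which the ring is treated
#'   as planar.
#' @return object of class `pucker_state`: list with `P`, `tau_m`, `label`,
#'   `defined`.
#' @export
pseudorotation <- function(nu, tau_threshold = 5) {
  stopifnot(length(nu) == 5L, all(is.finite(nu)))
  s36 <- sinpi(36 / 180); s72 <- sinpi(72 / 180)
  num <- (nu[5L] + nu[2L]) - (nu[4L] + nu[1L])
  den <- 2 * nu[3L] * (s36 + s72)
  if (num == 0 && den == 0)
    return(structure(list(P = NA_real_, tau_m = 0, label = NA_character_,
                          defined = FALSE), class = "pucker_state"))
  P <- atan2(num, den) * 180 / pi
  if (P < 0) P <- P + 360
  cP <- cospi(P / 180); sP <- sinpi(P / 180)
  tau_m <- if (abs(cP) >= abs(sP)) nu[3L] / cP else num / (2 * sP * (s36 + s72))
  tau_m <- unname(tau_m)
  if (!is.finite(tau_m) || tau_m < tau_threshold)
    return(structure(list(P = NA_real_, tau_m = tau_m, label = NA_character_,
                          defined = FALSE), class = "pucker_state"))
  sector <- floor((P %% 360) / 36) + 1L
  structure(list(P = unname(P), tau_m = tau_m,
                 label = PUCKER_LABELS[sector], defined = TRUE),
            class = "pucker_state")
}

#' @export
print.pucker_state <- function(x, ...) {
  if (x$defined)
    cat(sprintf("pucker: P = %.2f deg, tau_m = %.2f deg (%s)\n",
                x$P, x$tau_m, x$label))
  else cat("pucker: planar/undefined\n")
  invisible(x)
}

#' Sugar-pucker time series and sector occupancy along a trajectory
#'
#' Classifies the furanose ring of one residue (default: the ligand) in every
#' window frame of every replicate, and tabulates the fraction of frames per
#' conformer sector.
#'
#' @param traj a `trajectory_ensemble`.
#' @param model the matching `structure_model`.
#' @param residue residue index; default the (single) ligand residue.
#' @param ring_atom_names the five ring atom names, ring order.
#' @param window an `analysis_window`.
#' @param tau_threshold planarity threshold passed to [pseudorotation()].
#' @return list with `states` (data.frame: replicate, frame, P, tau_m, label)
#'   and `occupancy` (named numeric, fractions summing to 1 over defined
#'   states).
#' @export
pucker_timeseries <- function(traj, model, residue = NULL,
                              ring_atom_names = RING_ATOMS,
                              window = full_window(traj), tau_threshold = 5) {
  if (is.null(residue)) {
    lig <- which(model$residues$is_ligand)
    if (length(lig) != 1L)
      stop("residue not given and model does not have exactly one ligand residue")
    residue <- lig
  }
  ring_idx <- integer(5L)
  res_atoms <- which(model$atoms$residue_index == residue)
  for (j in seq_along(ring_atom_names)) {
    hit <- res_atoms[model$atoms$atom_name[res_atoms] == ring_atom_names[j]]
    if (length(hit) != 1L)
      stop("missing ring atom: ", ring_atom_names[j])
    ring_idx[j] <- hit
  }
  check_window(traj, window)
  sel <- (window$start + 1L):window$end
  rows <- list()
  for (r in seq_along(traj$replicates)) {
    rep_frames <- traj$replicates[[r]]
    for (f in sel) {
      coords <- rep_frames[f, ring_idx, , drop = TRUE]
      rownames(coords) <- ring_atom_names
      st <- pseudorotation(endocyclic_torsions(coords), tau_threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, frame = f, P = st$P, tau_m = st$tau_m,
        label = if (st$defined) st$label else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  states <- do.call(rbind, rows)
  defined <- states$label[!is.na(states$label)]
  occupancy <- if (length(defined)) table(defined) / length(defined) else table(character())
  occ <- stats::setNames(as.numeric(occupancy), names(occupancy))
  list(states = states, occupancy = occ)
}
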