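#' Scripted donor--H--acceptor scene with exact geometry
#'
#' Places a donor (N), its hydrogen and an acceptor (O) so that the
#' heavy--heavy distance and the D-H...A angle (at the hydrogen) equal the
#' request exactly, in a chosen fraction of frames; in the remaining frames
#' the acceptor residue is displaced 20 Angstrom away. Frame presence is
#' deterministic (the first `round(fraction * n_frames)` frames).
#'
#' @param distance donor--acceptor heavy-atom distance, Angstrom.
#' @param angle D-H...A angle at the hydrogen, degrees, in `(0, 180]`.
#' @param n_frames number of frames.
#' @param fraction fraction of frames in which the geometry is present.
#' @param n_hydrogens 1 or 2 donor hydrogens satisfying the same geometry
#'   (the second mirrored through the D--A axis plane).
#' @param dh donor--hydrogen bond length, Angstrom.
#' @return list with `model` and `traj`.
#' @export
gen_hbond_scene <- function(distance, angle, n_frames = 100L, fraction = 1,
                            n_hydrogens = 1L, dh = 1.0) {
  if (angle <= 0 || angle > 180)
    stop("geometry error: D-H...A angle must lie in (0, 180]")
  if (fraction < 0 || fraction > 1) stop("presence fraction must be in [0, 1]")
  if (distance <= dh)
    stop("geometry error: donor-acceptor distance must exceed the D-H bond")
  th <- angle * pi / 180
  # triangle D-H-A: |DH| = dh, angle at H = angle, |DA| = distance
  ha <- dh * cos(th) + sqrt(distance^2 - (dh * sin(th))^2)
  if (!is.finite(ha) || ha <= 0)
    stop("geometry error: requested distance/angle not realizable")
  # H at origin, D on +x, A at angle theta from D direction
  D <- c(dh, 0, 0)
  A <- ha * c(cos(th), sin(th), 0)
  H1 <- c(0, 0, 0)
  H2 <- c(0, 0, 0)
  atoms <- list(name = c("N3", "H31", "O2"),
                element = c("N", "H", "O"),
                resname = c("DON", "DON", "ACC"),
                resnum = c(1L, 1L, 2L),
                coords = rbind(D, H1, A))
  if (n_hydrogens == 2L) {
    # mirror the first hydrogen through the D-A axis (still exact geometry)
    u <- (A - D) / sqrt(sum((A - D)^2))
    refl <- D + sum((H1 - D) * u) * u
    H2 <- 2 * refl - H1
    H2[3L] <- H2[3L]  # planar scene: reflection stays in plane
    atoms$name <- c("N3", "H31", "H32", "O2")
    atoms$element <- c("N", "H", "H", "O")
    atoms$resname <- c("DON", "DON", "DON", "ACC")
    atoms$resnum <- c(1L, 1L, 1L, 2L)
    atoms$coords <- rbind(D, H1, H2, A)
  }
  model <- structure_model(atoms$name, atoms$element,
                           chain = rep("A", length(atoms$name)),
                           resnum = atoms$resnum, resname = atoms$resname,
                           coords = atoms$coords)
  n_present <- round(fraction * n_frames)
  frames <- array(rep(atoms$coords, each = n_frames),
                  dim = c(n_frames, nrow(atoms$coords), 3L))
  acc <- which(atoms$resnum == 2L)
  if (n_present < n_frames)
    frames[(n_present + 1L):n_frames, acc, 3L] <-
      frames[(n_present + 1L):n_frames, acc, 3L] + 20
  list(model = model,
       traj = trajectory_ensemble(list(frames), model, system_id = "hbond-scene"))
}

template_residue <- function(code) {
  t <- BASE_TEMPLATES[[code]]
  if (is.null(t)) stop("no residue template for '", code, "'")
  t
}

ring_centroid <- function(coords, names, atoms) {
  colMeans(coords[names %in% atoms, , drop = FALSE])
}

plane_normal <- function(coords) {
  c0 <- sweep(coords, 2L, colMeans(coords))
  v <- svd(c0)$v
  v[, 3L]
}

# rotation mapping orthonormal frame (v, n) -> (v2, n2)
frame_rotation <- function(v, n, v2, n2) {
  B1 <- cbind(v, n, cross3(v, n))
  B2 <- cbind(v2, n2, cross3(v2, n2))
  B2 %*% t(B1)
}

unit <- function(x) x / sqrt(sum(x^2))

#' Idealized guanine--cytosine base-pair scene
#'
#' Builds a planar G-C pair from idealized residue templates by docking the
#' cytosine Watson-Crick edge onto a chosen guanine edge: `"wc"` gives the
#' canonical cis Watson-Crick/Watson-Crick pair (N1-H1...N3, N2-H21...O2,
#' N4-H41...O6), `"hoogsteen"` docks the cytosine WC edge onto the guanine
#' Hoogsteen edge (N7/O6). The trans variant rotates the cytosine 180 degrees
#' about the central hydrogen-bond axis, which flips its glycosidic side
#' while preserving the central bond exactly.
#'
#' Frames follow a scripted cis/trans/absent pattern: `n_cis` cis frames,
#' then `n_trans` trans frames, then `n_absent` frames with the cytosine
#' displaced 30 Angstrom.
#'
#' @param n_cis,n_trans,n_absent frame counts per scripted state.
#' @param edge `"wc"` or `"hoogsteen"` (guanine edge receiving the cytosine).
#' @param d_nn central N...N hydrogen-bond heavy-atom distance, Angstrom.
#' @return list with `model` and `traj`.
#' @export
gen_basepair_scene <- function(n_cis = 1L, n_trans = 0L, n_absent = 0L,
                               edge = c("wc", "hoogsteen"), d_nn = 2.95) {
  edge <- match.arg(edge)
  g <- template_residue("G")
  c_ <- template_residue("C")
  if (edge == "hoogsteen") {
    # Hoogsteen G-C pairing needs a protonated cytosine N3 (C+), as in the
    # physiological triplex motif: add H3 along the Watson-Crick edge
    pyr <- c("N1", "C2", "N3", "C4", "C5", "C6")
    n3 <- c_$coords[c_$atom_name == "N3", ]
    cen <- ring_centroid(c_$coords, c_$atom_name, pyr)
    c_ <- list(atom_name = c(c_$atom_name, "H3"),
               element = c(c_$element, "H"),
               coords = rbind(c_$coords, n3 + 1.03 * unit(n3 - cen)))
  }
  gx <- g$coords
  pur_ring <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  g_centroid <- ring_centroid(gx, g$atom_name, pur_ring)
  g_normal <- plane_normal(gx[g$atom_name %in% pur_ring, , drop = FALSE])

  if (edge == "wc") {
    anchor <- gx[g$atom_name == "N1", ]
    u <- unit(gx[g$atom_name == "H1", ] - anchor)
  } else {
    anchor <- gx[g$atom_name == "N7", ]
    u <- unit(anchor - g_centroid)
  }
  target <- anchor + d_nn * u

  cx <- c_$coords
  pyr_ring <- c("N1", "C2", "N3", "C4", "C5", "C6")
  c_anchor <- cx[c_$atom_name == "N3", ]
  c_dir <- unit(ring_centroid(cx, c_$atom_name, pyr_ring) - c_anchor)
  c_normal <- plane_normal(cx[c_$atom_name %in% pyr_ring, , drop = FALSE])

  place <- function(flip_normal) {
    R <- frame_rotation(c_dir, if (flip_normal) -c_normal else c_normal,
                        u, g_normal)
    sweep(cx, 2L, c_anchor) %*% t(R) + matrix(target, nrow(cx), 3L, byrow = TRUE)
  }
  cand <- list(place(FALSE), place(TRUE))
  # pick the docking that realizes the flanking N4...O6 hydrogen bond
  o6 <- gx[g$atom_name == "O6", ]
  d_n4 <- vapply(cand, function(cc) sqrt(sum((cc[c_$atom_name == "N4", ] - o6)^2)),
                 numeric(1))
  cis_c <- cand[[which.min(d_n4)]]

  # rotation about an axis through `point`
  axis_rot <- function(coords, axis, point, angle_deg) {
    a <- unit(axis); th <- angle_deg * pi / 180
    K <- matrix(c(0, a[3L], -a[2L], -a[3L], 0, a[1L], a[2L], -a[1L], 0), 3L, 3L)
    R <- diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    sweep(coords, 2L, point) %*% t(R) + matrix(point, nrow(coords), 3L, byrow = TRUE)
  }
  if (edge == "hoogsteen") {
    # propeller the cytosine in-plane about the anchored N3 to close the
    # flanking N4-H...O6 bond (the central N...N distance is preserved)
    best <- 0; best_d <- Inf
    for (ang in seq(-60, 60, by = 1)) {
      cc <- axis_rot(cis_c, g_normal, target, ang)
      dd <- sqrt(sum((cc[c_$atom_name == "N4", ] - o6)^2))
      if (dd < best_d) { best_d <- dd; best <- ang }
    }
    cis_c <- axis_rot(cis_c, g_normal, target, best)
  }

  # trans: 180-degree rotation about the central H-bond axis through target
  trans_c <- axis_rot(cis_c, u, target, 180)

  atom_name <- c(g$atom_name, c_$atom_name)
  element <- c(g$element, c_$element)
  resnum <- c(rep(1L, nrow(gx)), rep(2L, nrow(cx)))
  resname <- c(rep("G", nrow(gx)), rep("C", nrow(cx)))
  model <- structure_model(atom_name, element, rep("A", length(atom_name)),
                           resnum, resname, rbind(gx, cis_c))

  n_frames <- n_cis + n_trans + n_absent
  if (n_frames < 2L) n_frames <- 2L
  frames <- array(NA_real_, dim = c(n_frames, length(atom_name), 3L))
  gi <- seq_len(nrow(gx)); ci <- nrow(gx) + seq_len(nrow(cx))
  far <- sweep(cis_c, 2L, c(0, 0, 30), `+`)
  for (f in seq_len(n_frames)) {
    frames[f, gi, ] <- gx
    frames[f, ci, ] <- if (f <= n_cis) cis_c
      else if (f <= n_cis + n_trans) trans_c else far
  }
  list(model = model,
       traj = trajectory_ensemble(list(frames), model, system_id = "basepair-scene"))
}

#' Scripted two-ring stacking scene
#'
#' Two guanine residues: the second is rotated by `normal_angle` about an
#' in-plane axis and its ring centroid displaced `distance` along the first
#' ring's normal plus `offset` laterally within the plane.
#'
#' @param distance centroid--centroid separation along the ring normal,
#'   Angstrom.
#' @param normal_angle angle between the two ring normals, degrees.
#' @param offset lateral (in-plane) centroid offset, Angstrom.
#' @param n_frames number of (identical) frames.
#' @return list with `model` and `traj`.
#' @export
gen_stack_scene <- function(distance = 3.4, normal_angle = 0, offset = 0,
                            n_frames = 2L) {
  g <- template_residue("G")
  pur_ring <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  ring_sel <- g$atom_name %in% pur_ring
  cen <- ring_centroid(g$coords, g$atom_name, pur_ring)
  nrm <- plane_normal(g$coords[ring_sel, , drop = FALSE])
  inplane <- unit(g$coords[g$atom_name == "N1", ] - cen)

  x2 <- sweep(g$coords, 2L, cen)
  th <- normal_angle * pi / 180
  a <- inplane
  K <- matrix(c(0, a[3L], -a[2L], -a[3L], 0, a[1L], a[2L], -a[1L], 0), 3L, 3L)
  R <- diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  x2 <- x2 %*% t(R)
  shift <- cen + distance * nrm + offset * inplane
  x2 <- sweep(x2, 2L, shift, `+`)

  atom_name <- c(g$atom_name, g$atom_name)
  element <- c(g$element, g$element)
  resnum <- c(rep(1L, nrow(g$coords)), rep(2L, nrow(g$coords)))
  model <- structure_model(atom_name, element, rep("A", length(atom_name)),
                           resnum, rep("G", length(atom_name)),
                           rbind(g$coords, x2))
  frames <- array(rep(rbind(g$coords, x2), each = n_frames),
                  dim = c(n_frames, length(atom_name), 3L))
  list(model = model,
       traj = trajectory_ensemble(list(frames), model, system_id = "stack-scene"))
}
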