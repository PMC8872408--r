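#' Endocyclic torsions of an ideal furanose ring at a given pucker
#'
#' Altona--Sundaralingam parametrization: `nu_j = tau_m * cos(P + 144 * (j - 2))`
#' (degrees), so `nu2 = tau_m * cos(P)`; phase P = 18 deg is C3'-endo and
#' P = 162 deg is C2'-endo. This is the exact ground truth the pseudorotation
#' analysis must invert.
#'
#' @param P pseudorotation phase, degrees in `[0, 360)`.
#' @param tau_m pucker amplitude, degrees, `>= 0`.
#' @return numeric vector `nu0..nu4` (degrees).
#' @export
gen_furanose_ring <- function(P, tau_m) {
  stopifnot(length(P) == 1L, length(tau_m) == 1L, is.finite(P), is.finite(tau_m))
  if (tau_m < 0) stop("pucker amplitude tau_m must be >= 0")
  if (P < 0 || P >= 360) stop("pseudorotation phase P must lie in [0, 360)")
  j <- 0:4
  nu <- tau_m * cospi((P + 144 * (j - 2)) / 180)
  names(nu) <- paste0("nu", j)
  nu
}

#' Cartesian furanose-ring fixture at a canonical pucker phase
#'
#' Embeds the five ring atoms (order O4', C1', C2', C3', C4') on a circle
#' with sinusoidal out-of-plane displacements, a standard puckered-ring
#' construction. The embedded ring's torsions follow the Altona--Sundaralingam
#' phase up to a small amplitude-dependent distortion, so the fixture is
#' meant for sector-level checks (C3'-endo vs C2'-endo), not for exact
#' round-trips -- the torsion-space generator [gen_furanose_ring()] is exact.
#'
#' @param P target pseudorotation phase, degrees.
#' @param amplitude out-of-plane displacement amplitude, Angstrom.
#' @param bond ring bond length, Angstrom.
#' @return 5 x 3 coordinate matrix, rows named O4', C1', C2', C3', C4'.
#' @export
furanose_ring_coords <- function(P, amplitude = 0.38, bond = 1.45) {
  m <- 0:4
  radius <- bond / (2 * sinpi(36 / 180))
  theta <- 72 * m
  # phase offset calibrated so the embedded ring's recovered phase tracks P
  z <- sqrt(2 / 5) * amplitude * cospi((P + 90 + 144 * m) / 180)
  xy <- cbind(radius * cospi(theta / 180), radius * sinpi(theta / 180))
  coords <- cbind(xy, z)
  rownames(coords) <- c("O4'", "C1'", "C2'", "C3'", "C4'")
  coords
}
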