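# replace the out-of-plane components of the five furanose ring atoms with a
# sinusoidal pucker at phase P (same construction as furanose_ring_coords);
# non-ring atoms are untouched
set_ring_pucker <- function(coords, names, P, amplitude = 0.38) {
  ring <- c("O4'", "C1'", "C2'", "C3'", "C4'")
  idx <- match(ring, names)
  if (anyNA(idx)) return(coords)
  x <- coords[idx, , drop = FALSE]
  cen <- colMeans(x)
  nrm <- plane_normal(x)
  m <- 0:4
  z <- sqrt(2 / 5) * amplitude * cospi((P + 90 + 144 * m) / 180)
  inplane <- sweep(x, 2L, cen) -
    outer(as.vector(sweep(x, 2L, cen) %*% nrm), nrm)
  coords[idx, ] <- sweep(inplane + outer(z, nrm), 2L, cen, `+`)
  coords
}

#' Deterministic toy aptamer with the canonical three-way-junction regions
#'
#' Builds a riboswitch-aptamer-like structure model from idealized nucleotide
#' templates: three paired stems (P1, P2, P3), the three junction strands
#' (J1/2, J2/3, J3/1), two loops (L2, L3) and one guanine-like ligand residue
#' placed against the junction. Residue centres sit on a ring layout so that
#' sequence neighbours and cross-strand partners are in contact range; the
#' geometry mimics the aptamer's region topology, not its true fold.
#'
#' The ligand carries guanine-like atom names (N1, N2, N3, O6, C1', O4',
#' O5', O3'); an rG-like ligand additionally has O2' (and its hydroxyl
#' hydrogen), a dG-like one does not.
#'
#' @param n_residues total residue count including the ligand, `>= 12`.
#' @param rng_seed integer seed; identical arguments give identical models.
#' @param ligand `"dG"` or `"rG"`.
#' @param ligand_code residue name given to the ligand.
#' @return list with `model` (a `structure_model`) and `map` (a
#'   `substructure_map` over the nine canonical regions).
#' @export
gen_toy_aptamer <- function(n_residues = 40L, rng_seed = 20220209L,
                            ligand = c("dG", "rG"), ligand_code = "LIG") {
  ligand <- match.arg(ligand)
  if (n_residues < 12L)
    stop("n_residues must be >= 12 to populate all canonical regions")
  m <- n_residues - 1L  # RNA residues
  set.seed(rng_seed)

  # sequential segments with proportional allocation, >= 1 residue each
  seg_names <- c("P1a", "J1/2", "P2a", "L2", "P2b", "J2/3", "P3a", "L3",
                 "P3b", "J3/1", "P1b")
  w <- c(3, 3, 4, 5, 4, 2, 4, 3, 4, 4, 3)
  alloc <- floor(w / sum(w) * m)
  alloc <- pmax(alloc, 1L)
  while (sum(alloc) > m) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  while (sum(alloc) < m) alloc[which.min(alloc)] <- alloc[which.min(alloc)] + 1L
  seg_of <- rep(seg_names, alloc)

  bases <- sample(c("A", "C", "G", "U"), m, replace = TRUE)
  theta <- 2 * pi * (seq_len(m) - 1L) / m
  radius <- max(6 * m / (2 * pi), 12)
  centers <- cbind(radius * cos(theta), radius * sin(theta),
                   stats::rnorm(m, sd = 0.5))

  rand_rotation <- function() {
    qr_ <- qr(matrix(stats::rnorm(9L), 3L))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1L] <- -R[, 1L]
    R
  }

  atom_name <- character(); element <- character()
  resnum <- integer(); resname <- character()
  coords <- matrix(numeric(), 0L, 3L)
  for (i in seq_len(m)) {
    t <- template_residue(bases[i])
    x <- sweep(t$coords, 2L, colMeans(t$coords)) %*% t(rand_rotation())
    x <- sweep(x, 2L, centers[i, ], `+`)
    atom_name <- c(atom_name, t$atom_name)
    element <- c(element, t$element)
    resnum <- c(resnum, rep(i, nrow(x)))
    resname <- c(resname, rep(bases[i], nrow(x)))
    coords <- rbind(coords, x)
  }

  # ligand: guanine nucleoside template against the junction side of the ring
  t <- template_residue("G")
  keep <- rep(TRUE, length(t$atom_name))
  if (ligand == "dG") keep <- !(t$atom_name %in% c("O2'", "HO2'"))
  lig_names <- t$atom_name[keep]
  lx <- t$coords[keep, , drop = FALSE]
  # repucker the furanose to the ligand's preferred conformer: S-type
  # C2'-endo for the deoxyribonucleoside, C3'-endo for the ribonucleoside
  lx <- set_ring_pucker(lx, lig_names,
                        P = if (ligand == "dG") 162 else 18, amplitude = 0.38)
  j31_first <- which(seg_of == "J3/1")[1L]
  lig_center <- 0.78 * centers[j31_first, ] + c(0, 0, 0)
  lx <- sweep(lx, 2L, colMeans(lx)) %*% t(rand_rotation())
  lx <- sweep(lx, 2L, lig_center, `+`)
  atom_name <- c(atom_name, lig_names)
  element <- c(element, t$element[keep])
  resnum <- c(resnum, rep(m + 1L, nrow(lx)))
  resname <- c(resname, rep(ligand_code, nrow(lx)))
  coords <- rbind(coords, lx)

  model <- structure_model(atom_name, element, rep("A", length(atom_name)),
                           resnum, resname, coords,
                           ligand_codes = ligand_code)
  regions <- list(
    P1 = which(seg_of %in% c("P1a", "P1b")),
    `J1/2` = which(seg_of == "J1/2"),
    P2 = which(seg_of %in% c("P2a", "P2b")),
    L2 = which(seg_of == "L2"),
    `J2/3` = which(seg_of == "J2/3"),
    P3 = which(seg_of %in% c("P3a", "P3b")),
    L3 = which(seg_of == "L3"),
    `J3/1` = which(seg_of == "J3/1"),
    Ligand = m + 1L
  )
  list(model = model, map = substructure_map(regions, model))
}
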