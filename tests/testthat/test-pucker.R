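test_that("dihedral follows the IUPAC sign convention (bio3d oracle)", {
  set.seed(44)
  for (i in 1:10) {
    p <- matrix(stats::rnorm(12), 4, 3)
    mine <- dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    oracle <- bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4)
    expect_equal(mine, unname(oracle), tolerance = 1e-6)
  }
})

test_that("pseudorotation inverts the torsion generator to 1e-9 degrees", {
  for (P in seq(0, 342, by = 18))
    for (tm in c(20, 35, 45)) {
      st <- pseudorotation(gen_furanose_ring(P, tm))
      expect_lt(abs(st$P - P), 1e-9)
      expect_lt(abs(st$tau_m - tm), 1e-9)
    }
})

test_that("conformer labels flip exactly at the 36-degree sector boundaries", {
  labels <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo", "C2'-endo",
              "C3'-exo", "C4'-endo", "O4'-exo", "C1'-endo", "C2'-exo")
  eps <- 1e-6
  for (k in 0:9) {
    b <- 36 * k
    below <- pseudorotation(gen_furanose_ring((b - eps) %% 360, 35))
    above <- pseudorotation(gen_furanose_ring(b + eps, 35))
    expect_identical(above$label, labels[k + 1L])
    expect_identical(below$label, labels[if (k == 0L) 10L else k])
  }
})

test_that("degenerate and chiral ring geometry is handled", {
  expect_false(pseudorotation(rep(0, 5))$defined)
  expect_false(pseudorotation(gen_furanose_ring(18, 3))$defined)

  co <- furanose_ring_coords(162)
  nu <- endocyclic_torsions(co)
  expect_lt(nu["nu2"], 0)                       # C2'-endo signature
  expect_equal(abs(unname(nu["nu2"])) / pseudorotation(nu)$tau_m,
               abs(cospi(162 / 180)), tolerance = 1e-6)
  mirror <- co; mirror[, 3] <- -mirror[, 3]
  expect_equal(unname(endocyclic_torsions(mirror)), -unname(nu),
               tolerance = 1e-9)

  planar <- co; planar[, 3] <- 0
  expect_equal(max(abs(endocyclic_torsions(planar))), 0, tolerance = 1e-9)

  co2 <- co; co2[2, ] <- NA
  expect_error(endocyclic_torsions(co2), "C1'")
})

test_that("phase is invariant under rigid motion of the ring", {
  co <- furanose_ring_coords(110)
  st0 <- pseudorotation(endocyclic_torsions(co))
  th <- 0.8
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- co %*% t(R) + matrix(c(4, 5, 6), 5, 3, byrow = TRUE)
  rownames(moved) <- rownames(co)
  st1 <- pseudorotation(endocyclic_torsions(moved))
  expect_equal(st1$P, st0$P, tolerance = 1e-9)
  expect_equal(st1$tau_m, st0$tau_m, tolerance = 1e-9)
})

test_that("pucker time series tabulates sector occupancy exactly", {
  ring_names <- c("O4'", "C1'", "C2'", "C3'", "C4'")
  north <- furanose_ring_coords(18)
  south <- furanose_ring_coords(162)
  m <- structure_model(rep(ring_names, 2), rep("C", 10), rep("A", 10),
                       rep(1:2, each = 5), rep(c("LIG", "G"), each = 5),
                       rbind(north, south + 20), ligand_codes = "LIG")
  nf <- 1000L
  frames <- array(rep(m$coords, each = nf), dim = c(nf, 10, 3))
  frames[801:1000, 1:5, ] <- array(rep(south, each = 200L), dim = c(200, 5, 3))
  tr <- trajectory_ensemble(list(frames), m)
  ts <- pucker_timeseries(tr, m)
  expect_equal(unname(ts$occupancy["C3'-endo"]), 0.8)
  expect_equal(unname(ts$occupancy["C2'-endo"]), 0.2)
  expect_identical(nrow(ts$states), nf)

  # alternating two-state trajectory splits 50/50
  fr2 <- frames[1:2, , , drop = FALSE]
  fr2[2, 1:5, ] <- south
  ts2 <- pucker_timeseries(trajectory_ensemble(list(fr2), m), m)
  expect_equal(unname(ts2$occupancy[c("C2'-endo", "C3'-endo")]), c(0.5, 0.5))

  m_broken <- structure_model(c(ring_names[-1], "X1", ring_names), rep("C", 10),
                              rep("A", 10), rep(1:2, each = 5),
                              rep(c("LIG", "G"), each = 5),
                              rbind(north, south), ligand_codes = "LIG")
  expect_error(pucker_timeseries(trajectory_ensemble(list(frames), m_broken),
                                 m_broken), "O4'")
})
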