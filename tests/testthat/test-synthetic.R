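test_that("fluctuation generator is deterministic and validates its spec", {
  ref <- matrix(stats::rnorm(9), 3, 3)
  rho <- diag(1, 3); rho[1, 2] <- rho[2, 1] <- 0.5
  s <- fluctuation_spec(ref, rho, 0.4, 50, rng_seed = 77L)
  e1 <- gen_fluctuation_ensemble(s)
  e2 <- gen_fluctuation_ensemble(s)
  expect_identical(e1$traj$replicates, e2$traj$replicates)

  expect_error(fluctuation_spec(ref, rho, 0, 50), "sigma")
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3)
  expect_error(fluctuation_spec(matrix(0, 3, 3), bad, 0.5, 50),
               "positive semi-definite")
  asym <- rho; asym[1, 2] <- 0.2
  expect_error(fluctuation_spec(ref, asym, 0.5, 50), "symmetric")
})

test_that("sampled ensembles reproduce the prescribed correlation", {
  n <- 12L
  rho <- diag(1, n)
  rho[3, 7] <- rho[7, 3] <- 0.9
  spec <- fluctuation_spec(matrix(stats::rnorm(n * 3) * 8, n, 3), rho, 0.5,
                           5000L, rng_seed = 20220209L)
  ens <- gen_fluctuation_ensemble(spec)
  C <- compute_dccm(ens$traj, ens$model, reference = NULL)$C
  expect_lt(abs(C[3, 7] - 0.9), 0.03)
  off <- abs(C[upper.tri(C)])[rho[upper.tri(rho)] == 0]
  expect_gte(mean(off < 0.05), 0.99)
})

test_that("furanose torsion generator follows the pseudorotation formula", {
  nu <- gen_furanose_ring(18, 35)
  expect_equal(unname(nu["nu2"]), 35 * cospi(18 / 180), tolerance = 1e-12)
  # the torsion two bonds around the ring at P = 18 is 35 cos(306) = 20.57
  expect_equal(unname(nu["nu4"]), 20.57, tolerance = 5e-3)
  expect_identical(unname(gen_furanose_ring(0, 0)), rep(0, 5))
  expect_equal(unname(gen_furanose_ring(198, 35)), -unname(nu),
               tolerance = 1e-12)
  expect_error(gen_furanose_ring(360, 35), "\\[0, 360\\)")
  expect_error(gen_furanose_ring(18, -1), ">= 0")
})

test_that("hydrogen-bond scenes reproduce the requested geometry exactly", {
  sc <- gen_hbond_scene(3.4, 150, n_frames = 2L)
  x <- sc$traj$replicates[[1]][1, , ]
  d_idx <- which(sc$model$atoms$atom_name == "N3")
  h_idx <- which(sc$model$atoms$atom_name == "H31")
  a_idx <- which(sc$model$atoms$atom_name == "O2")
  d <- sqrt(sum((x[d_idx, ] - x[a_idx, ])^2))
  v1 <- x[d_idx, ] - x[h_idx, ]; v2 <- x[a_idx, ] - x[h_idx, ]
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(d, 3.4, tolerance = 1e-9)
  expect_equal(ang, 150, tolerance = 1e-9)
  expect_error(gen_hbond_scene(3.4, 200), "geometry error")

  sc70 <- gen_hbond_scene(3.4, 150, n_frames = 100L, fraction = 0.7)
  present <- apply(sc70$traj$replicates[[1]], 1L, function(fr)
    sqrt(sum((fr[1, ] - fr[nrow(fr), ])^2)) < 3.5)
  expect_identical(sum(present), 70L)
})

test_that("toy aptamer is deterministic with full region coverage", {
  a1 <- gen_toy_aptamer(40L, 7L)
  a2 <- gen_toy_aptamer(40L, 7L)
  expect_identical(a1, a2)
  expect_setequal(names(a1$map),
                  c("P1", "J1/2", "P2", "L2", "J2/3", "P3", "L3", "J3/1",
                    "Ligand"))
  expect_true(all(vapply(a1$map, length, integer(1)) > 0L))
  expect_true(all(vapply(gen_toy_aptamer(12L, 7L)$map, length, integer(1)) > 0L))
  expect_error(gen_toy_aptamer(11L), ">= 12")

  lig_atoms <- function(x) {
    lig <- which(x$model$residues$is_ligand)
    x$model$atoms$atom_name[x$model$atoms$residue_index == lig]
  }
  expect_false("O2'" %in% lig_atoms(a1))                      # dG-like
  expect_true("O2'" %in% lig_atoms(gen_toy_aptamer(40L, 7L, ligand = "rG")))
  expect_true(all(c("N1", "N2", "N3", "O6", "C1'", "O4'", "O5'") %in%
                    lig_atoms(a1)))
})
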