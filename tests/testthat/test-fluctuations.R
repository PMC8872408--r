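test_that("Kabsch superposition recovers rigid motions and stays proper", {
  set.seed(31)
  a <- matrix(stats::rnorm(60), 20, 3)
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  b <- a %*% t(R) + matrix(c(1, 2, 3), 20, 3, byrow = TRUE)
  fit <- kabsch_superpose(b, a)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  ident <- kabsch_superpose(a, a)
  expect_equal(ident$rotation, diag(3), tolerance = 1e-10)
  expect_equal(ident$translation, c(0, 0, 0), tolerance = 1e-10)

  # mirror image: an improper fit could reach zero, the proper one cannot
  refl <- a; refl[, 1] <- -refl[, 1]
  fit_r <- kabsch_superpose(refl, a)
  expect_equal(det(fit_r$rotation), 1, tolerance = 1e-10)
  expect_gt(fit_r$rmsd, 0.1)
  # SVD oracle allowing improper rotation achieves a strictly better fit
  A <- t(scale(refl, scale = FALSE)) %*% scale(a, scale = FALSE)
  s <- svd(A)
  expect_lt(det(s$v %*% t(s$u)), 0)

  expect_error(kabsch_superpose(b, a, fit_indices = 1:2), "degenerate")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line + 1), "collinear")
})

test_that("agrees with the bio3d fitting oracle on noisy data", {
  set.seed(8)
  a <- matrix(stats::rnorm(45), 15, 3)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  b <- a %*% t(R) + matrix(c(3, -1, 2), 15, 3, byrow = TRUE) +
    matrix(stats::rnorm(45, sd = 0.1), 15, 3)
  mine <- kabsch_superpose(b, a)
  fitted <- bio3d::fit.xyz(as.vector(t(a)), as.vector(t(b)), 1:45, 1:45)
  oracle <- sqrt(mean(rowSums((matrix(fitted, 15, 3, byrow = TRUE) - a)^2)))
  expect_equal(mine$rmsd, oracle, tolerance = 1e-6)
})

test_that("RMSD series satisfies the closed-form contracts", {
  m <- toy_three_residue_model()
  heavy <- select_atoms(m, heavy = TRUE)
  expect_lt(max(rmsd_series(static_traj(m, 4L), m, heavy)$rmsd), 1e-8)

  # rigid global motion vanishes after fitting
  nf <- 4L
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  frames <- array(NA_real_, dim = c(nf, 60, 3))
  for (f in seq_len(nf))
    frames[f, , ] <- m$coords %*% t(R) + matrix(c(5, -2, f), 60, 3, byrow = TRUE)
  tr <- trajectory_ensemble(list(frames), m)
  expect_lt(max(rmsd_series(tr, m, heavy)$rmsd), 1e-8)

  # one displaced atom with the fit held by the others: RMSD = d / sqrt(N)
  d <- 1.7
  fr <- array(rep(m$coords, each = 2L), dim = c(2, 60, 3))
  fr[, heavy[1], 1] <- fr[, heavy[1], 1] + d
  tr2 <- trajectory_ensemble(list(fr), m)
  s <- rmsd_series(tr2, m, heavy, fit_selection = heavy[-1])
  expect_equal(s$mean, d / sqrt(length(heavy)), tolerance = 1e-9)

  expect_error(rmsd_series(static_traj(m), m, integer()), "zero atoms")
})

test_that("RMSF recovers the isotropic-jitter closed form", {
  m <- toy_three_residue_model()
  set.seed(99)
  nf <- 10000L
  sigma <- 0.3
  res1 <- which(m$atoms$residue_index == 1L)
  frames <- array(rep(m$coords, each = nf), dim = c(nf, 60, 3))
  frames[, res1, ] <- frames[, res1, ] +
    stats::rnorm(nf * length(res1) * 3, sd = sigma)
  tr <- trajectory_ensemble(list(frames), m)
  others <- select_atoms(m, heavy = TRUE, residues = 2:3)
  pr <- rmsf_profile(tr, m, fit_selection = others)
  expect_equal(pr$rmsf[1], sqrt(3) * sigma, tolerance = 0.02)
  expect_lt(max(pr$rmsf[-1]), 1e-8)

  # doubling sigma doubles the fluctuation (linearity)
  frames2 <- array(rep(m$coords, each = nf), dim = c(nf, 60, 3))
  set.seed(99)
  frames2[, res1, ] <- frames2[, res1, ] +
    stats::rnorm(nf * length(res1) * 3, sd = 2 * sigma)
  pr2 <- rmsf_profile(trajectory_ensemble(list(frames2), m), m,
                      fit_selection = others)
  expect_equal(pr2$rmsf[1] / pr$rmsf[1], 2, tolerance = 0.02)
})

test_that("RMSF pools replicates irrespective of their order", {
  m <- toy_three_residue_model()
  set.seed(12)
  mk <- function() array(rep(m$coords, each = 50L), dim = c(50, 60, 3)) +
    stats::rnorm(50 * 60 * 3, sd = 0.2)
  r1 <- mk(); r2 <- mk()
  p12 <- rmsf_profile(trajectory_ensemble(list(r1, r2), m), m)
  p21 <- rmsf_profile(trajectory_ensemble(list(r2, r1), m), m)
  expect_equal(p12$rmsf, p21$rmsf, tolerance = 1e-10)
})

test_that("substructure table fits each region to its own atoms", {
  toy <- gen_toy_aptamer(24L, 5L)
  m <- toy$model
  # displace region P1 rigidly: its own-fit RMSD stays zero while the
  # whole-RNA row sees the deformation
  p1_atoms <- select_atoms(m, region = "P1", map = toy$map)
  fr <- array(rep(m$coords, each = 2L), dim = c(2, nrow(m$atoms), 3))
  fr[, p1_atoms, 1] <- fr[, p1_atoms, 1] + 4
  tr <- trajectory_ensemble(list(fr), m)
  tb <- rmsd_table(tr, m, toy$map)
  expect_lt(tb$mean_rmsd[tb$region == "P1"], 1e-8)
  expect_gt(tb$mean_rmsd[tb$region == "RNA"], 0.5)
  expect_true(all(c("sd_rmsd", "sem_rmsd") %in% names(tb)))
})
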