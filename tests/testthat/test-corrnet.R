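two_node_dccm <- function(series_a, series_b, ref) {
  # helper: build a 2-residue model and trajectory from 1-D displacement
  # series applied along x
  m <- structure_model(c("C1'", "C1'"), c("C", "C"), c("A", "A"), 1:2,
                       c("G", "G"), ref)
  nf <- length(series_a)
  frames <- array(rep(ref, each = nf), dim = c(nf, 2, 3))
  frames[, 1, 1] <- frames[, 1, 1] + series_a
  frames[, 2, 1] <- frames[, 2, 1] + series_b
  compute_dccm(trajectory_ensemble(list(frames), m), m, reference = NULL)
}

test_that("perfectly coupled and anti-coupled nodes give +1 / -1", {
  s <- stats::rnorm(50)
  ref <- matrix(c(0, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(two_node_dccm(s, s, ref)$C[1, 2], 1, tolerance = 1e-12)
  expect_equal(two_node_dccm(s, -s, ref)$C[1, 2], -1, tolerance = 1e-12)
  expect_error(two_node_dccm(s, rep(0, 50), ref), "zero variance")
})

test_that("estimator recovers a prescribed 0.6 correlation and matches bio3d", {
  n <- 8L
  rho <- diag(1, n); rho[2, 5] <- rho[5, 2] <- 0.6
  spec <- fluctuation_spec(matrix(stats::rnorm(n * 3) * 6, n, 3), rho, 0.5,
                           5000L, rng_seed = 20220209L)
  ens <- gen_fluctuation_ensemble(spec)
  C <- compute_dccm(ens$traj, ens$model, reference = NULL)$C
  expect_gte(C[2, 5], 0.57)
  expect_lte(C[2, 5], 0.63)
  expect_equal(max(abs(C - t(C))), 0, tolerance = 1e-12)
  expect_equal(unname(diag(C)), rep(1, n))

  fr <- ens$traj$replicates[[1]]
  xyz <- matrix(NA_real_, dim(fr)[1], 3 * n)
  for (k in 1:3) xyz[, seq(k, by = 3, length.out = n)] <- fr[, , k]
  expect_equal(max(abs(C - bio3d::dccm.xyz(xyz))), 0, tolerance = 1e-10)
})

test_that("consensus is the element-wise mean with validated inputs", {
  C1 <- diag(1, 3); C1[1, 2] <- C1[2, 1] <- 0.5
  d1 <- structure(list(C = C1, nodes = c("a", "b", "c")), class = "dccm")
  expect_identical(consensus_dccm(list(d1, d1, d1, d1))$C, C1)
  expect_identical(consensus_dccm(list(d1))$C, C1)

  C2 <- diag(1, 3); C2[1, 2] <- C2[2, 1] <- -0.5
  d2 <- structure(list(C = C2, nodes = c("a", "b", "c")), class = "dccm")
  expect_identical(consensus_dccm(list(d1, d2))$C[1, 2], 0)

  d3 <- structure(list(C = C1, nodes = c("a", "b", "X")), class = "dccm")
  expect_error(consensus_dccm(list(d1, d3)), "node lists differ")
})

test_that("contact filter applies distance, persistence and exclusion rules", {
  ring_names <- c("C1'", "C1'", "C1'")
  mk <- function(d13) {
    structure_model(ring_names, rep("C", 3), rep("A", 3), 1:3, rep("G", 3),
                    matrix(c(0, 0, 0, 5, 0, 0, d13, 0, 0), 3, 3, byrow = TRUE))
  }
  m <- mk(15)
  cm <- contact_map(static_traj(m, 4L), m)
  expect_true(cm$contacts[1, 2])    # 5 A apart
  expect_false(cm$contacts[1, 3])   # 15 A apart
  expect_false(any(diag(cm$contacts)))

  # within cutoff in only 50% of frames at fraction 0.75: not a contact
  frames <- array(rep(m$coords, each = 4L), dim = c(4, 3, 3))
  frames[3:4, 3, 1] <- 8
  tr <- trajectory_ensemble(list(frames), m)
  cm2 <- contact_map(tr, m, frame_fraction = 0.75)
  expect_false(cm2$contacts[1, 3])
  cm3 <- contact_map(tr, m, frame_fraction = 0.5)
  expect_true(cm3$contacts[1, 3])

  cm4 <- contact_map(static_traj(m, 4L), m, neighbor_exclusion = 1L)
  expect_false(cm4$contacts[1, 2])
})

test_that("edge weights follow w = -ln|C| with exact landmark values", {
  C <- diag(1, 3)
  C[1, 2] <- C[2, 1] <- 1
  C[1, 3] <- C[3, 1] <- exp(-1)
  C[2, 3] <- C[3, 2] <- 0.5
  net <- make_net(C)
  w <- net$edges$w[order(net$edges$i, net$edges$j)]
  expect_identical(w[1], 0)          # |C| = 1
  expect_identical(w[2], 1)          # |C| = e^-1
  expect_equal(w[3], -log(0.5), tolerance = 1e-15)
  # monotone: larger |C| gives strictly smaller weight
  expect_true(all(diff(net$edges$w[order(-abs(net$edges$C))]) >= 0))
})

test_that("edge-count equalization keeps exactly the top-|C| contact pairs", {
  set.seed(13)
  n <- 5L
  C <- random_corr_graph(n, p_extra = 1)
  d <- structure(list(C = C, nodes = as.character(1:n)), class = "dccm")
  net <- build_network(d, target_edges = 4L)
  expect_identical(nrow(net$edges), 4L)
  # brute-force ranking oracle
  ut <- which(upper.tri(C), arr.ind = TRUE)
  ord <- order(-abs(C[ut]), ut[, 1], ut[, 2])
  expected <- ut[ord[1:4], , drop = FALSE]
  expected <- expected[order(expected[, 1], expected[, 2]), , drop = FALSE]
  expect_identical(cbind(net$edges$i, net$edges$j), unname(expected))

  expect_error(build_network(d, target_edges = 100L), "infeasible")
})

test_that("network construction is deterministic end to end", {
  toy <- gen_toy_aptamer(16L, 2L)
  mk <- function() {
    tr <- gen_system_trajectory(toy$model, diag(1, 16), n_frames = 30L,
                                rng_seed = 6L)
    d <- compute_dccm(tr, toy$model)
    cm <- contact_map(tr, toy$model)
    build_network(d, cm, target_edges = 15L)
  }
  expect_identical(mk(), mk())
})
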