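test_that("hydrogen-bond criterion truth table is exact", {
  for (d in c(3.4, 3.6))
    for (ang in c(110, 121, 150)) {
      sc <- gen_hbond_scene(d, ang, n_frames = 2L)
      hits <- detect_hbonds_frame(sc$traj$replicates[[1]][1, , ], sc$model)
      expect_identical(nrow(hits), as.integer(d < 3.5 && ang > 120),
                       info = sprintf("d=%.1f angle=%d", d, ang))
    }
})

test_that("occupancy counts scripted frames exactly and sorts stably", {
  sc <- gen_hbond_scene(3.4, 150, n_frames = 100L, fraction = 0.7)
  hb <- hbond_occupancy(sc$traj, sc$model)
  expect_identical(nrow(hb), 1L)
  expect_identical(hb$occupancy, 0.7)

  # never-formed pair absent
  sc0 <- gen_hbond_scene(3.6, 150, n_frames = 10L)
  expect_identical(nrow(hbond_occupancy(sc0$traj, sc0$model)), 0L)

  # two hydrogens of one donor to one acceptor: triple-level bookkeeping
  sc2 <- gen_hbond_scene(3.4, 150, n_frames = 4L, n_hydrogens = 2L)
  hb2 <- hbond_occupancy(sc2$traj, sc2$model)
  expect_identical(nrow(hb2), 2L)
  expect_identical(hb2$occupancy, c(1, 1))
  expect_identical(hb2$donor[1], hb2$donor[2])
  expect_false(hb2$h[1] == hb2$h[2])
})

test_that("detection matches a brute-force all-pairs enumeration", {
  # jittered base-pair scenes; oracle loops every (donor, H, acceptor) triple
  bp <- gen_basepair_scene(n_cis = 2L)
  m <- bp$model
  bonded <- aptanet:::bonded_hydrogens(m)
  set.seed(7)
  n_nonempty <- 0L
  for (trial in 1:8) {
    frame <- bp$traj$replicates[[1]][1, , ] +
      stats::rnorm(length(m$coords), sd = 0.3)
    mine <- detect_hbonds_frame(frame, m, bonded = bonded)
    mine <- as.matrix(mine[order(mine$donor, mine$h, mine$acceptor), ,
                           drop = FALSE])
    storage.mode(mine) <- "integer"

    polar <- which(m$atoms$element %in% c("N", "O"))
    oracle <- list()
    for (d in polar) for (h in bonded[[as.character(d)]]) for (a in polar) {
      if (a == d) next
      if (m$atoms$residue_index[a] == m$atoms$residue_index[d]) next
      if (sqrt(sum((frame[d, ] - frame[a, ])^2)) >= 3.5) next
      v1 <- frame[d, ] - frame[h, ]; v2 <- frame[a, ] - frame[h, ]
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (ang > 120) oracle[[length(oracle) + 1L]] <- c(d, h, a)
    }
    oracle <- if (length(oracle)) do.call(rbind, oracle) else
      matrix(integer(), 0, 3)
    storage.mode(oracle) <- "integer"
    oracle <- oracle[order(oracle[, 1], oracle[, 2], oracle[, 3]), ,
                     drop = FALSE]
    expect_identical(unname(mine), unname(oracle))
    if (nrow(oracle)) n_nonempty <- n_nonempty + 1L
  }
  expect_gt(n_nonempty, 0L)  # the comparison actually exercised hits
})

test_that("detection is invariant under rigid motion of the frame", {
  sc <- gen_hbond_scene(3.4, 150, n_frames = 2L)
  fr <- sc$traj$replicates[[1]][1, , ]
  th <- 1.3
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- fr %*% t(R) + matrix(c(-3, 8, 1), nrow(fr), 3, byrow = TRUE)
  h1 <- detect_hbonds_frame(fr, sc$model)
  h2 <- detect_hbonds_frame(moved, sc$model)
  expect_identical(h1, h2)
})

test_that("hydrogen-free models are rejected for hydrogen-bond analysis", {
  m <- toy_three_residue_model()
  heavy <- select_atoms(m, heavy = TRUE)
  m2 <- structure_model(m$atoms$atom_name[heavy], m$atoms$element[heavy],
                        m$atoms$chain[heavy], m$atoms$resnum[heavy],
                        m$atoms$resname[heavy], m$coords[heavy, ])
  expect_error(detect_hbonds_frame(m2$coords, m2), "no hydrogens")
})

test_that("canonical G-C geometry is annotated cis Watson-Crick/Watson-Crick", {
  bp <- gen_basepair_scene(n_cis = 2L)
  pa <- annotate_pairs_frame(bp$traj$replicates[[1]][1, , ], bp$model)
  expect_identical(nrow(pa), 1L)
  expect_identical(pa$edge_i, "Watson-Crick")
  expect_identical(pa$edge_j, "Watson-Crick")
  expect_identical(pa$orientation, "cis")
  expect_gte(pa$n_hbonds, 3L)

  # separated bases are not a pair
  ab <- gen_basepair_scene(n_cis = 1L, n_absent = 1L)
  expect_identical(nrow(annotate_pairs_frame(ab$traj$replicates[[1]][2, , ],
                                             ab$model)), 0L)
})

test_that("Hoogsteen-edge docking is classified by edge majority vote", {
  hg <- gen_basepair_scene(n_cis = 2L, edge = "hoogsteen")
  pa <- annotate_pairs_frame(hg$traj$replicates[[1]][1, , ], hg$model)
  expect_identical(nrow(pa), 1L)
  expect_identical(pa$edge_i, "Hoogsteen")      # guanine side: N7/O6
  expect_identical(pa$edge_j, "Watson-Crick")   # cytosine side: N3/N4
})

test_that("stacking thresholds behave as declared", {
  stacked <- function(d, ang, off) {
    sc <- gen_stack_scene(d, ang, off)
    nrow(annotate_stacking_frame(sc$traj$replicates[[1]][1, , ], sc$model))
  }
  expect_identical(stacked(3.4, 0, 0), 1L)
  expect_identical(stacked(3.4, 90, 0), 0L)
  expect_identical(stacked(3.4, 0, 3.0), 0L)
  expect_identical(stacked(5.0, 0, 0), 0L)
})

test_that("occupancy map splits cis/trans interchange into separate records", {
  bt <- gen_basepair_scene(n_cis = 60L, n_trans = 40L)
  am <- interaction_occupancy_map(bt$traj, bt$model)
  pairs <- as.data.frame(am$pairs)
  expect_identical(nrow(pairs), 2L)
  expect_identical(pairs$orientation, c("cis", "trans"))
  expect_identical(pairs$occupancy, c(0.6, 0.4))
  expect_lte(sum(pairs$occupancy), 1)

  # static pair holds occupancy 1.0
  st <- gen_basepair_scene(n_cis = 5L)
  am2 <- interaction_occupancy_map(st$traj, st$model)
  expect_identical(as.data.frame(am2$pairs)$occupancy, 1)

  expect_error(interaction_occupancy_map(bt$traj, bt$model,
                                         analysis_window(200, 300)),
               "out of bounds")
})
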