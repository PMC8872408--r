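test_that("structure model enforces its invariants", {
  expect_error(
    structure_model("C1'", "C", "A", 1L, "G", matrix(0, 1, 3)),
    "at least 2 residues")
  expect_error(
    structure_model(c("C1", "C2"), c("C", "C"), c("A", "A"), c(1L, 2L),
                    c("G", "C"), matrix(c(0, NA, 1, 1, 1, 1), 2, 3)),
    "finite")
  # interleaved residues rejected
  expect_error(
    structure_model(c("C1", "C2", "C3"), c("C", "C", "C"), rep("A", 3),
                    c(1L, 2L, 1L), c("G", "C", "G"), matrix(1, 3, 3)),
    "contiguous")
  # hydrogen-only residue rejected
  expect_error(
    structure_model(c("C1", "H1"), c("C", "H"), c("A", "A"), c(1L, 2L),
                    c("G", "C"), matrix(1, 2, 3)),
    "heavy")
})

test_that("atom selection resolves predicates and is idempotent", {
  m <- toy_three_residue_model()
  heavy <- select_atoms(m, heavy = TRUE)
  expect_length(heavy, 50L)  # 60 atoms minus 10 hydrogens
  expect_identical(heavy, select_atoms(m, heavy = TRUE))
  expect_true(all(diff(heavy) > 0))

  r1 <- select_atoms(m, residues = 1L)
  expect_length(r1, 20L)
  expect_identical(m$atoms$residue_index[r1], rep(1L, 20L))

  toy <- gen_toy_aptamer(20L, 11L)
  p1 <- select_atoms(toy$model, region = "P1", map = toy$map, heavy = TRUE)
  in_p1 <- toy$model$atoms$residue_index %in% toy$map$P1
  expect_identical(p1, which(in_p1 & toy$model$atoms$element != "H"))
})

test_that("unknown selection tokens raise resolution errors naming them", {
  m <- toy_three_residue_model()
  toy <- gen_toy_aptamer(20L, 11L)
  expect_error(select_atoms(toy$model, region = "P9", map = toy$map), "P9")
  expect_error(select_atoms(m, residues = "A:X99"), "A:X99")
  expect_error(select_atoms(m, atom_names = "O2'"), "O2'")
  # dG-like ligand genuinely lacks O2'
  lig <- which(toy$model$residues$is_ligand)
  expect_error(
    select_atoms(toy$model, residues = lig, atom_names = "O2'"), "O2'")
})

test_that("window concatenation stacks replicates in order, bit-exactly", {
  m <- toy_three_residue_model()
  reps <- lapply(1:4, function(r) {
    fr <- array(stats::rnorm(100 * 60 * 3), dim = c(100, 60, 3))
    fr
  })
  tr <- trajectory_ensemble(reps, m)
  w <- analysis_window(50, 100)
  cc <- concat_window(tr, w)
  expect_identical(dim(cc), c(200L, 60L, 3L))
  expect_identical(cc[1:50, , ], reps[[1]][51:100, , ])
  expect_identical(cc[151:200, , ], reps[[4]][51:100, , ])
  expect_identical(attr(cc, "replicate"), rep(1:4, each = 50L))

  one <- trajectory_ensemble(reps[1], m)
  expect_identical(concat_window(one, full_window(one))[, , ], reps[[1]])

  short <- trajectory_ensemble(list(reps[[1]][1:80, , ]), m)
  expect_error(concat_window(short, analysis_window(90, 100)), "replicate 1")
})

test_that("analysis window validates its bounds", {
  expect_error(analysis_window(-1, 10), "0 <= start < end")
  expect_error(analysis_window(10, 10), "0 <= start < end")
})
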