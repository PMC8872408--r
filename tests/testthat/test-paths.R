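test_that("trivial graphs yield the only possible paths", {
  C <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  net <- make_net(C)
  pe <- yen_k_shortest(net, 1, 2, k = 5L)
  expect_length(pe$paths, 1L)
  expect_identical(pe$paths[[1]], c(1L, 2L))
  expect_equal(pe$lengths, -log(0.5), tolerance = 1e-15)

  expect_error(yen_k_shortest(net, 1, 1), "differ")
  C4 <- diag(1, 4); C4[1, 2] <- C4[2, 1] <- 0.9; C4[3, 4] <- C4[4, 3] <- 0.9
  expect_error(yen_k_shortest(make_net(C4), 1, 4), "disconnected")
})

test_that("complete-graph enumeration matches Yen exactly", {
  set.seed(21)
  C <- random_corr_graph(4L, p_extra = 1)
  net <- make_net(C)
  y <- yen_k_shortest(net, 1, 4, k = 10L)
  e <- enumerate_simple_paths(net, 1, 4)
  expect_length(e$paths, 5L)  # all simple 1->4 paths in K4
  expect_identical(y$paths, e$paths)
  expect_equal(y$lengths, e$lengths, tolerance = 0)
  expect_true(all(diff(y$lengths) >= 0))
})

test_that("Yen reproduces brute force on random connected graphs", {
  set.seed(20220209)
  for (g in 1:30) {
    n <- sample(4:8, 1L)
    net <- make_net(random_corr_graph(n))
    y <- yen_k_shortest(net, 1, n, k = 20L)
    e <- enumerate_simple_paths(net, 1, n)
    keep <- seq_len(min(20L, length(e$paths)))
    expect_identical(y$paths, e$paths[keep])
    expect_equal(y$lengths, e$lengths[keep], tolerance = 0)
  }
})

test_that("shortest length agrees with the igraph oracle on a larger graph", {
  skip_if_not_installed("igraph")
  set.seed(5)
  n <- 30L
  C <- random_corr_graph(n, p_extra = 0.2)
  net <- make_net(C)
  y <- yen_k_shortest(net, 1, n, k = 1L)
  g <- igraph::graph_from_data_frame(net$edges[, c("i", "j")],
                                     directed = FALSE,
                                     vertices = data.frame(name = 1:n))
  d <- igraph::distances(g, v = "1", to = as.character(n),
                         weights = net$edges$w)
  expect_equal(y$lengths[1], as.numeric(d), tolerance = 1e-12)
})

test_that("degeneracy counts node membership with unit endpoints", {
  pe <- structure(list(paths = list(c(1L, 2L, 4L), c(1L, 3L, 4L),
                                    c(1L, 2L, 3L, 4L)),
                       lengths = c(1, 1.5, 2), source = 1L, target = 4L,
                       nodes = c("a", "b", "c", "d"), n_nodes = 4L),
                  class = "path_ensemble")
  d <- node_degeneracy(pe)
  expect_equal(unname(d$fraction), c(1, 2 / 3, 2 / 3, 1))
  expect_identical(unname(d$fraction[5 - 1]), 1)
  empty <- pe; empty$paths <- list()
  expect_error(node_degeneracy(empty), "empty")
})

test_that("nodes-per-path histogram exposes corridor bimodality", {
  pe <- structure(list(paths = list(1:3, c(1L, 4L, 3L), 1:5),
                       lengths = 1:3, source = 1L, target = 3L,
                       nodes = letters[1:5], n_nodes = 5L),
                  class = "path_ensemble")
  h <- path_node_counts(pe)
  expect_identical(as.integer(h$counts), c(2L, 1L))
  expect_identical(names(h$counts), c("3", "5"))
  expect_identical(h$modes, 3L)

  # engineered short and long corridors between source and target
  n <- 9L
  C <- diag(1, n)
  link <- function(i, j, v) C[i, j] <<- C[j, i] <<- v
  link(1, 2, 0.9); link(2, 9, 0.9)                    # 3-node corridor
  for (k in 3:7) link(k, k + 1, 0.95)
  link(1, 3, 0.95); link(8, 9, 0.95)                  # 8-node corridor
  pe2 <- yen_k_shortest(make_net(C), 1, 9, k = 2L)
  h2 <- path_node_counts(pe2)
  expect_setequal(as.integer(names(h2$counts)), c(3L, 8L))
})

test_that("SIP formula, symmetry and scale invariance hold", {
  expect_identical(sip(c(1, 1, 0), c(1, 0, 1)), 0.25)
  expect_identical(sip(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_identical(sip(c(1, 0, 0), c(0, 1, 0)), 0)
  d1 <- stats::runif(10); d2 <- stats::runif(10)
  expect_equal(sip(d1, d2), sip(d2, d1), tolerance = 1e-15)
  expect_equal(sip(3.7 * d1, d2), sip(d1, d2), tolerance = 1e-12)
  expect_error(sip(c(0, 0), c(1, 0)), "zero-norm")
  expect_error(sip(c(1, 0), c(1, 0, 0)), "node universes")
})
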