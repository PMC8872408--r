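# shared fixture builders; everything generated in code, no stored data

# trajectory of nf identical copies of the model's reference coordinates
static_traj <- function(model, nf = 3L) {
  frames <- array(rep(model$coords, each = nf),
                  dim = c(nf, nrow(model$atoms), 3L))
  trajectory_ensemble(list(frames), model)
}

# wrap a correlation matrix as a dccm and build the unfiltered network
make_net <- function(C, nodes = as.character(seq_len(nrow(C)))) {
  build_network(structure(list(C = C, nodes = nodes), class = "dccm"))
}

# random connected weighted graph as a correlation matrix (chain backbone
# guarantees connectivity); |C| in (0, 1) so weights are finite
random_corr_graph <- function(n, p_extra = 0.5) {
  C <- matrix(0, n, n)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      if (j == i + 1L || stats::runif(1) < p_extra) {
        v <- stats::runif(1, 0.05, 0.99)
        C[i, j] <- C[j, i] <- v
      }
  diag(C) <- 1
  C
}

# tiny 3-residue model: 60 atoms of which 10 are hydrogens
toy_three_residue_model <- function() {
  n_h <- c(4L, 3L, 3L)
  atom_name <- unlist(lapply(1:3, function(r)
    c(sprintf("C%d", seq_len(18L - n_h[r])), sprintf("O%d", 1:2),
      sprintf("H%d", seq_len(n_h[r])))))
  element <- unlist(lapply(1:3, function(r)
    c(rep("C", 18L - n_h[r]), rep("O", 2), rep("H", n_h[r]))))
  ang <- seq_len(60L)
  coords <- cbind(5 * cos(ang), 5 * sin(ang), ang / 3)
  structure_model(atom_name, element, rep("A", 60),
                  rep(1:3, each = 20L), rep(c("G", "C", "U"), each = 20L),
                  coords)
}
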