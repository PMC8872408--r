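#' Dynamic cross-correlation matrix over nucleotide nodes
#'
#' Each frame is superposed onto the reference over `fit_selection` (heavy
#' atoms by default), one representative atom per residue (C1' by default,
#' configurable to any atom name or `"centroid"` of heavy atoms) provides the
#' node position, and
#' `C(i,j) = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)` with displacements
#' taken from the window-mean node positions.
#'
#' @param traj a `trajectory_ensemble`.
#' @param model matching `structure_model`.
#' @param reference reference coordinates for superposition; default the
#'   model's. `NULL` skips fitting (already-aligned or node-level input).
#' @param window an `analysis_window`.
#' @param representation `"centroid"` or an atom name present in every
#'   residue.
#' @param fit_selection atoms used for superposition.
#' @param replicate restrict to one replicate index (default: all,
#'   concatenated).
#' @return object of class `dccm`: list with `C` (symmetric, unit diagonal),
#'   `nodes` (residue labels).
#' @export
compute_dccm <- function(traj, model, reference = model$coords,
                         window = full_window(traj),
                         representation = "C1'",
                         fit_selection = select_atoms(model, heavy = TRUE),
                         replicate = NULL) {
  frames <- if (is.null(replicate)) concat_window(traj, window) else {
    check_window(traj, window)
    sel <- (window$start + 1L):window$end
    traj$replicates[[replicate]][sel, , , drop = FALSE]
  }
  nf <- dim(frames)[1L]
  if (nf < 2L) stop("need at least 2 frames for a correlation matrix")
  if (!is.null(reference))
    for (f in seq_len(nf))
      frames[f, , ] <- kabsch_superpose(frames[f, , , drop = TRUE],
                                        reference, fit_selection)$coords
  nres <- n_residues(model)
  node_xyz <- array(NA_real_, dim = c(nf, nres, 3L))
  if (identical(representation, "centroid")) {
    heavy <- model$atoms$element != "H"
    for (r in seq_len(nres)) {
      idx <- which(model$atoms$residue_index == r & heavy)
      node_xyz[, r, ] <- apply(frames[, idx, , drop = FALSE], c(1L, 3L), mean)
    }
  } else {
    for (r in seq_len(nres)) {
      idx <- which(model$atoms$residue_index == r &
                     model$atoms$atom_name == representation)
      if (length(idx) != 1L)
        stop("representation atom '", representation,
             "' not found in residue ", residue_labels(model)[r])
      node_xyz[, r, ] <- frames[, idx, ]
    }
  }
  dccm_from_nodes(node_xyz, residue_labels(model))
}

# C from a frames x nodes x 3 displacement source
dccm_from_nodes <- function(node_xyz, nodes) {
  nf <- dim(node_xyz)[1L]; n <- dim(node_xyz)[2L]
  cov_sum <- matrix(0, n, n)
  for (k in 1:3) {
    x <- node_xyz[, , k]
    x <- sweep(x, 2L, colMeans(x))
    cov_sum <- cov_sum + crossprod(x) / nf
  }
  v <- diag(cov_sum)
  zero <- which(v <= 0 | !is.finite(v))
  if (length(zero))
    stop("undefined correlation: node ", nodes[zero[1L]], " has zero variance")
  C <- cov_sum / sqrt(outer(v, v))
  C <- (C + t(C)) / 2
  diag(C) <- 1
  structure(list(C = C, nodes = nodes), class = "dccm")
}

#' @export
print.dccm <- function(x, ...) {
  cat(sprintf("dccm: %d nodes, |C| off-diagonal range [%.3f, %.3f]\n",
              length(x$nodes), min(abs(x$C[upper.tri(x$C)])),
              max(abs(x$C[upper.tri(x$C)]))))
  invisible(x)
}

#' Consensus of per-replicate correlation matrices
#'
#' Element-wise mean over replicate matrices sharing one node list (an
#' occasionally used alternative, the signed element-wise minimum-magnitude
#' consensus, is available via `method = "min"`).
#'
#' @param dccms list of `dccm` objects with identical node lists.
#' @param method `"mean"` (default) or `"min"` (minimum magnitude, sign of
#'   the element-wise mean).
#' @return a `dccm`.
#' @export
consensus_dccm <- function(dccms, method = c("mean", "min")) {
  method <- match.arg(method)
  stopifnot(length(dccms) >= 1L)
  nodes <- dccms[[1L]]$nodes
  for (d in dccms)
    if (!identical(d$nodes, nodes))
      stop("consensus error: node lists differ across matrices")
  mats <- lapply(dccms, `[[`, "C")
  C <- if (method == "mean") Reduce(`+`, mats) / length(mats) else {
    mag <- Reduce(pmin, lapply(mats, abs))
    sgn <- sign(Reduce(`+`, mats))
    mag * ifelse(sgn == 0, 1, sgn)
  }
  C <- (C + t(C)) / 2
  diag(C) <- 1
  structure(list(C = C, nodes = nodes), class = "dccm")
}

#' Residue contact map over an analysis window
#'
#' Residues i and j are in contact when their minimum heavy-atom distance is
#' at most `d_cut` in at least `frame_fraction` of the window frames;
#' sequence neighbours with `|i - j| <= neighbor_exclusion` are removed.
#'
#' @param traj a `trajectory_ensemble`.
#' @param model matching `structure_model`.
#' @param d_cut distance cutoff, Angstrom.
#' @param frame_fraction minimum fraction of frames.
#' @param neighbor_exclusion sequence-neighbour exclusion span.
#' @param window an `analysis_window`.
#' @return object of class `contact_map`: list with `contacts` (logical
#'   matrix, FALSE diagonal) and the parameters.
#' @export
contact_map <- function(traj, model, d_cut = 10, frame_fraction = 0.75,
                        neighbor_exclusion = 0L, window = full_window(traj)) {
  frames <- concat_window(traj, window)
  nf <- dim(frames)[1L]
  nres <- n_residues(model)
  heavy_by_res <- lapply(seq_len(nres), function(r)
    which(model$atoms$residue_index == r & model$atoms$element != "H"))
  count <- matrix(0L, nres, nres)
  for (f in seq_len(nf)) {
    fr <- frames[f, , , drop = TRUE]
    for (i in seq_len(nres - 1L)) {
      xi <- fr[heavy_by_res[[i]], , drop = FALSE]
      for (j in (i + 1L):nres) {
        xj <- fr[heavy_by_res[[j]], , drop = FALSE]
        d2 <- min(outer(rowSums(xi^2), rowSums(xj^2), `+`) - 2 * xi %*% t(xj))
        if (d2 <= d_cut^2) count[i, j] <- count[i, j] + 1L
      }
    }
  }
  contacts <- count / nf >= frame_fraction
  contacts <- contacts | t(contacts)
  if (neighbor_exclusion > 0L)
    contacts[abs(row(contacts) - col(contacts)) <= neighbor_exclusion] <- FALSE
  diag(contacts) <- FALSE
  structure(list(contacts = contacts,
                 params = list(d_cut = d_cut, frame_fraction = frame_fraction,
                               neighbor_exclusion = neighbor_exclusion)),
            class = "contact_map")
}

#' Build the contact-filtered correlation network
#'
#' Candidate edges are the contact pairs with nonzero correlation; each edge
#' carries weight `w(i,j) = -ln |C(i,j)|` (so perfectly correlated nodes are
#' zero distance apart). When `target_edges` is given, exactly that many
#' edges are kept -- the pairs of largest `|C|`, ties broken toward the lower
#' node-id pair -- which equalizes edge counts across systems.
#'
#' @param consensus a `dccm`.
#' @param contacts a `contact_map` (or NULL: all pairs are candidates).
#' @param target_edges exact edge count to keep, or NULL for all candidates.
#' @return object of class `correlation_network`: list with `nodes`, `edges`
#'   (data.frame i, j, C, w), `n_nodes`.
#' @export
build_network <- function(consensus, contacts = NULL, target_edges = NULL) {
  C <- consensus$C
  n <- nrow(C)
  keep <- if (is.null(contacts)) matrix(TRUE, n, n) else contacts$contacts
  if (!is.null(contacts) && nrow(keep) != n)
    stop("contact map and correlation matrix shapes differ")
  idx <- which(upper.tri(C) & keep & abs(C) > 0, arr.ind = TRUE)
  if (!is.null(target_edges)) {
    if (target_edges > nrow(idx))
      stop(sprintf("infeasible filter: requested %d edges but only %d contact pairs with |C| > 0 exist",
                   target_edges, nrow(idx)))
    absC <- abs(C[idx])
    ord <- order(-absC, idx[, 1L], idx[, 2L])
    idx <- idx[ord[seq_len(target_edges)], , drop = FALSE]
  }
  ord <- order(idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]
  edges <- data.frame(i = idx[, 1L], j = idx[, 2L], C = C[idx],
                      w = -log(abs(C[idx])) + 0)  # + 0 normalizes -0
  structure(list(nodes = consensus$nodes, edges = edges, n_nodes = n),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network: %d nodes, %d edges, weight range [%.3f, %.3f]\n",
              x$n_nodes, nrow(x$edges), min(x$edges$w), max(x$edges$w)))
  invisible(x)
}
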