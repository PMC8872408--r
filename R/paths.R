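# adjacency list from a correlation_network: per node, matrix of (neighbor,
# weight) sorted by neighbor id for deterministic traversal
network_adjacency <- function(network) {
  adj <- vector("list", network$n_nodes)
  e <- network$edges
  for (r in seq_len(nrow(e))) {
    adj[[e$i[r]]] <- rbind(adj[[e$i[r]]], c(as.integer(e$j[r]), e$w[r]))
    adj[[e$j[r]]] <- rbind(adj[[e$j[r]]], c(as.integer(e$i[r]), e$w[r]))
  }
  lapply(adj, function(m) if (is.null(m)) matrix(numeric(), 0L, 2L)
         else m[order(m[, 1L]), , drop = FALSE])
}

# lexicographic comparison of integer vectors; -1, 0, 1
lex_cmp <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(-1L)
    if (a[i] > b[i]) return(1L)
  }
  sign(length(a) - length(b))
}

# canonical path length: left-to-right sum of edge weights (bit-reproducible)
path_length <- function(nodes, wmat) {
  s <- 0
  for (i in seq_len(length(nodes) - 1L)) s <- s + wmat[nodes[i], nodes[i + 1L]]
  s
}

# Dijkstra returning the lexicographically smallest shortest path, honouring
# blocked nodes and blocked directed edges (keys "i|j")
dijkstra_lex <- function(adj, n, source, target, blocked_nodes = integer(),
                         blocked_edges = character()) {
  dist <- rep(Inf, n)
  paths <- vector("list", n)
  done <- rep(FALSE, n)
  done[blocked_nodes] <- TRUE
  dist[source] <- 0
  paths[[source]] <- as.integer(source)
  blocked <- if (length(blocked_edges)) new.env(parent = emptyenv()) else NULL
  for (k in blocked_edges) if (!is.null(blocked)) blocked[[k]] <- TRUE
  repeat {
    open <- which(!done & is.finite(dist))
    if (!length(open)) break
    u <- open[which.min(dist[open])]
    # among equal-distance open nodes pick any; path tie-break happens on relax
    if (u == target) break
    done[u] <- TRUE
    nb <- adj[[u]]
    for (r in seq_len(nrow(nb))) {
      v <- as.integer(nb[r, 1L])
      if (done[v]) next
      if (!is.null(blocked) &&
          (isTRUE(blocked[[paste(u, v, sep = "|")]]) ||
             isTRUE(blocked[[paste(v, u, sep = "|")]]))) next
      nd <- dist[u] + nb[r, 2L]
      cand <- c(paths[[u]], v)
      if (nd < dist[v] || (nd == dist[v] && lex_cmp(cand, paths[[v]]) < 0)) {
        dist[v] <- nd
        paths[[v]] <- cand
      }
    }
  }
  if (!is.finite(dist[target])) return(NULL)
  list(nodes = paths[[target]], length = dist[target])
}

#' Yen's k shortest loopless paths
#'
#' Deterministic suboptimal-path ensemble between two nodes of a
#' [build_network()] graph: up to `k` simple paths in non-decreasing total
#' edge weight, equal lengths ordered by lexicographic node sequence. Path
#' length is the sum of edge weights along the path.
#'
#' @param network a `correlation_network`.
#' @param source,target node indices (or node labels), distinct.
#' @param k number of paths to collect (fewer if the graph holds fewer).
#' @return object of class `path_ensemble`: list with `paths` (list of node
#'   index vectors), `lengths`, `source`, `target`, `nodes` (labels),
#'   `n_nodes`.
#' @export
yen_k_shortest <- function(network, source, target, k = 1000L) {
  source <- resolve_node(network, source)
  target <- resolve_node(network, target)
  if (source == target) stop("source and target must differ")
  n <- network$n_nodes
  adj <- network_adjacency(network)
  wmat <- matrix(NA_real_, n, n)
  e <- network$edges
  wmat[cbind(e$i, e$j)] <- e$w
  wmat[cbind(e$j, e$i)] <- e$w

  first <- dijkstra_lex(adj, n, source, target)
  if (is.null(first)) stop("no path between source and target: disconnected pair")
  first$length <- path_length(first$nodes, wmat)
  A <- list(first)
  B <- list()          # candidates
  B_keys <- character()

  kth_len <- function() {
    len <- sort(vapply(A, `[[`, numeric(1), "length"))
    len[min(k, length(len))]
  }
  repeat {
    prev <- A[[length(A)]]$nodes
    for (i in seq_len(length(prev) - 1L)) {
      spur <- prev[i]
      root <- prev[seq_len(i)]
      blocked_edges <- character()
      for (p in A) {
        pn <- p$nodes
        if (length(pn) > i && identical(pn[seq_len(i)], root))
          blocked_edges <- c(blocked_edges, paste(pn[i], pn[i + 1L], sep = "|"))
      }
      blocked_nodes <- setdiff(root, spur)
      sp <- dijkstra_lex(adj, n, spur, target, blocked_nodes, blocked_edges)
      if (is.null(sp)) next
      cand_nodes <- c(root[-length(root)], sp$nodes)
      key <- paste(cand_nodes, collapse = ",")
      if (key %in% B_keys) next
      B_keys <- c(B_keys, key)
      B[[length(B) + 1L]] <- list(nodes = cand_nodes,
                                  length = path_length(cand_nodes, wmat))
    }
    if (!length(B)) break
    # drop candidates already accepted
    acc <- vapply(A, function(p) paste(p$nodes, collapse = ","), character(1))
    live <- !vapply(B, function(p) paste(p$nodes, collapse = ","), character(1)) %in% acc
    B <- B[live]
    if (!length(B)) break
    lens <- vapply(B, `[[`, numeric(1), "length")
    best <- which(lens == min(lens))
    if (length(best) > 1L) {
      bi <- best[1L]
      for (b in best[-1L])
        if (lex_cmp(B[[b]]$nodes, B[[bi]]$nodes) < 0) bi <- b
      best <- bi
    }
    A[[length(A) + 1L]] <- B[[best]]
    B <- B[-best]
    # boundary rule: collect until the next path is strictly longer than the
    # k-th best, so equal-length ties at the cut are resolved by one sort
    if (length(A) > k && A[[length(A)]]$length > kth_len()) {
      A <- A[-length(A)]
      break
    }
  }
  ord <- order_paths(A)
  A <- A[ord][seq_len(min(k, length(A)))]
  structure(list(paths = lapply(A, `[[`, "nodes"),
                 lengths = vapply(A, `[[`, numeric(1), "length"),
                 source = source, target = target,
                 nodes = network$nodes, n_nodes = n),
            class = "path_ensemble")
}

order_paths <- function(A) {
  lens <- vapply(A, `[[`, numeric(1), "length")
  idx <- seq_along(A)
  idx[order(lens)][order_lex_within(A[order(lens)], lens[order(lens)])]
}

# stable lex ordering within equal-length groups
order_lex_within <- function(A, lens) {
  out <- seq_along(A)
  i <- 1L
  while (i <= length(A)) {
    j <- i
    while (j < length(A) && lens[j + 1L] == lens[i]) j <- j + 1L
    if (j > i) {
      grp <- i:j
      nodes <- lapply(A[grp], `[[`, "nodes")
      perm <- grp[order_lex(nodes)]
      out[grp] <- perm
    }
    i <- j + 1L
  }
  out
}

order_lex <- function(node_list) {
  n <- length(node_list)
  idx <- seq_len(n)
  if (n < 2L) return(idx)
  # insertion sort by lex_cmp (groups are small)
  for (i in 2:n) {
    j <- i
    while (j > 1L && lex_cmp(node_list[[idx[j - 1L]]], node_list[[idx[j]]]) > 0) {
      tmp <- idx[j]; idx[j] <- idx[j - 1L]; idx[j - 1L] <- tmp
      j <- j - 1L
    }
  }
  idx
}

#' @export
print.path_ensemble <- function(x, ...) {
  cat(sprintf("path_ensemble: %d paths %s -> %s, lengths [%.3f, %.3f]\n",
              length(x$paths), x$nodes[x$source], x$nodes[x$target],
              min(x$lengths), max(x$lengths)))
  invisible(x)
}

resolve_node <- function(network, node) {
  if (is.character(node)) {
    idx <- match(node, network$nodes)
    if (is.na(idx)) stop("unknown node label: '", node, "'")
    return(idx)
  }
  node <- as.integer(node)
  if (node < 1L || node > network$n_nodes) stop("node index out of range")
  node
}

#' Exhaustive simple-path enumeration (reference oracle)
#'
#' Depth-first enumeration of every simple source-to-target path, sorted by
#' total edge weight with lexicographic tie-break -- the brute-force
#' reference [yen_k_shortest()] must reproduce. Exponential in graph size;
#' intended for small graphs.
#'
#' @inheritParams yen_k_shortest
#' @return a `path_ensemble` holding every simple path.
#' @export
enumerate_simple_paths <- function(network, source, target) {
  source <- resolve_node(network, source)
  target <- resolve_node(network, target)
  n <- network$n_nodes
  adj <- network_adjacency(network)
  wmat <- matrix(NA_real_, n, n)
  e <- network$edges
  wmat[cbind(e$i, e$j)] <- e$w
  wmat[cbind(e$j, e$i)] <- e$w
  acc <- list()
  visited <- rep(FALSE, n)
  walk <- function(u, path) {
    if (u == target) {
      acc[[length(acc) + 1L]] <<- list(nodes = path,
                                       length = path_length(path, wmat))
      return(invisible())
    }
    visited[u] <<- TRUE
    for (v in as.integer(adj[[u]][, 1L]))
      if (!visited[v]) walk(v, c(path, v))
    visited[u] <<- FALSE
  }
  walk(as.integer(source), as.integer(source))
  if (!length(acc)) stop("no path between source and target: disconnected pair")
  acc <- acc[order_paths(acc)]
  structure(list(paths = lapply(acc, `[[`, "nodes"),
                 lengths = vapply(acc, `[[`, numeric(1), "length"),
                 source = source, target = target,
                 nodes = network$nodes, n_nodes = n),
            class = "path_ensemble")
}

#' Node degeneracy of a path ensemble
#'
#' Fraction of ensemble paths that pass through each node; source and target
#' are 1 by construction.
#'
#' @param paths a `path_ensemble`.
#' @return object of class `degeneracy_profile`: list with `fraction` (named
#'   numeric over all nodes), `source`, `target`, `nodes`.
#' @export
node_degeneracy <- function(paths) {
  if (!length(paths$paths)) stop("empty path ensemble")
  counts <- numeric(paths$n_nodes)
  for (p in paths$paths) counts[p] <- counts[p] + 1
  frac <- counts / length(paths$paths)
  names(frac) <- paths$nodes
  structure(list(fraction = frac, source = paths$source,
                 target = paths$target, nodes = paths$nodes),
            class = "degeneracy_profile")
}

#' Nodes-per-path histogram
#'
#' Multiset of path cardinalities (number of nodes per path) with the modal
#' count(s); a bimodal histogram signals alternative communication corridors.
#'
#' @param paths a `path_ensemble`.
#' @return list with `counts` (named table: nodes-per-path -> path count) and
#'   `modes` (integer vector of modal cardinalities).
#' @export
path_node_counts <- function(paths) {
  if (!length(paths$paths)) stop("empty path ensemble")
  card <- vapply(paths$paths, length, integer(1))
  tab <- table(card)
  modes <- as.integer(names(tab)[tab == max(tab)])
  list(counts = tab, modes = modes)
}

#' Square inner product of two degeneracy profiles
#'
#' `SIP = (d1 . d2)^2 / ((d1 . d1)(d2 . d2))`: 1 for proportional profiles,
#' 0 for orthogonal supports; symmetric and invariant to positive scaling.
#'
#' @param d1,d2 `degeneracy_profile` objects or plain numeric vectors over
#'   the same node universe.
#' @return scalar in `[0, 1]`.
#' @export
sip <- function(d1, d2) {
  v1 <- if (inherits(d1, "degeneracy_profile")) d1$fraction else as.numeric(d1)
  v2 <- if (inherits(d2, "degeneracy_profile")) d2$fraction else as.numeric(d2)
  if (length(v1) != length(v2))
    stop("degeneracy profiles are over different node universes")
  n1 <- sum(v1^2); n2 <- sum(v2^2)
  if (n1 == 0 || n2 == 0) stop("zero-norm degeneracy profile")
  sum(v1 * v2)^2 / (n1 * n2)
}
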