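# Leontis-Westhof atom-to-edge tables and ring definitions, one place for
# auditability. An atom may sit on two edges (e.g. guanine O6 on both the
# Watson-Crick and Hoogsteen edges); majority voting with WC > Hoogsteen >
# Sugar tie priority resolves the pair-level class.
LW_EDGES <- list(
  G = list(`Watson-Crick` = c("N1", "C2", "N2", "O6"),
           Hoogsteen = c("N7", "O6", "C8"),
           Sugar = c("N3", "N2", "O2'", "O4'")),
  A = list(`Watson-Crick` = c("N1", "C2", "N6"),
           Hoogsteen = c("N7", "N6", "C8"),
           Sugar = c("N3", "O2'", "O4'")),
  C = list(`Watson-Crick` = c("N3", "N4", "O2"),
           Hoogsteen = c("C5", "C6", "N4"),
           Sugar = c("O2", "O2'", "O4'")),
  U = list(`Watson-Crick` = c("N3", "O4", "O2"),
           Hoogsteen = c("C5", "C6", "O4"),
           Sugar = c("O2", "O2'", "O4'"))
)

BASE_RINGS <- list(
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  U = c("N1", "C2", "N3", "C4", "C5", "C6")
)

GLYCOSIDIC_N <- c(G = "N9", A = "N9", C = "N1", U = "N1")

# residue type for annotation: A/C/G/U by residue name; ligand residues are
# guanine-like (the 2'-deoxyguanosine/riboguanosine ligand); others NA
base_type <- function(model) {
  ty <- ifelse(model$residues$resname %in% c("A", "C", "G", "U"),
               model$residues$resname, NA_character_)
  ty[model$residues$is_ligand] <- "G"
  ty
}

res_atom_index <- function(model, residue, name) {
  idx <- which(model$atoms$residue_index == residue &
                 model$atoms$atom_name == name)
  if (length(idx)) idx[1L] else NA_integer_
}

ring_atom_indices <- function(model, residue, type) {
  nms <- BASE_RINGS[[type]]
  idx <- vapply(nms, function(n) res_atom_index(model, residue, n), integer(1))
  idx[!is.na(idx)]
}

fold_angle <- function(n1, n2) {
  a <- acos(pmin(pmax(abs(sum(n1 * n2)), 0), 1)) * 180 / pi
  a
}

#' Annotate base pairs in one frame (simplified Leontis-Westhof)
#'
#' A residue pair is annotated when (i) at least `min_hbonds` hydrogen bonds
#' (criterion of [detect_hbonds_frame()]) connect atoms of the two residues'
#' edge tables, (ii) the angle between the base-plane normals is at most
#' `max_normal_angle`, and (iii) the ring centres are within
#' `max_center_dist`. Each base's edge is the edge table holding the majority
#' of its hydrogen-bonded atoms (ties resolved Watson-Crick > Hoogsteen >
#' Sugar); the cis/trans orientation comes from the C1'-N(gly)...N(gly)-C1'
#' pseudo-dihedral (cis when its magnitude is below 90 degrees). The
#' geometric thresholds are declared heuristics, configurable here.
#'
#' @param frame n_atoms x 3 coordinates.
#' @param model matching `structure_model`.
#' @param d_cut,angle_cut hydrogen-bond criterion (Angstrom, degrees).
#' @param max_normal_angle maximum base-plane normal angle, degrees.
#' @param max_center_dist maximum ring-centre distance, Angstrom.
#' @param min_hbonds minimum inter-edge hydrogen bonds.
#' @param bonded precomputed [bonded_hydrogens()] map.
#' @return data.frame: res_i, res_j, edge_i, edge_j, orientation, n_hbonds.
#' @export
annotate_pairs_frame <- function(frame, model, d_cut = 3.5, angle_cut = 120,
                                 max_normal_angle = 65, max_center_dist = 8.5,
                                 min_hbonds = 2L, bonded = NULL) {
  if (is.null(bonded)) bonded <- bonded_hydrogens(model)
  ty <- base_type(model)
  unknown <- unique(model$residues$resname[is.na(ty)])
  if (length(unknown))
    warning("skipping residues of unknown type: ",
            paste(unknown, collapse = ", "))
  annot <- which(!is.na(ty))
  rings <- lapply(seq_len(n_residues(model)), function(r)
    if (is.na(ty[r])) integer() else ring_atom_indices(model, r, ty[r]))
  centers <- t(vapply(rings, function(idx)
    if (length(idx)) colMeans(frame[idx, , drop = FALSE]) else rep(NA_real_, 3L),
    numeric(3)))
  edge_atoms <- lapply(seq_len(n_residues(model)), function(r) {
    if (is.na(ty[r])) return(integer())
    nms <- unique(unlist(LW_EDGES[[ty[r]]]))
    idx <- vapply(nms, function(n) res_atom_index(model, r, n), integer(1))
    idx[!is.na(idx)]
  })

  out <- list()
  for (ii in seq_along(annot)) {
    i <- annot[ii]
    for (j in annot[-seq_len(ii)]) {
      dc <- sqrt(sum((centers[i, ] - centers[j, ])^2))
      if (!is.finite(dc) || dc > max_center_dist) next
      ni <- plane_normal(frame[rings[[i]], , drop = FALSE])
      nj <- plane_normal(frame[rings[[j]], , drop = FALSE])
      if (fold_angle(ni, nj) > max_normal_angle) next
      cand <- c(edge_atoms[[i]], edge_atoms[[j]])
      hits <- detect_hbonds_frame(frame, model, d_cut, angle_cut,
                                  bonded = bonded, candidates = cand)
      keep <- (model$atoms$residue_index[hits$donor] == i &
                 model$atoms$residue_index[hits$acceptor] == j) |
        (model$atoms$residue_index[hits$donor] == j &
           model$atoms$residue_index[hits$acceptor] == i)
      hits <- hits[keep, , drop = FALSE]
      if (nrow(hits) < min_hbonds) next

      edge_of <- function(r) {
        part <- unique(c(hits$donor[model$atoms$residue_index[hits$donor] == r],
                         hits$acceptor[model$atoms$residue_index[hits$acceptor] == r]))
        nm <- model$atoms$atom_name[part]
        votes <- vapply(LW_EDGES[[ty[r]]], function(ed) sum(nm %in% ed), numeric(1))
        names(votes)[which.max(votes)]  # which.max ties -> first: WC > HG > Sugar
      }
      c1i <- res_atom_index(model, i, "C1'"); c1j <- res_atom_index(model, j, "C1'")
      ngi <- res_atom_index(model, i, GLYCOSIDIC_N[[ty[i]]])
      ngj <- res_atom_index(model, j, GLYCOSIDIC_N[[ty[j]]])
      orient <- NA_character_
      if (!anyNA(c(c1i, c1j, ngi, ngj))) {
        dih <- dihedral(frame[c1i, ], frame[ngi, ], frame[ngj, ], frame[c1j, ])
        orient <- if (abs(dih) <= 90) "cis" else "trans"
      }
      out[[length(out) + 1L]] <- data.frame(
        res_i = i, res_j = j, edge_i = edge_of(i), edge_j = edge_of(j),
        orientation = orient, n_hbonds = nrow(hits), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(res_i = integer(), res_j = integer(),
                      edge_i = character(), edge_j = character(),
                      orientation = character(), n_hbonds = integer()))
  do.call(rbind, out)
}

#' Annotate aromatic stacking in one frame
#'
#' Two bases stack when their ring centres are within `max_dist`, the angle
#' between ring normals is at most `max_normal_angle`, and the lateral offset
#' (centre displacement projected onto the mean base plane) is at most
#' `max_offset`.
#'
#' @param frame n_atoms x 3 coordinates.
#' @param model matching `structure_model`.
#' @param max_dist centre--centre cutoff, Angstrom.
#' @param max_normal_angle normal--normal cutoff, degrees.
#' @param max_offset lateral offset cutoff, Angstrom.
#' @return data.frame: res_i, res_j, dist, normal_angle, offset.
#' @export
annotate_stacking_frame <- function(frame, model, max_dist = 4.5,
                                    max_normal_angle = 40, max_offset = 2.5) {
  ty <- base_type(model)
  annot <- which(!is.na(ty))
  rings <- lapply(seq_len(n_residues(model)), function(r)
    if (is.na(ty[r])) integer() else ring_atom_indices(model, r, ty[r]))
  centers <- t(vapply(rings, function(idx)
    if (length(idx)) colMeans(frame[idx, , drop = FALSE]) else rep(NA_real_, 3L),
    numeric(3)))
  out <- list()
  for (ii in seq_along(annot)) {
    i <- annot[ii]
    for (j in annot[-seq_len(ii)]) {
      dvec <- centers[j, ] - centers[i, ]
      dc <- sqrt(sum(dvec^2))
      if (!is.finite(dc) || dc > max_dist) next
      ni <- plane_normal(frame[rings[[i]], , drop = FALSE])
      nj <- plane_normal(frame[rings[[j]], , drop = FALSE])
      ang <- fold_angle(ni, nj)
      if (ang > max_normal_angle) next
      if (sum(ni * nj) < 0) nj <- -nj
      nbar <- unit(ni + nj)
      offset <- sqrt(max(sum(dvec^2) - sum(dvec * nbar)^2, 0))
      if (offset > max_offset) next
      out[[length(out) + 1L]] <- data.frame(res_i = i, res_j = j, dist = dc,
                                            normal_angle = ang, offset = offset)
    }
  }
  if (!length(out))
    return(data.frame(res_i = integer(), res_j = integer(), dist = numeric(),
                      normal_angle = numeric(), offset = numeric()))
  do.call(rbind, out)
}

#' Base-pair and stacking occupancy over an analysis window
#'
#' Annotates every windowed frame and reports occupancy per (residue pair,
#' edge combination, orientation) -- cis and trans interchange of one pair
#' yields separate records -- and per stacked pair.
#'
#' @inheritParams annotate_pairs_frame
#' @param traj a `trajectory_ensemble`.
#' @param window an `analysis_window`.
#' @param stack_params list of [annotate_stacking_frame()] thresholds.
#' @return list of two [tabular_report()]s: `pairs` (res_i, res_j, labels,
#'   edge_i, edge_j, orientation, occupancy) and `stacks` (res_i, res_j,
#'   labels, occupancy), both occupancy-descending.
#' @export
interaction_occupancy_map <- function(traj, model, window = full_window(traj),
                                      d_cut = 3.5, angle_cut = 120,
                                      max_normal_angle = 65,
                                      max_center_dist = 8.5, min_hbonds = 2L,
                                      stack_params = list()) {
  frames <- concat_window(traj, window)
  nf <- dim(frames)[1L]
  bonded <- bonded_hydrogens(model)
  pair_counts <- new.env(parent = emptyenv())
  stack_counts <- new.env(parent = emptyenv())
  bump <- function(env, key) env[[key]] <-
      (if (is.null(env[[key]])) 0L else env[[key]]) + 1L
  for (f in seq_len(nf)) {
    fr <- frames[f, , , drop = TRUE]
    pa <- suppressWarnings(
      annotate_pairs_frame(fr, model, d_cut, angle_cut, max_normal_angle,
                           max_center_dist, min_hbonds, bonded))
    for (i in seq_len(nrow(pa)))
      bump(pair_counts, paste(pa$res_i[i], pa$res_j[i], pa$edge_i[i],
                              pa$edge_j[i], pa$orientation[i], sep = "\t"))
    st <- do.call(annotate_stacking_frame, c(list(fr, model), stack_params))
    for (i in seq_len(nrow(st)))
      bump(stack_counts, paste(st$res_i[i], st$res_j[i], sep = "\t"))
  }
  lab <- residue_labels(model)
  tab_from <- function(env, cols) {
    keys <- ls(env)
    if (!length(keys)) {
      df <- stats::setNames(
        as.data.frame(matrix(nrow = 0L, ncol = length(cols) + 1L)),
        c(cols, "occupancy"))
      return(df)
    }
    parts <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
    df <- as.data.frame(parts, stringsAsFactors = FALSE)
    names(df) <- cols
    df$occupancy <- vapply(keys, function(k) env[[k]], integer(1)) / nf
    df
  }
  pairs <- tab_from(pair_counts,
                    c("res_i", "res_j", "edge_i", "edge_j", "orientation"))
  if (nrow(pairs)) {
    pairs$res_i <- as.integer(pairs$res_i); pairs$res_j <- as.integer(pairs$res_j)
    pairs$label_i <- lab[pairs$res_i]; pairs$label_j <- lab[pairs$res_j]
    pairs <- pairs[order(-pairs$occupancy, pairs$res_i, pairs$res_j,
                         pairs$orientation), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  stacks <- tab_from(stack_counts, c("res_i", "res_j"))
  if (nrow(stacks)) {
    stacks$res_i <- as.integer(stacks$res_i); stacks$res_j <- as.integer(stacks$res_j)
    stacks$label_i <- lab[stacks$res_i]; stacks$label_j <- lab[stacks$res_j]
    stacks <- stacks[order(-stacks$occupancy, stacks$res_i, stacks$res_j), ,
                     drop = FALSE]
    rownames(stacks) <- NULL
  }
  params <- list(d_cut = d_cut, angle_cut = angle_cut,
                 max_normal_angle = max_normal_angle,
                 max_center_dist = max_center_dist, min_hbonds = min_hbonds)
  list(pairs = tabular_report(pairs, params, window),
       stacks = tabular_report(stacks, c(params, stack_params), window))
}
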