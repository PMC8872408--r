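#' Bonded-hydrogen assignment for polar heavy atoms
#'
#' Hydrogens are assigned to the heavy atom of the same residue within
#' `max_bond` Angstrom in the reference coordinates (covalent-geometry
#' convention; PDB files carry no explicit bonds).
#'
#' @param model a `structure_model`.
#' @param max_bond X-H bond-length cutoff, Angstrom.
#' @return list mapping heavy-atom index (as character) to integer vector of
#'   hydrogen indices.
#' @keywords internal
bonded_hydrogens <- function(model, max_bond = 1.2) {
  h_idx <- which(model$atoms$element == "H")
  if (!length(h_idx))
    stop("configuration error: model contains no hydrogens; ",
         "hydrogen-bond analysis without explicit hydrogens is unsupported")
  heavy_idx <- which(model$atoms$element != "H")
  out <- list()
  for (h in h_idx) {
    res <- model$atoms$residue_index[h]
    cand <- heavy_idx[model$atoms$residue_index[heavy_idx] == res]
    d2 <- rowSums((model$coords[cand, , drop = FALSE] -
                     matrix(model$coords[h, ], length(cand), 3L, byrow = TRUE))^2)
    parent <- cand[which.min(d2)]
    if (min(d2) <= max_bond^2)
      out[[as.character(parent)]] <- c(out[[as.character(parent)]], h)
  }
  out
}

#' Detect hydrogen bonds in a single frame
#'
#' Geometric criterion: two polar heavy atoms (elements in `polar_elements`),
#' at least one with a bonded hydrogen, heavy--heavy distance strictly below
#' `d_cut` and D-H...A angle (at the hydrogen) strictly above `angle_cut`.
#' One hit per (donor, hydrogen, acceptor) triple; intra-residue pairs are
#' excluded by default.
#'
#' @param frame n_atoms x 3 coordinate matrix.
#' @param model matching `structure_model`.
#' @param d_cut heavy-atom distance cutoff, Angstrom.
#' @param angle_cut D-H...A angle cutoff, degrees.
#' @param polar_elements donor/acceptor element set.
#' @param exclude_intra drop donor and acceptor in the same residue.
#' @param bonded precomputed [bonded_hydrogens()] map (recomputed if NULL).
#' @param candidates optional atom-index set restricting both endpoints.
#' @return data.frame with columns donor, h, acceptor (atom indices).
#' @export
detect_hbonds_frame <- function(frame, model, d_cut = 3.5, angle_cut = 120,
                                polar_elements = c("N", "O"),
                                exclude_intra = TRUE, bonded = NULL,
                                candidates = NULL) {
  if (is.null(bonded)) bonded <- bonded_hydrogens(model)
  polar <- which(model$atoms$element %in% polar_elements)
  if (!is.null(candidates)) polar <- intersect(polar, candidates)
  donors <- polar[as.character(polar) %in% names(bonded)]
  if (!length(donors) || length(polar) < 2L)
    return(data.frame(donor = integer(), h = integer(), acceptor = integer()))

  res <- model$atoms$residue_index
  hits <- list()
  acc_xyz <- frame[polar, , drop = FALSE]
  for (d in donors) {
    dx <- frame[d, ]
    dd <- sqrt(rowSums((acc_xyz - matrix(dx, length(polar), 3L, byrow = TRUE))^2))
    ok <- polar[dd < d_cut & polar != d &
                  (!exclude_intra | res[polar] != res[d])]
    if (!length(ok)) next
    for (h in bonded[[as.character(d)]]) {
      hx <- frame[h, ]
      v1 <- dx - hx
      for (a in ok) {
        v2 <- frame[a, ] - hx
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        if (ang > angle_cut)
          hits[[length(hits) + 1L]] <- c(d, h, a)
      }
    }
  }
  if (!length(hits))
    return(data.frame(donor = integer(), h = integer(), acceptor = integer()))
  m <- do.call(rbind, hits)
  data.frame(donor = m[, 1L], h = m[, 2L], acceptor = m[, 3L])
}

#' Hydrogen-bond occupancy over an analysis window
#'
#' Detects hydrogen bonds in every windowed frame (replicates concatenated)
#' and reports, per (donor, hydrogen, acceptor) triple seen at least once,
#' the fraction of window frames in which it is formed. Output is sorted by
#' occupancy (descending), then donor/h/acceptor indices.
#'
#' @inheritParams detect_hbonds_frame
#' @param traj a `trajectory_ensemble`.
#' @param window an `analysis_window`.
#' @return a [tabular_report()] with columns donor, h, acceptor (atom
#'   indices), donor_label, acceptor_label ("residue@atom"), occupancy.
#' @export
hbond_occupancy <- function(traj, model, window = full_window(traj),
                            d_cut = 3.5, angle_cut = 120,
                            polar_elements = c("N", "O"),
                            exclude_intra = TRUE, candidates = NULL) {
  frames <- concat_window(traj, window)
  nf <- dim(frames)[1L]
  bonded <- bonded_hydrogens(model)
  counts <- new.env(parent = emptyenv())
  for (f in seq_len(nf)) {
    hits <- detect_hbonds_frame(frames[f, , , drop = TRUE], model, d_cut,
                                angle_cut, polar_elements, exclude_intra,
                                bonded, candidates)
    for (i in seq_len(nrow(hits))) {
      key <- paste(hits$donor[i], hits$h[i], hits$acceptor[i])
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  keys <- ls(counts)
  if (!length(keys)) {
    df <- data.frame(donor = integer(), h = integer(), acceptor = integer(),
                     donor_label = character(), acceptor_label = character(),
                     occupancy = numeric())
    return(tabular_report(df, params = list(d_cut = d_cut, angle_cut = angle_cut),
                          window = window))
  }
  m <- do.call(rbind, lapply(strsplit(keys, " "), as.integer))
  occ <- vapply(keys, function(k) counts[[k]], integer(1)) / nf
  lab <- function(i) sprintf("%s@%s",
                             residue_labels(model)[model$atoms$residue_index[i]],
                             model$atoms$atom_name[i])
  df <- data.frame(donor = m[, 1L], h = m[, 2L], acceptor = m[, 3L],
                   donor_label = vapply(m[, 1L], lab, character(1)),
                   acceptor_label = vapply(m[, 3L], lab, character(1)),
                   occupancy = unname(occ), stringsAsFactors = FALSE)
  df <- df[order(-df$occupancy, df$donor, df$h, df$acceptor), , drop = FALSE]
  rownames(df) <- NULL
  tabular_report(df, params = list(d_cut = d_cut, angle_cut = angle_cut),
                 window = window)
}
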