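#' aptanet: trajectory analysis for riboswitch aptamer ensembles
#'
#' Shared domain containers: the topology every analysis indexes into
#' (`structure_model`), the named substructure map (helices P1-P3, junctions
#' J1/2, J2/3, J3/1, loops L2/L3, and the ligand), replicate trajectory
#' ensembles and half-open analysis windows.
#'
#' @keywords internal
"_PACKAGE"

CANONICAL_REGIONS <- c("P1", "J1/2", "P2", "L2", "J2/3", "P3", "L3", "J3/1",
                       "Ligand")

#' Construct a structure model
#'
#' The topology container all analyses index into: per-atom names, elements
#' and residue membership, reference coordinates in Angstrom, and a residue
#' table with a per-residue ligand flag. Atoms of one residue occupy a
#' contiguous slice, in file order.
#'
#' @param atom_name character vector of PDB atom names (e.g. `"C1'"`).
#' @param element per-atom element symbols (`"C"`, `"N"`, `"O"`, `"P"`, `"H"`).
#' @param chain,resnum,resname per-atom residue identity; residue identity is
#'   the (chain, resnum, resname) triple, 1-based resnum as in PDB.
#' @param coords n_atoms x 3 numeric matrix of reference coordinates (Angstrom).
#' @param ligand_codes residue names flagged as ligand (e.g. `"LIG"`).
#' @return An object of class `structure_model` with components `atoms`
#'   (data.frame: atom_name, element, chain, resnum, resname, residue_index),
#'   `coords`, and `residues` (data.frame: chain, resnum, resname, first_atom,
#'   last_atom, is_ligand).
#' @export
structure_model <- function(atom_name, element, chain, resnum, resname,
                            coords, ligand_codes = character()) {
  n <- length(atom_name)
  stopifnot(length(element) == n, length(chain) == n, length(resnum) == n,
            length(resname) == n)
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || nrow(coords) != n || ncol(coords) != 3)
    stop("coords must be an n_atoms x 3 numeric matrix")
  if (any(!is.finite(coords)))
    stop("reference coordinates must be finite")
  if (n == 0L) stop("empty input: model has zero atoms")

  key <- paste(chain, resnum, resname, sep = "|")
  # contiguity: residues must not be interleaved
  ridx <- match(key, unique(key))
  if (any(diff(ridx) < 0L) || anyDuplicated(rle(ridx)$values))
    stop("atoms of one residue must be contiguous in input order")

  first <- match(unique(key), key)
  last <- c(first[-1L] - 1L, n)
  residues <- data.frame(
    chain = chain[first], resnum = resnum[first], resname = resname[first],
    first_atom = first, last_atom = last,
    is_ligand = resname[first] %in% ligand_codes,
    stringsAsFactors = FALSE
  )
  if (nrow(residues) < 2L) stop("model must contain at least 2 residues")

  atoms <- data.frame(atom_name = atom_name, element = element,
                      chain = chain, resnum = resnum, resname = resname,
                      residue_index = ridx, stringsAsFactors = FALSE)
  heavy_per_res <- tapply(element != "H", ridx, any)
  if (!all(heavy_per_res))
    stop("every residue must contain at least one heavy atom")

  structure(list(atoms = atoms, coords = coords, residues = residues),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d residues (%d ligand)\n",
              nrow(x$atoms), nrow(x$residues), sum(x$residues$is_ligand)))
  invisible(x)
}

n_atoms <- function(model) nrow(model$atoms)
n_residues <- function(model) nrow(model$residues)

#' Residue labels ("chain:resname resnum")
#' @param model a `structure_model`.
#' @return character vector, one label per residue.
#' @export
residue_labels <- function(model) {
  with(model$residues, sprintf("%s:%s%d", chain, resname, resnum))
}

#' Construct a substructure map
#'
#' Named regions over residues of a model. Canonical region names for the
#' three-way-junction aptamer are P1, J1/2, P2, L2, J2/3, P3, L3, J3/1 and
#' Ligand; other names are allowed. Regions are user-supplied annotation
#' (crystal-structure knowledge), never inferred.
#'
#' @param regions named list; each element an integer vector of residue
#'   indices into `model$residues`.
#' @param model the `structure_model` the map refers to.
#' @return Object of class `substructure_map` (the validated named list).
#' @export
substructure_map <- function(regions, model) {
  stopifnot(is.list(regions), !is.null(names(regions)), all(nzchar(names(regions))))
  all_idx <- unlist(regions, use.names = FALSE)
  if (length(all_idx) && (any(all_idx < 1L) || any(all_idx > n_residues(model))))
    stop("region residue index out of range for model")
  if (anyDuplicated(all_idx))
    stop("regions must be disjoint: residue ",
         all_idx[duplicated(all_idx)][1L], " appears twice")
  structure(lapply(regions, as.integer), class = "substructure_map")
}

#' Ordered coordinate frames grouped into a replicate ensemble
#'
#' @param replicates list of `n_frames x n_atoms x 3` numeric arrays
#'   (Angstrom); all replicates must share the model's atom count.
#' @param model the `structure_model` the frames index into.
#' @param system_id free-text system label.
#' @param frame_stride_ps time between stored frames, picoseconds (metadata).
#' @return Object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(replicates, model, system_id = "system",
                                frame_stride_ps = NA_real_) {
  stopifnot(is.list(replicates), length(replicates) >= 1L)
  na <- n_atoms(model)
  for (r in seq_along(replicates)) {
    x <- replicates[[r]]
    if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3L] != 3L)
      stop("replicate ", r, " must be an n_frames x n_atoms x 3 array")
    if (dim(x)[2L] != na)
      stop(sprintf("replicate %d has %d atoms but model has %d",
                   r, dim(x)[2L], na))
    if (dim(x)[1L] < 2L)
      stop("replicate ", r, " must have at least 2 frames")
  }
  structure(list(system_id = system_id, replicates = replicates,
                 frame_stride_ps = frame_stride_ps),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  nf <- vapply(x$replicates, function(r) dim(r)[1L], integer(1))
  cat(sprintf("trajectory_ensemble '%s': %d replicate(s), frames: %s\n",
              x$system_id, length(x$replicates), paste(nf, collapse = ", ")))
  invisible(x)
}

n_frames <- function(traj) {
  vapply(traj$replicates, function(r) dim(r)[1L], integer(1))
}

#' Half-open per-replicate analysis window
#'
#' Frames `[start, end)` (0-based, half-open) of every replicate enter the
#' analysis; the convention mirrors concatenating each run's final segment.
#'
#' @param start,end frame bounds, `0 <= start < end`.
#' @return Object of class `analysis_window`.
#' @export
analysis_window <- function(start, end) {
  stopifnot(length(start) == 1L, length(end) == 1L)
  if (start < 0 || end <= start)
    stop("analysis window requires 0 <= start < end")
  structure(list(start = as.integer(start), end = as.integer(end)),
            class = "analysis_window")
}

#' Default window spanning all frames of a trajectory
#' @param traj a `trajectory_ensemble`.
#' @return an `analysis_window` covering the shortest replicate.
#' @export
full_window <- function(traj) analysis_window(0L, min(n_frames(traj)))

check_window <- function(traj, window) {
  nf <- n_frames(traj)
  bad <- which(window$end > nf)
  if (length(bad))
    stop(sprintf("window [%d,%d) out of bounds for replicate %d (%d frames)",
                 window$start, window$end, bad[1L], nf[bad[1L]]))
  invisible(TRUE)
}

#' Select atom indices by residue, atom name, region and element class
#'
#' Deterministic, order-preserving (file-order) atom selection. Unknown
#' region, residue or atom names raise a resolution error naming the token.
#'
#' @param model a `structure_model`.
#' @param region region name(s); requires `map`.
#' @param map a `substructure_map` (needed only with `region`).
#' @param residues integer residue indices, or residue labels as produced by
#'   [residue_labels()].
#' @param atom_names restrict to these PDB atom names.
#' @param heavy if TRUE, exclude hydrogens (element `"H"`).
#' @param ligand if TRUE, restrict to ligand residues.
#' @return increasing integer vector of atom indices.
#' @export
select_atoms <- function(model, region = NULL, map = NULL, residues = NULL,
                         atom_names = NULL, heavy = FALSE, ligand = FALSE) {
  keep <- rep(TRUE, n_atoms(model))
  res_keep <- NULL

  if (!is.null(region)) {
    if (is.null(map)) stop("region selection requires a substructure_map")
    unknown <- setdiff(region, names(map))
    if (length(unknown))
      stop("unknown region name: '", unknown[1L], "'")
    res_keep <- unlist(map[region], use.names = FALSE)
  }
  if (!is.null(residues)) {
    if (is.character(residues)) {
      idx <- match(residues, residue_labels(model))
      if (anyNA(idx)) {
        alt <- match(residues, model$residues$resname)
        idx[is.na(idx)] <- alt[is.na(idx)]
      }
      if (anyNA(idx))
        stop("unknown residue: '", residues[which(is.na(idx))[1L]], "'")
      residues <- idx
    }
    if (any(residues < 1L | residues > n_residues(model)))
      stop("residue index out of range")
    res_keep <- if (is.null(res_keep)) residues else intersect(res_keep, residues)
  }
  if (ligand) {
    lig <- which(model$residues$is_ligand)
    res_keep <- if (is.null(res_keep)) lig else intersect(res_keep, lig)
  }
  if (!is.null(res_keep))
    keep <- keep & model$atoms$residue_index %in% res_keep

  if (!is.null(atom_names)) {
    pool <- if (is.null(res_keep)) model$atoms$atom_name else
      model$atoms$atom_name[model$atoms$residue_index %in% res_keep]
    missing <- setdiff(atom_names, pool)
    if (length(missing))
      stop("unknown atom name in selection: '", missing[1L], "'")
    keep <- keep & model$atoms$atom_name %in% atom_names
  }
  if (heavy) keep <- keep & model$atoms$element != "H"

  out <- which(keep)
  if (!length(out)) stop("selection resolved to zero atoms")
  out
}

#' Concatenate windowed frames across replicates
#'
#' Applies the same half-open window to every replicate and stacks the frames
#' replicate-by-replicate in input order. Coordinates pass through unchanged
#' (no recentring or fitting).
#'
#' @param traj a `trajectory_ensemble`.
#' @param window an `analysis_window`; default all frames.
#' @return `total_frames x n_atoms x 3` array with attribute `replicate`
#'   (integer origin of each frame).
#' @export
concat_window <- function(traj, window = full_window(traj)) {
  check_window(traj, window)
  sel <- (window$start + 1L):window$end
  parts <- lapply(traj$replicates, function(r) r[sel, , , drop = FALSE])
  out <- do.call(abind3, parts)
  attr(out, "replicate") <- rep(seq_along(parts), each = length(sel))
  out
}

# bind 3-d arrays along dim 1 without an extra dependency
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1L]])
  n1 <- sum(vapply(parts, function(p) dim(p)[1L], integer(1)))
  out <- array(NA_real_, dim = c(n1, d[2L], d[3L]))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[1L]
    out[at + seq_len(k), , ] <- p
    at <- at + k
  }
  out
}
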