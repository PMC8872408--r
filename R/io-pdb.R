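#' Read a structure model from a PDB file
#'
#' Parses ATOM/HETATM records of the first MODEL (topology-from-first-model
#' convention). Parsing is delegated to bio3d; a validation pass first checks
#' every coordinate field so malformed lines are reported with their line
#' number. Residues whose residue name is in `ligand_codes` are flagged as
#' ligand (HETATM or ATOM alike).
#'
#' @param path PDB file with at least one ATOM/HETATM record.
#' @param ligand_codes residue names to flag as ligand.
#' @return a [structure_model()].
#' @export
read_structure <- function(path, ligand_codes = c("LIG", "DG", "RG")) {
  validate_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  if (nrow(a) == 0L) stop("empty input: no ATOM/HETATM records in ", path)
  elem <- a$elesy
  blank <- is.na(elem) | !nzchar(trimws(elem))
  if (any(blank)) elem[blank] <- element_from_name(a$elety[blank])
  chain <- a$chain
  chain[is.na(chain) | !nzchar(chain)] <- "A"
  structure_model(
    atom_name = a$elety, element = trimws(elem),
    chain = chain, resnum = a$resno, resname = trimws(a$resid),
    coords = cbind(a$x, a$y, a$z),
    ligand_codes = ligand_codes
  )
}

# PDB element inference when columns 77-78 are blank: first letter of the
# atom name that is not a digit; names like "1H5'" are hydrogens.
element_from_name <- function(name) {
  core <- sub("^[0-9]+", "", trimws(name))
  substr(core, 1L, 1L)
}

validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("empty input: no ATOM/HETATM records in ", path)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54L)
      stop(sprintf("parse error at line %d: truncated ATOM/HETATM record", i))
    xyz <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(xyz))))
      stop(sprintf("parse error at line %d: non-numeric coordinate field", i))
  }
  invisible(TRUE)
}

#' Read a trajectory (multi-model PDB or DCD) against a topology
#'
#' Multi-model PDB: each MODEL/ENDMDL block is one frame; a file without
#' MODEL records is a single frame. DCD is read through bio3d. Coordinates
#' are Angstrom throughout.
#'
#' @param path trajectory file (`.pdb` or `.dcd` by extension).
#' @param model the `structure_model` giving the atom count to match.
#' @param system_id,frame_stride_ps metadata passed to
#'   [trajectory_ensemble()].
#' @return a single-replicate [trajectory_ensemble()]. Combine several calls
#'   with [merge_replicates()].
#' @export
read_trajectory <- function(path, model, system_id = basename(path),
                            frame_stride_ps = NA_real_) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    validate_pdb_lines(path)
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
  }
  xyz <- as.matrix(xyz)
  na_file <- ncol(xyz) / 3L
  if (na_file != n_atoms(model))
    stop(sprintf("topology mismatch: trajectory has %d atoms, model has %d",
                 na_file, n_atoms(model)))
  frames <- xyz_to_frames(xyz)
  if (dim(frames)[1L] == 1L)  # single structure: duplicate-free ensembles need >=2
    frames <- frames[c(1L, 1L), , , drop = FALSE]
  trajectory_ensemble(list(frames), model, system_id = system_id,
                      frame_stride_ps = frame_stride_ps)
}

# bio3d xyz matrix (frames x 3N, x1 y1 z1 x2 ...) -> frames x N x 3 array
xyz_to_frames <- function(xyz) {
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3L
  out <- array(NA_real_, dim = c(nf, na, 3L))
  for (k in 1:3) out[, , k] <- xyz[, seq(k, by = 3L, length.out = na), drop = FALSE]
  out
}

frames_to_xyz <- function(frames) {
  nf <- dim(frames)[1L]; na <- dim(frames)[2L]
  out <- matrix(NA_real_, nf, 3L * na)
  for (k in 1:3) out[, seq(k, by = 3L, length.out = na)] <- frames[, , k]
  out
}

#' Merge single-replicate ensembles into one multi-replicate ensemble
#' @param ... `trajectory_ensemble` objects over the same model.
#' @param system_id label for the merged system.
#' @return a `trajectory_ensemble` whose replicates are the inputs', in order.
#' @export
merge_replicates <- function(..., system_id = "system") {
  parts <- list(...)
  reps <- unlist(lapply(parts, function(p) p$replicates), recursive = FALSE)
  structure(list(system_id = system_id, replicates = reps,
                 frame_stride_ps = parts[[1L]]$frame_stride_ps),
            class = "trajectory_ensemble")
}

#' Write a trajectory as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame, atoms in model order. Ligand residues
#' are written as HETATM.
#'
#' @param traj a `trajectory_ensemble` (replicates are concatenated).
#' @param model the `structure_model` supplying names and residue ids.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, model, path) {
  frames <- concat_window(traj)
  a <- model$atoms
  het <- model$residues$is_ligand[a$residue_index]
  rectype <- ifelse(het, "HETATM", "ATOM  ")
  # PDB atom-name column convention: 1-3 char names start in column 14
  nm <- ifelse(nchar(a$atom_name) < 4L, paste0(" ", a$atom_name), a$atom_name)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(dim(frames)[1L])) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf("%s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       rectype, seq_len(nrow(a)), nm, a$resname, a$chain,
                       a$resnum, frames[f, , 1L], frames[f, , 2L],
                       frames[f, , 3L], 1, 0, a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
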