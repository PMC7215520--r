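#' Trajectory objects
#'
#' A `trajectory` holds a fixed atom topology plus ordered per-frame
#' coordinates for a (pre-stripped, protein-only) molecular dynamics run.
#' Every frame shares the same atoms in the same order; this is the
#' substrate of all downstream metrics.
#'
#' @param atoms A data.frame with one row per atom and columns `atom_name`
#'   (e.g. `"CA"`, `"CB"`), `residue_name` (3-letter code), `residue_number`
#'   (author numbering; may start at 23) and `chain_id` (single character).
#' @param xyz Numeric array of dimension `n_frames x n_atoms x 3`, in
#'   Angstrom. A single frame may be given as an `n_atoms x 3` matrix.
#' @param label Protein label, e.g. `"WT"` or `"S100P"`.
#' @param timestep_ps Optional frame spacing in picoseconds.
#' @param check_residues If `TRUE` (default), residue names must be one of
#'   the 20 standard amino-acid codes.
#' @return An object of class `trajectory` with elements `atoms`, `xyz`,
#'   `label`, `timestep_ps` and `residues` (the per-residue topology, one
#'   row per residue in order of first appearance).
#' @export
trajectory <- function(atoms, xyz, label = "", timestep_ps = NULL,
                       check_residues = TRUE) {
  stopifnot(is.data.frame(atoms))
  need <- c("atom_name", "residue_name", "residue_number", "chain_id")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  }
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(1L, dim(xyz)))
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[3] == 3L)
  if (dim(xyz)[1] < 1L) stop("a trajectory needs at least one frame")
  if (dim(xyz)[2] != nrow(atoms)) {
    stop("xyz has ", dim(xyz)[2], " atoms but the topology has ", nrow(atoms))
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  atoms$residue_number <- as.integer(atoms$residue_number)
  atoms$residue_name <- toupper(atoms$residue_name)
  if (check_residues && !all(atoms$residue_name %in% AA3)) {
    stop("non-standard residue name(s): ",
         paste(unique(setdiff(atoms$residue_name, AA3)), collapse = ", "))
  }
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$atom_name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue_number, atom_name) in topology: ",
         key[duplicated(key)][1])
  }
  rkey <- paste(atoms$chain_id, atoms$residue_number)
  first <- !duplicated(rkey)
  residues <- atoms[first, c("chain_id", "residue_number", "residue_name")]
  rownames(residues) <- NULL
  # consistency: one residue_name per (chain, number)
  nm <- tapply(atoms$residue_name, rkey, function(v) length(unique(v)))
  if (any(nm > 1)) {
    stop("conflicting residue names at: ", names(nm)[nm > 1][1])
  }
  structure(
    list(atoms = atoms, xyz = xyz, label = label, timestep_ps = timestep_ps,
         residues = residues),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %s: %d frames, %d residues, %d atoms%s\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    n_frames(x), n_residues(x), nrow(x$atoms),
    if (!is.null(x$timestep_ps)) sprintf(", %g ps/frame", x$timestep_ps) else ""
  ))
  invisible(x)
}

#' @rdname trajectory
#' @param x,traj A `trajectory`.
#' @export
n_frames <- function(traj) dim(traj$xyz)[1]

#' @rdname trajectory
#' @export
n_residues <- function(traj) nrow(traj$residues)

#' Frame times in picoseconds
#'
#' `frame_index * timestep_ps`, or `NULL` when no timestep is set.
#'
#' @param traj A `trajectory`.
#' @return Numeric vector of length `n_frames(traj)`, or `NULL`.
#' @export
frame_times <- function(traj) {
  if (is.null(traj$timestep_ps)) return(NULL)
  (seq_len(n_frames(traj)) - 1) * traj$timestep_ps
}

#' Residue labels of a trajectory
#'
#' @param traj A `trajectory`.
#' @return Character vector like `c("Glu23", "Ser24", ...)`, one per residue.
#' @export
residue_labels <- function(traj) {
  format_residue_label(traj$residues$residue_name,
                       traj$residues$residue_number)
}

#' Subset frames of a trajectory
#'
#' @param traj A `trajectory`.
#' @param frames Integer vector of frame indices (1-based), e.g. a stride
#'   `seq(1, n_frames(traj), by = s)`.
#' @return A `trajectory` with the selected frames.
#' @export
subset_frames <- function(traj, frames) {
  stopifnot(all(frames >= 1), all(frames <= n_frames(traj)))
  out <- traj
  out$xyz <- traj$xyz[frames, , , drop = FALSE]
  out
}

#' Resolve a per-residue atom selection
#'
#' Two selection modes are supported: `"CA"` picks the alpha-carbon of every
#' residue (the selection used for RMSD, Rg, RMSF and cross-correlation);
#' `"CB_GLY_CA"` picks the beta-carbon, substituting the alpha-carbon for
#' glycine, which has none (the selection used for residue contact
#' networks). Resolution fails with an error listing the residues for which
#' the required atom is missing.
#'
#' @param traj A `trajectory`.
#' @param mode `"CA"` or `"CB_GLY_CA"`.
#' @return An object of class `atom_selection`: an integer vector of atom
#'   indices, one per residue in topology order, named by residue label,
#'   with the mode in attribute `"mode"`.
#' @export
resolve_selection <- function(traj, mode = c("CA", "CB_GLY_CA")) {
  mode <- match.arg(mode)
  at <- traj$atoms
  rkey <- paste(at$chain_id, at$residue_number)
  res <- traj$residues
  rkeys <- paste(res$chain_id, res$residue_number)
  want <- if (mode == "CA") {
    rep("CA", nrow(res))
  } else {
    ifelse(res$residue_name == "GLY", "CA", "CB")
  }
  idx <- match(paste(rkeys, want), paste(rkey, at$atom_name))
  if (anyNA(idx)) {
    miss <- format_residue_label(res$residue_name[is.na(idx)],
                                 res$residue_number[is.na(idx)])
    stop("selection '", mode, "' unresolved; missing ",
         paste(unique(want[is.na(idx)]), collapse = "/"), " for residue(s): ",
         paste(miss, collapse = ", "))
  }
  structure(idx, names = residue_labels(traj), mode = mode,
            class = "atom_selection")
}

#' Extract per-residue coordinates
#'
#' Dense coordinate array for a resolved selection, in topology residue
#' order.
#'
#' @param traj A `trajectory`.
#' @param selection An `atom_selection` from [resolve_selection()], or a
#'   mode string passed on to it.
#' @return Numeric array `n_frames x n_residues x 3` (Angstrom), residue
#'   labels as dimnames on the second margin.
#' @export
coordinates_for <- function(traj, selection = "CA") {
  if (is.character(selection)) selection <- resolve_selection(traj, selection)
  out <- traj$xyz[, as.integer(selection), , drop = FALSE]
  dimnames(out) <- list(NULL, names(selection), c("x", "y", "z"))
  out
}

# ---- multi-model PDB input/output -------------------------------------

# Atom-identity string of the fixed PDB columns 13-27
# (name, altLoc, resName, chainID, resSeq, iCode) for topology comparison.
pdb_atom_identity <- function(lines) substr(lines, 13, 27)

#' Read a multi-model PDB trajectory
#'
#' Reads MODEL/ENDMDL-delimited coordinate sets (or a single model) into a
#' [trajectory()]. Parsing is done by [bio3d::read.pdb()]; this wrapper
#' enforces the dialect assumed throughout: models must share an identical
#' atom ordering, alternate locations other than blank/"A" are skipped,
#' insertion codes are rejected, and residue names must be standard unless
#' `map_nonstandard = TRUE` maps known parents (e.g. MSE to MET).
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier to keep. Required when the file holds more
#'   than one chain; single-chain files need no flag.
#' @param map_nonstandard Map known non-standard residues to their standard
#'   parent instead of rejecting them.
#' @param label Protein label stored on the trajectory.
#' @param timestep_ps Optional frame spacing (ps) stored on the trajectory.
#' @return A [trajectory()]; single-model files yield one frame.
#' @export
read_multimodel_pdb <- function(path, chain = NULL, map_nonstandard = FALSE,
                                label = "", timestep_ps = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  model_id <- cumsum(grepl("^MODEL", lines))
  model_id[model_id == 0L] <- 1L
  ids <- split(pdb_atom_identity(lines[is_atom]), model_id[is_atom])
  ref <- ids[[1]]
  for (k in seq_along(ids)[-1]) {
    if (!identical(ids[[k]], ref)) {
      stop("topology mismatch: MODEL ", names(ids)[k],
           " does not match MODEL ", names(ids)[1],
           " (atom count ", length(ids[[k]]), " vs ", length(ref), ")")
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  nf <- nrow(pdb$xyz)
  xyz <- array(NA_real_, dim = c(nf, nrow(at), 3))
  xyz[, , 1] <- pdb$xyz[, seq(1, ncol(pdb$xyz), by = 3), drop = FALSE]
  xyz[, , 2] <- pdb$xyz[, seq(2, ncol(pdb$xyz), by = 3), drop = FALSE]
  xyz[, , 3] <- pdb$xyz[, seq(3, ncol(pdb$xyz), by = 3), drop = FALSE]

  if (any(!is.na(at$insert) & nzchar(at$insert))) {
    stop("insertion codes are not supported")
  }
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  xyz <- xyz[, keep, , drop = FALSE]

  chains <- unique(at$chain)
  if (length(chains) > 1) {
    if (is.null(chain)) {
      stop("multi-chain input (", paste(chains, collapse = ", "),
           "); pass `chain` explicitly")
    }
    keep <- at$chain == chain
    if (!any(keep)) stop("no atoms in chain ", chain)
    at <- at[keep, , drop = FALSE]
    xyz <- xyz[, keep, , drop = FALSE]
  }

  resid <- toupper(at$resid)
  if (map_nonstandard) {
    mapped <- !is.na(match(resid, names(NONSTANDARD_MAP)))
    resid[mapped] <- NONSTANDARD_MAP[resid[mapped]]
  }
  if (!all(resid %in% AA3)) {
    stop("non-standard residue(s): ",
         paste(unique(setdiff(resid, AA3)), collapse = ", "),
         if (!map_nonstandard) " (see map_nonstandard)" else "")
  }

  atoms <- data.frame(
    atom_name = at$elety,
    residue_name = resid,
    residue_number = as.integer(at$resno),
    chain_id = ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain),
    stringsAsFactors = FALSE
  )
  trajectory(atoms, xyz, label = label, timestep_ps = timestep_ps)
}

#' Write a multi-model PDB trajectory
#'
#' Writes standard MODEL/ENDMDL blocks with coordinates at 3 decimals and
#' author residue numbering, via [bio3d::write.pdb()].
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_multimodel_pdb <- function(traj, path) {
  xyz <- matrix(aperm(traj$xyz, c(3, 2, 1)), nrow = n_frames(traj),
                byrow = TRUE)
  bio3d::write.pdb(
    file = path, xyz = xyz,
    elety = traj$atoms$atom_name,
    resid = traj$atoms$residue_name,
    resno = traj$atoms$residue_number,
    chain = traj$atoms$chain_id
  )
  invisible(path)
}

# ---- residue-set lists -------------------------------------------------

#' Residue sets
#'
#' A named set of residue labels, e.g. one predictor's binding-site
#' residues. Duplicates are collapsed; membership is order-independent.
#'
#' @param members Character vector of labels like `"Gly26"`.
#' @param name Set name (e.g. `"sitemap"`, `"cport"`).
#' @return An object of class `residue_set` with elements `name`,
#'   `members` (sorted by residue number) and `numbers`.
#' @export
residue_set <- function(members, name = "") {
  parsed <- parse_residue_label(members)
  keep <- !duplicated(parsed$residue_number)
  members <- format_residue_label(parsed$residue_name, parsed$residue_number)[keep]
  numbers <- parsed$residue_number[keep]
  o <- order(numbers)
  structure(list(name = name, members = members[o], numbers = numbers[o]),
            class = "residue_set")
}

#' @export
print.residue_set <- function(x, ...) {
  cat(sprintf("<residue_set> %s: %d residues\n",
              if (nzchar(x$name)) x$name else "(unnamed)", length(x$members)))
  invisible(x)
}

#' @export
length.residue_set <- function(x) length(x$members)

#' Parse a residue-set list
#'
#' Reads one `"Xxx###"` residue label per line; `#` starts a comment;
#' blank lines are ignored; duplicates collapse.
#'
#' @param path Path to a UTF-8 text file (ignored when `text` is given).
#' @param text Character scalar or vector of lines, as an alternative to
#'   `path`.
#' @param name Name for the resulting set (defaults to the file base name).
#' @return A [residue_set()].
#' @export
parse_residue_set <- function(path = NULL, text = NULL, name = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("give `path` or `text`")
    text <- readLines(path, warn = FALSE)
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  } else {
    text <- unlist(strsplit(text, "\n", fixed = TRUE))
    if (is.null(name)) name <- ""
  }
  stripped <- trimws(sub("#.*$", "", text))
  keep <- nzchar(stripped)
  labels <- stripped[keep]
  lineno <- which(keep)
  ok <- grepl("^[A-Za-z]{3}[0-9]+$", labels) &
    toupper(substr(labels, 1, 3)) %in% AA3
  if (any(!ok)) {
    stop("unparseable residue label at line ", lineno[!ok][1], ": '",
         labels[!ok][1], "'")
  }
  residue_set(labels, name = name)
}
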