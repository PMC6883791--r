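# Standard atomic masses (u) by element symbol; used when a file carries no
# masses of its own.
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  MG = 24.305, NA. = 22.990, CL = 35.45, K = 39.098, ZN = 65.38, FE = 55.845,
  MN = 54.938, CA. = 40.078
)

.mass_from_element <- function(element) {
  el <- toupper(trimws(element))
  m <- unname(.atomic_masses[el])
  m[is.na(m)] <- .atomic_masses[["C"]]
  m
}

# Infer an element symbol from a PDB-style atom name ("CA" -> C, "P" -> P,
# "OP1" -> O, "1H2'" -> H).
.element_from_atom_name <- function(atom) {
  a <- gsub("[^A-Za-z]", "", atom)
  substr(toupper(a), 1L, 1L)
}

# Nucleic-acid residue names as they appear in PDB files.
.nucleic_resnames <- c(
  "DA", "DT", "DG", "DC", "DU", "A", "T", "G", "C", "U",
  "DA5", "DT5", "DG5", "DC5", "DA3", "DT3", "DG3", "DC3"
)

#' Construct a labelled coordinate trajectory
#'
#' The container every in-silico analysis operates on: an ordered set of
#' frames, each a matrix of 3D coordinates in nanometres, plus per-atom
#' labels, masses, and a flag marking residue representatives (protein
#' C-alpha and nucleic-acid P atoms).
#'
#' @param coords A list of numeric matrices, one per frame, each `n_atoms` x 3
#'   (columns x, y, z in nm). All frames must share the same atom count.
#' @param atoms A data frame with one row per atom and columns `chain`,
#'   `resid`, `resname`, `atom`; optional columns `element`, `mass`,
#'   `representative`. Missing elements are inferred from atom names, missing
#'   masses from elements, and missing representative flags from atom names
#'   (`CA` or `P`).
#'
#' @return An object of class `traj_frames`.
#' @seealso [read_trajectory()], [gen_cylinder_trajectory()]
#' @export
trajectory_frames <- function(coords, atoms) {
  if (!is.list(coords) || length(coords) == 0L) {
    abort("`coords` must be a non-empty list of per-frame coordinate matrices.")
  }
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  n_atoms <- ncol_ok <- NULL
  counts <- vapply(coords, nrow, integer(1))
  if (length(unique(counts)) != 1L) {
    abort("inconsistent topology: frames have differing atom counts.")
  }
  if (any(vapply(coords, ncol, integer(1)) != 3L)) {
    abort("each frame must be an n_atoms x 3 coordinate matrix.")
  }
  if (any(!vapply(coords, function(m) all(is.finite(m)), logical(1)))) {
    abort("coordinates must be finite.")
  }
  atoms <- as_tibble(atoms)
  required <- c("chain", "resid", "resname", "atom")
  if (!all(required %in% names(atoms))) {
    abort(paste0("`atoms` must have columns: ", paste(required, collapse = ", ")))
  }
  if (nrow(atoms) != counts[1]) {
    abort("`atoms` must have one row per atom in each frame.")
  }
  if (is.null(atoms[["element"]])) {
    atoms$element <- .element_from_atom_name(atoms$atom)
  }
  if (is.null(atoms[["mass"]])) {
    atoms$mass <- .mass_from_element(atoms$element)
  }
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0)) {
    abort("atom masses must be positive and finite.")
  }
  if (is.null(atoms[["representative"]])) {
    atoms$representative <- atoms$atom %in% c("CA", "P")
  }
  structure(
    list(coords = coords, atoms = atoms),
    class = "traj_frames"
  )
}

#' @export
print.traj_frames <- function(x, ...) {
  cat(sprintf(
    "<traj_frames> %d frames x %d atoms (%d representatives)\n",
    n_frames(x), n_atoms(x), sum(x$atoms$representative)
  ))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `traj_frames` object.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$coords)

#' Number of atoms in a trajectory
#' @param traj A `traj_frames` object.
#' @return Integer atom count.
#' @export
n_atoms <- function(traj) nrow(traj$atoms)

#' @export
as_tibble.traj_frames <- function(x, ...) {
  nf <- n_frames(x)
  purrr::map_dfr(seq_len(nf), function(f) {
    m <- x$coords[[f]]
    dplyr::bind_cols(
      tibble(frame = f),
      x$atoms,
      tibble(x = m[, 1], y = m[, 2], z = m[, 3])
    )
  })
}

# Subset frames (and optionally atoms) of a trajectory.
.subset_frames <- function(traj, frames = NULL, atoms_idx = NULL) {
  coords <- traj$coords
  if (!is.null(frames)) coords <- coords[frames]
  atoms <- traj$atoms
  if (!is.null(atoms_idx)) {
    coords <- lapply(coords, function(m) m[atoms_idx, , drop = FALSE])
    atoms <- atoms[atoms_idx, , drop = FALSE]
  }
  trajectory_frames(coords, atoms)
}

# Resolve an atom selection to an integer index vector. `selection` may be
# NULL / "representatives" (C-alpha + P), "calpha", "all", a logical vector,
# or an integer vector.
.resolve_selection <- function(traj, selection) {
  at <- traj$atoms
  if (is.null(selection) || identical(selection, "representatives")) {
    idx <- which(at$representative)
  } else if (identical(selection, "calpha")) {
    idx <- which(at$atom == "CA" & !(at$resname %in% .nucleic_resnames))
  } else if (identical(selection, "all")) {
    idx <- seq_len(nrow(at))
  } else if (is.logical(selection)) {
    stopifnot(length(selection) == nrow(at))
    idx <- which(selection)
  } else if (is.numeric(selection)) {
    idx <- as.integer(selection)
  } else {
    abort("unknown atom selection.")
  }
  if (length(idx) == 0L) abort("empty atom selection.")
  idx
}
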