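#' Read a coordinate trajectory
#'
#' Reads either a multi-model PDB (via bio3d; coordinates converted from
#' angstrom to nanometres) or the package's plain-text trajectory format:
#' one header line of whitespace-separated `chain:resid:resname:atom` tokens,
#' followed by per-frame blocks of `x y z` rows in nm (blank lines between
#' frames are ignored).
#'
#' @param path Path to the trajectory file.
#' @param format `"auto"` (by extension: `.pdb` vs anything else), `"pdb"`,
#'   or `"plain"`.
#' @return A [trajectory_frames()] object with coordinates in nm and
#'   representative flags set from atom names (C-alpha, P).
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "plain")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "plain"
  }
  switch(format,
    pdb = .read_trajectory_pdb(path),
    plain = .read_trajectory_plain(path)
  )
}

.read_trajectory_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- grepl("^MODEL", lines)
  if (any(model_starts)) {
    # Count ATOM records per MODEL block: bio3d silently recycles when models
    # disagree, so validate here.
    model_id <- cumsum(model_starts)
    counts <- tapply(is_atom[model_id > 0], model_id[model_id > 0], sum)
    counts <- counts[counts > 0]
    if (length(unique(counts)) > 1L) {
      abort("inconsistent topology: MODEL blocks have differing atom counts.")
    }
  }
  if (!any(is_atom)) abort("zero frames: no ATOM records in PDB file.")
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3L
  if (nf < 1L || na < 1L) abort("zero frames: empty PDB trajectory.")
  atom <- trimws(pdb$atom$elety)
  element <- pdb$atom$elesy %||% rep("", length(atom))
  element <- trimws(element)
  missing_el <- is.na(element) | element == ""
  element[missing_el] <- .element_from_atom_name(atom[missing_el])
  atoms <- tibble(
    chain = as.character(pdb$atom$chain),
    resid = as.integer(pdb$atom$resno),
    resname = trimws(pdb$atom$resid),
    atom = atom,
    element = element
  )
  coords <- lapply(seq_len(nf), function(f) {
    matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10  # angstrom -> nm
  })
  trajectory_frames(coords, atoms)
}

.read_trajectory_plain <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) abort("zero frames: file too short.")
  tokens <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  parts <- strsplit(tokens, ":", fixed = TRUE)
  if (any(lengths(parts) != 4L)) {
    abort("unknown format: header tokens must be chain:resid:resname:atom.")
  }
  atoms <- tibble(
    chain = vapply(parts, `[`, "", 1),
    resid = as.integer(vapply(parts, `[`, "", 2)),
    resname = vapply(parts, `[`, "", 3),
    atom = vapply(parts, `[`, "", 4)
  )
  na <- nrow(atoms)
  body <- lines[-1]
  if (length(body) %% na != 0L) {
    abort("inconsistent topology: coordinate rows are not a multiple of the atom count.")
  }
  vals <- suppressWarnings(
    as.numeric(unlist(strsplit(trimws(body), "\\s+"), use.names = FALSE))
  )
  if (anyNA(vals) || length(vals) != 3L * length(body)) {
    abort("unknown format: coordinate rows must contain exactly x y z numbers.")
  }
  all_m <- matrix(vals, ncol = 3, byrow = TRUE)
  nf <- length(body) %/% na
  coords <- lapply(seq_len(nf), function(f) {
    all_m[((f - 1L) * na + 1L):(f * na), , drop = FALSE]
  })
  trajectory_frames(coords, atoms)
}

#' Write a trajectory to disk
#'
#' @param traj A [trajectory_frames()] object.
#' @param path Output path.
#' @param format `"plain"` (the package's text format, nm) or `"pdb"`
#'   (multi-model PDB, coordinates converted to angstrom).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("plain", "pdb")) {
  format <- match.arg(format)
  if (format == "plain") {
    at <- traj$atoms
    header <- paste(
      sprintf("%s:%d:%s:%s", at$chain, at$resid, at$resname, at$atom),
      collapse = " "
    )
    rows <- unlist(lapply(traj$coords, function(m) {
      sprintf("%.9f %.9f %.9f", m[, 1], m[, 2], m[, 3])
    }), use.names = FALSE)
    writeLines(c(header, rows), path)
  } else {
    .write_trajectory_pdb(traj, path)
  }
  invisible(path)
}

.write_trajectory_pdb <- function(traj, path) {
  at <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    m <- traj$coords[[f]] * 10  # nm -> angstrom
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)) %% 100000L,
      substr(at$atom, 1, 4), substr(at$resname, 1, 3),
      substr(at$chain, 1, 1), at$resid %% 10000L,
      m[, 1], m[, 2], m[, 3], substr(at$element, 1, 2)
    ), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
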