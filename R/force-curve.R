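#' Construct an AFM force curve
#'
#' A calibrated approach curve: tip displacement (nm) against measured force
#' (pN), with the tip radius and sample Poisson ratio needed for Hertz
#' analysis carried as metadata.
#'
#' @param displacement Numeric vector, nm. Must be strictly increasing within
#'   the approach segment.
#' @param force Numeric vector, pN, same length.
#' @param tip_radius Tip radius R in nm (default 10 nm, typical for
#'   oxide-sharpened silicon-nitride probes).
#' @param poisson Sample Poisson ratio, in `[0, 0.5)`. Default 1/3, the value
#'   conventionally assumed for nucleoprotein particles.
#' @param note Free-text calibration note.
#'
#' @return A tibble of class `force_curve` with columns `displacement_nm` and
#'   `force_pN` and metadata in attributes.
#' @seealso [read_force_curve()], [fit_hertz()], [gen_force_curve()]
#' @export
force_curve <- function(displacement, force, tip_radius = 10, poisson = 1 / 3,
                        note = NULL) {
  displacement <- as.numeric(displacement)
  force <- as.numeric(force)
  if (length(displacement) != length(force)) {
    abort("`displacement` and `force` must have equal length.")
  }
  if (any(!is.finite(displacement)) || any(!is.finite(force))) {
    abort("force-curve values must be finite.")
  }
  if (!is.finite(tip_radius) || tip_radius <= 0) abort("tip radius must be > 0 nm.")
  if (poisson < 0 || poisson >= 0.5) abort("Poisson ratio must lie in [0, 0.5).")
  out <- tibble(displacement_nm = displacement, force_pN = force)
  class(out) <- c("force_curve", class(out))
  attr(out, "tip_radius_nm") <- tip_radius
  attr(out, "poisson") <- poisson
  attr(out, "note") <- note
  out
}

# Longest strictly-increasing prefix of the displacement axis = the approach
# segment; a trailing retract (reversal) is dropped.
.approach_segment <- function(displacement) {
  n <- length(displacement)
  if (n < 2L) return(seq_len(n))
  drops <- which(diff(displacement) <= 0)
  if (length(drops) == 0L) seq_len(n) else seq_len(drops[1])
}

#' Read an AFM force curve from a CSV file
#'
#' Expects a two-column numeric table. Values are normalised to nm / pN; the
#' approach segment is isolated as the longest strictly monotone prefix of
#' the displacement axis (a trailing retract segment is discarded).
#'
#' @param path CSV file path.
#' @param columns Length-2 character vector naming the displacement and force
#'   columns, in that order. Defaults to the first two columns.
#' @param units `"nm_pN"` (already calibrated) or `"m_N"` (SI; scaled by 1e9
#'   and 1e12 respectively).
#' @inheritParams force_curve
#' @return A [force_curve()] object.
#' @export
read_force_curve <- function(path, columns = NULL, units = c("nm_pN", "m_N"),
                             tip_radius = 10, poisson = 1 / 3) {
  units <- match.arg(units)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (is.null(columns)) {
    if (ncol(df) < 2L) abort("force-curve file must have at least two columns.")
    columns <- names(df)[1:2]
  }
  if (!all(columns %in% names(df))) {
    abort(paste0("columns not found: ", paste(setdiff(columns, names(df)), collapse = ", ")))
  }
  d <- df[[columns[1]]]
  f <- df[[columns[2]]]
  if (!is.numeric(d) || !is.numeric(f) || anyNA(d) || anyNA(f)) {
    abort("non-numeric rows in force-curve file.")
  }
  if (units == "m_N") {
    d <- d * 1e9   # m  -> nm
    f <- f * 1e12  # N  -> pN
  }
  if (length(d) < 10L) abort("too few points: a force curve needs at least 10 rows.")
  keep <- .approach_segment(d)
  if (length(keep) < 10L) abort("too few points in the approach segment.")
  force_curve(d[keep], f[keep], tip_radius = tip_radius, poisson = poisson)
}

#' Write a force curve to CSV
#'
#' @param curve A [force_curve()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  readr::write_csv(as_tibble(curve)[, c("displacement_nm", "force_pN")], path)
  invisible(path)
}
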