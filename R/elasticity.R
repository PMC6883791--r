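# --- Orientation --------------------------------------------------------

# Fix an eigenvector's sign so its largest-magnitude component is positive.
# Keeps axes from flipping between frames that differ only by small
# fluctuations.
.fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' Orient a structure onto its principal axes of inertia
#'
#' Centres the coordinates at the mass-weighted centre of mass and rotates
#' them so the inertia tensor is diagonal, with the axis of the *largest*
#' principal moment mapped to z. For a flat, disc-like particle such as a
#' nucleosome this lays the broadest plane onto x-y, the orientation in which
#' cylinder height is a z-extent and radius an x-y extent.
#'
#' @param coords Numeric `n x 3` matrix of positions (nm), `n >= 3` and not
#'   collinear.
#' @param masses Optional numeric vector of atomic masses; equal masses when
#'   `NULL`.
#'
#' @return A list with `coords` (oriented positions), `rotation` (proper
#'   3x3 rotation matrix, columns = new axes), and `center` (the removed
#'   centre of mass).
#' @export
orient_frame <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3L) abort("degenerate geometry: need at least 3 atoms to orient.")
  if (is.null(masses)) masses <- rep(1, n)
  com <- colSums(coords * masses) / sum(masses)
  x <- sweep(coords, 2, com)
  # Inertia tensor I = sum m (|r|^2 Id - r r^T)
  r2 <- rowSums(x^2)
  xtx <- crossprod(x * sqrt(masses))
  inertia <- diag(sum(masses * r2), 3) - xtx
  e <- eigen(inertia, symmetric = TRUE)  # eigenvalues decreasing
  # the smallest principal moment vanishes only for collinear (or coincident)
  # point sets, for which no broadest plane exists
  if (e$values[3] <= 1e-10 * max(e$values[1], 1e-300)) {
    abort("degenerate geometry: collinear or coincident atoms.")
  }
  z_ax <- .fix_sign(e$vectors[, 1])  # largest principal moment -> z
  x_ax <- .fix_sign(e$vectors[, 3])  # smallest -> x
  y_ax <- c(
    z_ax[2] * x_ax[3] - z_ax[3] * x_ax[2],
    z_ax[3] * x_ax[1] - z_ax[1] * x_ax[3],
    z_ax[1] * x_ax[2] - z_ax[2] * x_ax[1]
  )
  rot <- cbind(x_ax, y_ax, z_ax, deparse.level = 0)
  list(coords = x %*% rot, rotation = rot, center = com)
}

# Orient every frame; returns X, Y, Z matrices (n_frames x n_sel) holding the
# oriented coordinates of the selected atoms.
.orient_all <- function(traj, sel_idx) {
  nf <- n_frames(traj)
  ns <- length(sel_idx)
  masses <- traj$atoms$mass
  X <- matrix(0, nf, ns); Y <- matrix(0, nf, ns); Z <- matrix(0, nf, ns)
  for (f in seq_len(nf)) {
    o <- orient_frame(traj$coords[[f]], masses)
    m <- o$coords[sel_idx, , drop = FALSE]
    X[f, ] <- m[, 1]; Y[f, ] <- m[, 2]; Z[f, ] <- m[, 3]
  }
  list(X = X, Y = Y, Z = Z)
}

# Contiguous near-equal window assignment of nf frames into n_windows blocks.
.window_index <- function(nf, n_windows) {
  if (n_windows == 1L) return(rep(1L, nf))
  as.integer(cut(seq_len(nf), breaks = n_windows, labels = FALSE))
}

# --- Windowed RMSF ------------------------------------------------------

#' Windowed per-residue fluctuations of an oriented trajectory
#'
#' Splits the trajectory into `n_windows` contiguous, near-equal blocks of
#' frames. Every frame is oriented onto its principal axes; within each
#' window the mean position and the RMSF (root-mean-square deviation from
#' that mean, over the three coordinates jointly) of each selected atom are
#' computed. RMSF is a time-averaged quantity, so each window must contain
#' at least two frames.
#'
#' @param traj A [trajectory_frames()] object.
#' @param n_windows Number of windows (default 800, suitable for
#'   microsecond-scale trajectories).
#' @param selection Atom selection: `"representatives"` (default; protein
#'   C-alpha plus nucleic P), `"calpha"`, `"all"`, or a logical/integer
#'   vector.
#'
#' @return A tibble with one row per window x selected atom: `window`,
#'   the atom labels, mean oriented coordinates `x`, `y`, `z` (nm), `rmsf`
#'   (nm), and `frames_in_window`.
#' @export
windowed_rmsf <- function(traj, n_windows = 800, selection = "representatives") {
  stopifnot(n_windows >= 1)
  sel <- .resolve_selection(traj, selection)
  nf <- n_frames(traj)
  if (nf < 2L * n_windows) {
    abort(sprintf(
      "insufficient frames per window: %d frames cannot fill %d windows with >= 2 frames each.",
      nf, n_windows
    ))
  }
  o <- .orient_all(traj, sel)
  win <- .window_index(nf, n_windows)
  cnt <- as.vector(table(win))
  mx <- rowsum(o$X, win) / cnt
  my <- rowsum(o$Y, win) / cnt
  mz <- rowsum(o$Z, win) / cnt
  sq <- rowsum(o$X^2 + o$Y^2 + o$Z^2, win) / cnt
  msd <- pmax(sq - (mx^2 + my^2 + mz^2), 0)
  rmsf <- sqrt(msd)
  at <- traj$atoms[sel, c("chain", "resid", "resname", "atom")]
  out <- purrr::map_dfr(seq_len(n_windows), function(w) {
    dplyr::bind_cols(
      tibble(window = w),
      at,
      tibble(
        x = mx[w, ], y = my[w, ], z = mz[w, ],
        rmsf = rmsf[w, ], frames_in_window = cnt[w]
      )
    )
  })
  attr(out, "n_windows") <- n_windows
  out
}

# --- Minimal cylinder ---------------------------------------------------

#' Fit the minimal cylinder of one trajectory window
#'
#' Implements the face-stopping construction: atoms are scanned inward from
#' the extreme z on each side, and the face plane stops at the z-coordinate
#' of the `n_exclude`-th atom encountered whose RMSF is below the stiffness
#' threshold (inclusive). Floppy atoms (tails) never stop the plane; if a
#' side has fewer than `n_exclude` stiff atoms the face stays at that side's
#' extreme z. The radius is the largest in-plane distance `sqrt(x^2 + y^2)`
#' among atoms lying between the two faces.
#'
#' @param window A data frame with columns `x`, `y`, `z`, `rmsf` (one row per
#'   atom), e.g. one window of [windowed_rmsf()].
#' @param rmsf_threshold Stiffness cutoff in nm: atoms with `rmsf` strictly
#'   below it are "stiff". `NULL` (default) uses the median RMSF of the
#'   window, a parameter-free choice.
#' @param n_exclude Number of stiff atoms excluded outside each face
#'   (default 10).
#'
#' @return A one-row tibble: `h`, `r`, `z_top`, `z_bottom` (nm),
#'   `excluded_top`, `excluded_bottom`, `rmsf_threshold`.
#' @export
minimal_cylinder <- function(window, rmsf_threshold = NULL, n_exclude = 10) {
  stopifnot(all(c("x", "y", "z", "rmsf") %in% names(window)))
  z <- window$z
  rmsf <- window$rmsf
  n <- length(z)
  if (n < 2L) abort("minimal cylinder needs at least 2 atoms.")
  thr <- rmsf_threshold %||% median(rmsf)
  stiff <- rmsf < thr
  # Scan from the top: order decreasing z, ties by input order (stable).
  ord_top <- order(-z)
  ord_bot <- order(z)
  face <- function(ord) {
    cs <- cumsum(stiff[ord])
    k <- which(cs == n_exclude)[1]
    if (is.na(k)) z[ord[1]] else z[ord[k]]
  }
  z_top <- face(ord_top)
  z_bottom <- face(ord_bot)
  h <- z_top - z_bottom
  if (h <= 0) {
    abort("cylinder collapsed: stiffness threshold leaves no positive height.")
  }
  in_slab <- z >= z_bottom & z <= z_top
  r <- sqrt(max(window$x[in_slab]^2 + window$y[in_slab]^2))
  tibble(
    h = h, r = r, z_top = z_top, z_bottom = z_bottom,
    excluded_top = sum(stiff & z > z_top),
    excluded_bottom = sum(stiff & z < z_bottom),
    rmsf_threshold = thr
  )
}

#' Per-window minimal-cylinder series for a trajectory
#'
#' Convenience pipeline: [windowed_rmsf()] followed by [minimal_cylinder()]
#' on every window.
#'
#' @inheritParams windowed_rmsf
#' @inheritParams minimal_cylinder
#' @return A tibble with one row per window (columns of
#'   [minimal_cylinder()] plus `window`).
#' @export
cylinder_series <- function(traj, n_windows = 800, rmsf_threshold = NULL,
                            n_exclude = 10, selection = "representatives") {
  win <- windowed_rmsf(traj, n_windows = n_windows, selection = selection)
  .series_from_windows(win, rmsf_threshold, n_exclude)
}

.series_from_windows <- function(win, rmsf_threshold, n_exclude) {
  purrr::map_dfr(split(win, win$window), function(w) {
    dplyr::bind_cols(
      tibble(window = w$window[1]),
      minimal_cylinder(w, rmsf_threshold = rmsf_threshold, n_exclude = n_exclude)
    )
  })
}

#' Summary statistics of a minimal-cylinder series
#'
#' Means and population standard deviations of the per-window heights and
#' radii; the SDs are the deformation amplitudes entering the equipartition
#' modulus.
#'
#' @param series A data frame with columns `h` and `r` (nm), one row per
#'   window; at least 2 windows.
#' @return One-row tibble: `h_avg`, `dh`, `r_avg`, `dr` (nm), `n_windows`.
#' @export
cylinder_stats <- function(series) {
  if (is.null(series) || nrow(series) < 2L) {
    abort("cylinder_stats needs at least 2 windows.")
  }
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  tibble(
    h_avg = mean(series$h), dh = pop_sd(series$h),
    r_avg = mean(series$r), dr = pop_sd(series$r),
    n_windows = nrow(series)
  )
}

# --- Equipartition modulus ----------------------------------------------

#' Young's modulus of a thermally vibrating elastic cylinder
#'
#' Treats the particle as a homogeneous elastic cylinder with two
#' independent shear-free deformation modes (axial and radial). Each mode is
#' a quadratic degree of freedom carrying `k_b T / 2` of thermal energy by
#' equipartition; equating that to the stored strain energy
#' `E eps^2 V / 2` of the observed deformation gives, per mode,
#' `E_m = k_b T / (V eps_m^2)` with `V = pi r_avg^2 h_avg` and strains
#' `eps_h = dh / h_avg`, `eps_r = dr / r_avg`. The headline modulus is the
#' arithmetic mean of the modes with non-zero strain.
#'
#' @param stats A one-row data frame with `h_avg`, `dh`, `r_avg`, `dr` (nm),
#'   as from [cylinder_stats()].
#' @param temperature Bath temperature in kelvin (default 300).
#' @return One-row tibble: `E`, `E_axial`, `E_radial` (MPa), `V_nm3`,
#'   `strain_h`, `strain_r`, `temperature`.
#' @examples
#' # V = 414.1947 nm^3 and 10% strains give exactly 1 MPa at 300 K
#' s <- tibble::tibble(
#'   h_avg = 5.5, dh = 0.55,
#'   r_avg = sqrt(414.1947 / (pi * 5.5)), dr = 0.1 * sqrt(414.1947 / (pi * 5.5))
#' )
#' youngs_modulus(s)$E
#' @export
youngs_modulus <- function(stats, temperature = 300) {
  stopifnot(all(c("h_avg", "dh", "r_avg", "dr") %in% names(stats)))
  if (stats$h_avg <= 0 || stats$r_avg <= 0) abort("cylinder dimensions must be positive.")
  eps_h <- stats$dh / stats$h_avg
  eps_r <- stats$dr / stats$r_avg
  if (eps_h == 0 && eps_r == 0) {
    abort("no observable fluctuation: both strains are zero.")
  }
  V <- pi * stats$r_avg^2 * stats$h_avg            # nm^3
  kbt <- .kbT_pN_nm(temperature)                   # pN nm
  # E [pN/nm^2 = MPa] = k_b T / (V eps^2)
  e_mode <- function(eps) if (eps > 0) kbt / (V * eps^2) else NA_real_
  E_axial <- e_mode(eps_h)
  E_radial <- e_mode(eps_r)
  E <- mean(c(E_axial, E_radial), na.rm = TRUE)
  tibble(
    E = E, E_axial = E_axial, E_radial = E_radial,
    V_nm3 = V, strain_h = eps_h, strain_r = eps_r,
    temperature = temperature
  )
}

# --- Full pipeline ------------------------------------------------------

#' Estimate the Young's modulus of a particle from trajectory fluctuations
#'
#' Runs the full minimal-cylinder / equipartition pipeline: orient every
#' frame on its principal inertia axes, compute windowed per-atom RMSF, fit
#' a minimal cylinder per window with the stiff-face stopping rule, reduce
#' to mean dimensions and deformation SDs, and convert to a modulus by
#' equipartition. The headline `E` comes from the whole analyzed range; its
#' uncertainty is the SD of `E` recomputed on `n_subsections` contiguous
#' equal subsections.
#'
#' @inheritParams windowed_rmsf
#' @inheritParams minimal_cylinder
#' @param n_subsections Number of contiguous equal subsections used for the
#'   SD of the modulus (default 3).
#' @param temperature Bath temperature, K.
#' @param frames Optional integer vector of frame indices to analyse (e.g.
#'   to trim an equilibration period); default all frames.
#'
#' @return An object of class `elasticity_fit`; see [tidy.elasticity_fit()]
#'   and [glance.elasticity_fit()]. Key fields: `$estimate` (one-row tibble
#'   with `E`, `E_axial`, `E_radial`, `sd`, geometry and strains),
#'   `$subsections`, `$series` (per-window cylinders), `$params`.
#' @examples
#' traj <- gen_cylinder_trajectory(E_true = 10, n_frames = 400, seed = 1)
#' fit <- estimate_elasticity(traj, n_windows = 40, n_subsections = 2)
#' glance(fit)
#' @export
estimate_elasticity <- function(traj, n_windows = 800, rmsf_threshold = NULL,
                                n_exclude = 10, n_subsections = 3,
                                temperature = 300, frames = NULL,
                                selection = "representatives") {
  if (!is.null(frames)) traj <- .subset_frames(traj, frames = frames)
  nf <- n_frames(traj)
  if (nf < 2L * n_windows * max(n_subsections, 1L)) {
    abort("insufficient frames per window across subsections.")
  }
  sel <- .resolve_selection(traj, selection)
  o <- .orient_all(traj, sel)
  run <- function(frame_idx) {
    win_id <- .window_index(length(frame_idx), n_windows)
    X <- o$X[frame_idx, , drop = FALSE]
    Y <- o$Y[frame_idx, , drop = FALSE]
    Z <- o$Z[frame_idx, , drop = FALSE]
    cnt <- as.vector(table(win_id))
    mx <- rowsum(X, win_id) / cnt
    my <- rowsum(Y, win_id) / cnt
    mz <- rowsum(Z, win_id) / cnt
    sq <- rowsum(X^2 + Y^2 + Z^2, win_id) / cnt
    rmsf <- sqrt(pmax(sq - (mx^2 + my^2 + mz^2), 0))
    series <- purrr::map_dfr(seq_len(n_windows), function(w) {
      wd <- tibble(x = mx[w, ], y = my[w, ], z = mz[w, ], rmsf = rmsf[w, ])
      dplyr::bind_cols(
        tibble(window = w),
        minimal_cylinder(wd, rmsf_threshold = rmsf_threshold, n_exclude = n_exclude)
      )
    })
    series
  }
  series <- run(seq_len(nf))
  stats <- cylinder_stats(series)
  est <- youngs_modulus(stats, temperature = temperature)
  sub_id <- .window_index(nf, n_subsections)
  sub_E <- vapply(seq_len(n_subsections), function(s) {
    ser <- run(which(sub_id == s))
    youngs_modulus(cylinder_stats(ser), temperature = temperature)$E
  }, numeric(1))
  estimate <- dplyr::bind_cols(
    est[, c("E", "E_axial", "E_radial")],
    tibble(sd = sd(sub_E)),
    est[, c("V_nm3", "strain_h", "strain_r", "temperature")],
    stats[, c("h_avg", "dh", "r_avg", "dr")]
  )
  structure(
    list(
      estimate = estimate,
      subsections = tibble(subsection = seq_len(n_subsections), E = sub_E),
      series = series,
      stats = stats,
      params = list(
        n_windows = n_windows, rmsf_threshold = rmsf_threshold,
        n_exclude = n_exclude, n_subsections = n_subsections,
        temperature = temperature, n_frames = nf,
        selection = if (is.character(selection)) selection else "custom"
      )
    ),
    class = "elasticity_fit"
  )
}

#' @export
print.elasticity_fit <- function(x, ...) {
  e <- x$estimate
  cat(sprintf(
    "<elasticity_fit> E = %.3g +/- %.2g MPa (axial %.3g, radial %.3g)\n",
    e$E, e$sd, e$E_axial, e$E_radial
  ))
  cat(sprintf(
    "  cylinder: h = %.3g +/- %.2g nm, r = %.3g +/- %.2g nm, V = %.4g nm^3\n",
    e$h_avg, e$dh, e$r_avg, e$dr, e$V_nm3
  ))
  cat(sprintf(
    "  %d windows over %d frames, T = %g K\n",
    x$params$n_windows, x$params$n_frames, e$temperature
  ))
  invisible(x)
}
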