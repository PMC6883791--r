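# --- Superposition ------------------------------------------------------

# Kabsch least-squares superposition: returns the proper rotation R and
# translation that map `mobile` onto `ref` (both n x 3), optionally
# weighted. Applied as sweep(mobile, 2, mob_c) %*% R + ref_c.
.kabsch <- function(mobile, ref, weights = NULL) {
  n <- nrow(mobile)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  mob_c <- colSums(mobile * w)
  ref_c <- colSums(ref * w)
  a <- sweep(mobile, 2, mob_c)
  b <- sweep(ref, 2, ref_c)
  h <- crossprod(a * w, b)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = rot, mobile_center = mob_c, ref_center = ref_c)
}

# Superpose every frame of `traj` onto `ref_coords` using the atoms in
# `fit_idx`; returns the list of transformed full-frame coordinate matrices.
.superpose_frames <- function(traj, ref_coords, fit_idx) {
  lapply(traj$coords, function(m) {
    k <- .kabsch(m[fit_idx, , drop = FALSE], ref_coords[fit_idx, , drop = FALSE])
    sweep(sweep(m, 2, k$mobile_center) %*% k$rotation, 2, k$ref_center, "+")
  })
}

# --- Phosphate triad ----------------------------------------------------

#' Extract a labelled phosphate triad from a trajectory
#'
#' Tracks three DNA backbone phosphates (by convention the positions -33,
#' -43 and +38 relative to the pseudodyad, numbered 5' to 3') across a
#' trajectory. The reference frame is oriented on its principal inertia
#' axes; every other frame is least-squares superposed onto it using the
#' histone-core C-alpha atoms, so rigid body motion of the whole particle
#' cannot masquerade as DNA motion. Coordinates are then translated so the
#' reference position of the first vertex (-33) is the origin.
#'
#' @param traj A [trajectory_frames()] object.
#' @param residues Integer vector (length 3) of residue numbers, as they
#'   appear in the trajectory labels.
#' @param chains Character vector (length 3, or 1 recycled) of chain ids.
#' @param labels Display labels for the three vertices; default
#'   `c("-33", "-43", "+38")`.
#' @param fit_selection Atom selection used for superposition; default
#'   `"calpha"` (protein C-alpha only, excluding DNA and anything the user
#'   filters out beforehand).
#' @param reference_frame Index of the reference frame (default 1).
#'
#' @return An object of class `phosphate_triad`: a tibble with columns
#'   `frame`, `label`, `x`, `y`, `z` (nm) and the reference stored in
#'   attributes.
#' @export
extract_triad <- function(traj, residues, chains,
                          labels = c("-33", "-43", "+38"),
                          fit_selection = "calpha", reference_frame = 1) {
  stopifnot(length(residues) == 3L)
  chains <- rep_len(chains, 3L)
  at <- traj$atoms
  idx <- vapply(1:3, function(i) {
    j <- which(at$chain == chains[i] & at$resid == residues[i] & at$atom == "P")
    if (length(j) == 0L) {
      abort(sprintf("triad atom not found: chain %s residue %d has no P atom.",
                    chains[i], residues[i]))
    }
    if (length(j) > 1L) {
      abort(sprintf("ambiguous chain mapping: chain %s residue %d has %d P atoms.",
                    chains[i], residues[i], length(j)))
    }
    j
  }, integer(1))
  fit_idx <- .resolve_selection(traj, fit_selection)
  nf <- n_frames(traj)
  stopifnot(reference_frame >= 1, reference_frame <= nf)
  ref <- orient_frame(traj$coords[[reference_frame]], traj$atoms$mass)$coords
  sup <- .superpose_frames(traj, ref, fit_idx)
  origin <- ref[idx[1], ]
  out <- purrr::map_dfr(seq_len(nf), function(f) {
    v <- sweep(sup[[f]][idx, , drop = FALSE], 2, origin)
    tibble(frame = f, label = labels, x = v[, 1], y = v[, 2], z = v[, 3])
  })
  class(out) <- c("phosphate_triad", class(out))
  attr(out, "labels") <- labels
  attr(out, "reference_frame") <- reference_frame
  out
}

# --- Gaping / sliding ---------------------------------------------------

.vertex_angles <- function(p1, p2, p3) {
  ang <- function(a, b, c) {
    u <- b - a; v <- c - a
    acos(pmin(pmax(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1), 1))
  }
  c(ang(p1, p2, p3), ang(p2, p3, p1), ang(p3, p1, p2))
}

#' Gaping and sliding displacements from a phosphate triad
#'
#' Per frame, decomposes the displacement of the +38 vertex from its
#' reference position into gaping (`dy`: the component along the oriented
#' superhelical z-axis, i.e. the gyres separating out of plane) and sliding
#' (`dx`: the in-plane component along the local DNA tangent, estimated from
#' the reference -33 to -43 direction). Triangle side lengths and the skew
#' (mean absolute deviation of the three vertex angles from the reference
#' triangle, degrees) are recorded alongside.
#'
#' @param triad A [extract_triad()] result with at least 2 frames.
#' @return A tibble of class `gape_slide_series`: `frame`, `dx_nm`, `dy_nm`,
#'   `side_12_nm`, `side_13_nm`, `side_23_nm`, `skew_deg`.
#' @export
gape_slide <- function(triad) {
  labels <- attr(triad, "labels") %||% unique(triad$label)
  ref_f <- attr(triad, "reference_frame") %||% 1L
  frames <- unique(triad$frame)
  if (length(frames) < 2L) abort("gape_slide needs at least 2 frames.")
  get_frame <- function(f) {
    v <- triad[triad$frame == f, ]
    v <- v[match(labels, v$label), ]
    as.matrix(v[, c("x", "y", "z")])
  }
  ref <- get_frame(ref_f)
  # Local DNA tangent at +38: reference -33 -> -43 direction, projected in
  # plane (z dropped) and normalised.
  tangent <- ref[2, ] - ref[1, ]
  tangent[3] <- 0
  tn <- sqrt(sum(tangent^2))
  if (tn < 1e-12) abort("degenerate reference triangle: in-plane tangent undefined.")
  tangent <- tangent / tn
  ref_ang <- .vertex_angles(ref[1, ], ref[2, ], ref[3, ])
  if (any(!is.finite(ref_ang)) || min(ref_ang) < 1e-6) {
    abort("degenerate reference triangle: collinear vertices.")
  }
  out <- purrr::map_dfr(frames, function(f) {
    v <- get_frame(f)
    d38 <- v[3, ] - ref[3, ]
    ang <- .vertex_angles(v[1, ], v[2, ], v[3, ])
    tibble(
      frame = f,
      dx_nm = sum(d38 * tangent),
      dy_nm = unname(d38[3]),
      side_12_nm = sqrt(sum((v[1, ] - v[2, ])^2)),
      side_13_nm = sqrt(sum((v[1, ] - v[3, ])^2)),
      side_23_nm = sqrt(sum((v[2, ] - v[3, ])^2)),
      skew_deg = mean(abs(ang - ref_ang)) * 180 / pi
    )
  })
  class(out) <- c("gape_slide_series", class(out))
  attr(out, "labels") <- labels
  attr(out, "reference_frame") <- ref_f
  out
}

#' Box-plot summary of gaping and sliding distributions
#'
#' For each displacement component, the statistics of a standard box plot
#' with whiskers at the extrema: mean, median, quartiles (linear
#' interpolation between order statistics, i.e. `quantile(type = 7)`), min
#' and max. The vertex triangles at the frames of minimum and maximum skew
#' are attached as the `"extreme_triangles"` attribute.
#'
#' @param series A [gape_slide()] result (non-empty).
#' @param triad Optional: the originating [extract_triad()] object; when
#'   supplied, the extreme-skew triangles carry vertex coordinates.
#' @return A tibble with one row per component (`dx_nm`, `dy_nm`).
#' @export
gape_slide_summary <- function(series, triad = NULL) {
  if (is.null(series) || nrow(series) == 0L) abort("empty series.")
  one <- function(v, name) {
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble(
      component = name, mean = mean(v), median = q[2],
      q1 = q[1], q3 = q[3], min = min(v), max = max(v)
    )
  }
  out <- dplyr::bind_rows(one(series$dx_nm, "dx_nm"), one(series$dy_nm, "dy_nm"))
  f_min <- series$frame[which.min(series$skew_deg)]
  f_max <- series$frame[which.max(series$skew_deg)]
  tri <- tibble(which = c("min_skew", "max_skew"), frame = c(f_min, f_max))
  if (!is.null(triad)) {
    tri <- dplyr::left_join(
      tri, as_tibble(triad)[, c("frame", "label", "x", "y", "z")],
      by = "frame"
    )
  }
  attr(out, "extreme_triangles") <- tri
  out
}
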