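# Iteratively superpose all frames of `traj` (selection atoms only) onto the
# mean structure: first pass fits onto frame 1, then `n_iter` passes onto
# the running mean. Returns the n_frames x 3n matrix of superposed selected
# coordinates and the final mean structure (n_sel x 3).
.superposed_matrix <- function(traj, sel_idx, n_iter = 2) {
  coords <- lapply(traj$coords, function(m) m[sel_idx, , drop = FALSE])
  ref <- coords[[1]]
  for (it in seq_len(n_iter + 1L)) {
    fit_all <- lapply(coords, function(m) {
      k <- .kabsch(m, ref)
      sweep(sweep(m, 2, k$mobile_center) %*% k$rotation, 2, k$ref_center, "+")
    })
    mean_s <- Reduce(`+`, fit_all) / length(fit_all)
    if (it <= n_iter) ref <- mean_s
  }
  mat <- do.call(rbind, lapply(fit_all, function(m) as.vector(t(m))))
  list(matrix = mat, mean = mean_s)
}

#' Principal component analysis of trajectory fluctuations
#'
#' Superposes the selected atoms of every frame onto their mean structure
#' (iterated twice), then decomposes the covariance of the concatenated 3N
#' coordinates. Modes are sorted by decreasing variance, identifying the
#' largest-amplitude collective motions.
#'
#' @inheritParams windowed_rmsf
#' @param n_iter Superposition iterations onto the running mean (default 2).
#' @param superpose Set `FALSE` to skip superposition (coordinates already
#'   aligned).
#'
#' @return An object of class `traj_pca`: `mean_structure` (n_sel x 3 nm),
#'   `modes` (3N x k orthonormal columns), `variances` (nm^2, decreasing),
#'   `projections` (n_frames x k scores, nm), `atoms` (labels of the
#'   selection).
#' @export
pca_modes <- function(traj, selection = "representatives", n_iter = 2,
                      superpose = TRUE) {
  if (n_frames(traj) < 3L) abort("PCA needs at least 3 frames.")
  sel <- .resolve_selection(traj, selection)
  if (superpose) {
    sp <- .superposed_matrix(traj, sel, n_iter = n_iter)
    mat <- sp$matrix
    mean_s <- sp$mean
  } else {
    mat <- do.call(rbind, lapply(traj$coords, function(m) {
      as.vector(t(m[sel, , drop = FALSE]))
    }))
    mean_s <- matrix(colMeans(mat), ncol = 3, byrow = TRUE)
  }
  pc <- prcomp(mat, center = TRUE, scale. = FALSE)
  modes <- unname(pc$rotation)
  projections <- unname(pc$x)
  structure(
    list(
      mean_structure = mean_s,
      modes = modes,
      variances = pc$sdev^2,
      projections = projections,
      atoms = traj$atoms[sel, c("chain", "resid", "resname", "atom")]
    ),
    class = "traj_pca"
  )
}

#' @export
print.traj_pca <- function(x, ...) {
  vtot <- sum(x$variances)
  cat(sprintf(
    "<traj_pca> %d frames, %d atoms; PC1/PC2 variance fractions %.1f%% / %.1f%%\n",
    nrow(x$projections), nrow(x$atoms),
    100 * x$variances[1] / vtot, 100 * x$variances[2] / vtot
  ))
  invisible(x)
}

#' Free-energy surface from the first two principal components
#'
#' Histograms the frame scores on two PCs and Boltzmann-inverts the
#' occupancy: `FE_i = -ln(N_i / N_max)` in units of `k_b T`, so the global
#' minimum over occupied bins is 0. Unoccupied bins are reported with
#' `fe_kbt = NA` (unknown, not zero energy).
#'
#' @param x A [pca_modes()] result, or a matrix/data frame whose first two
#'   columns are the scores.
#' @param n_bins Bins per axis (default 50; >= 2).
#' @param pcs Which two components to use when `x` is a `traj_pca`.
#'
#' @return A tibble of class `fe_surface` in long format: `pc1_center`,
#'   `pc2_center`, `count`, `fe_kbt`; bin edges in attributes.
#' @export
free_energy_surface <- function(x, n_bins = 50, pcs = c(1, 2)) {
  if (inherits(x, "traj_pca")) {
    if (ncol(x$projections) < max(pcs)) abort("not enough PCs in the decomposition.")
    p1 <- x$projections[, pcs[1]]
    p2 <- x$projections[, pcs[2]]
  } else {
    m <- as.matrix(x)
    if (ncol(m) < 2L) abort("need two score columns.")
    p1 <- m[, 1]; p2 <- m[, 2]
  }
  if (length(p1) < 1L) abort("zero frames: nothing to histogram.")
  if (n_bins < 2L) abort("n_bins must be >= 2 per axis.")
  pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r
  r1 <- pad(range(p1)); r2 <- pad(range(p2))
  b1 <- seq(r1[1], r1[2], length.out = n_bins + 1L)
  b2 <- seq(r2[1], r2[2], length.out = n_bins + 1L)
  i1 <- findInterval(p1, b1, rightmost.closed = TRUE, all.inside = TRUE)
  i2 <- findInterval(p2, b2, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, n_bins, n_bins)
  tab <- table(factor(i1, levels = seq_len(n_bins)),
               factor(i2, levels = seq_len(n_bins)))
  counts[] <- as.integer(tab)
  n_max <- max(counts)
  centers1 <- (head(b1, -1) + tail(b1, -1)) / 2
  centers2 <- (head(b2, -1) + tail(b2, -1)) / 2
  out <- tidyr::expand_grid(pc1_bin = seq_len(n_bins), pc2_bin = seq_len(n_bins)) |>
    mutate(
      pc1_center = centers1[.data$pc1_bin],
      pc2_center = centers2[.data$pc2_bin],
      count = counts[cbind(.data$pc1_bin, .data$pc2_bin)],
      fe_kbt = ifelse(.data$count > 0, -log(.data$count / n_max), NA_real_)
    ) |>
    select("pc1_center", "pc2_center", "count", "fe_kbt")
  class(out) <- c("fe_surface", class(out))
  attr(out, "breaks_pc1") <- b1
  attr(out, "breaks_pc2") <- b2
  out
}

#' Per-residue RMSF profile over a whole trajectory
#'
#' Superposes the selected atoms of every frame onto their mean structure
#' (iterated twice) and reports each atom's root-mean-square fluctuation
#' about its time-averaged position.
#'
#' @inheritParams pca_modes
#' @return A tibble: `chain`, `resid`, `resname`, `atom`, `rmsf_nm`.
#' @export
rmsf_profile <- function(traj, selection = "representatives", superpose = TRUE) {
  if (n_frames(traj) < 2L) abort("RMSF needs at least 2 frames.")
  sel <- .resolve_selection(traj, selection)
  if (superpose) {
    sp <- .superposed_matrix(traj, sel, n_iter = 2)
    mat <- sp$matrix
  } else {
    mat <- do.call(rbind, lapply(traj$coords, function(m) {
      as.vector(t(m[sel, , drop = FALSE]))
    }))
  }
  dev2 <- sweep(mat, 2, colMeans(mat))^2
  per_atom <- matrix(colMeans(dev2), ncol = 3, byrow = TRUE)
  dplyr::bind_cols(
    traj$atoms[sel, c("chain", "resid", "resname", "atom")],
    tibble(rmsf_nm = sqrt(rowSums(per_atom)))
  )
}

#' Difference of two RMSF profiles
#'
#' Elementwise difference (`a - b`) of two profiles with identical atom
#' labels, e.g. to quantify how a bound ligand suppresses fluctuations.
#'
#' @param a,b Tibbles from [rmsf_profile()] with identical label columns.
#' @return `a` with `rmsf_nm` replaced by `delta_rmsf_nm`.
#' @export
rmsf_difference <- function(a, b) {
  keys <- c("chain", "resid", "resname", "atom")
  if (!identical(a[keys], b[keys])) {
    abort("profiles must share identical atom labels, in the same order.")
  }
  dplyr::bind_cols(a[keys], tibble(delta_rmsf_nm = a$rmsf_nm - b$rmsf_nm))
}
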