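# Shared fixtures and independent oracles, all built in code.

# A rigid scaffold whose principal inertia axes coincide with the coordinate
# axes (flat pancake: largest moment about z), so orient_frame() is the
# identity on it. Optional extra atoms are appended unchanged.
axis_aligned_scaffold <- function(extra = NULL) {
  pts <- rbind(
    c(4, 0, 0), c(-4, 0, 0),
    c(0, 3, 0), c(0, -3, 0),
    c(0, 0, 1), c(0, 0, -1)
  )
  if (!is.null(extra)) pts <- rbind(pts, extra)
  pts
}

scaffold_atoms <- function(n, chain = "H", atom = "CA", resname = "ALA",
                           mass = 12) {
  tibble::tibble(
    chain = chain, resid = seq_len(n), resname = resname, atom = atom,
    element = "C", mass = mass, representative = TRUE
  )
}

# Random proper rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(traj, rot, shift) {
  coords <- lapply(traj$coords, function(m) {
    sweep(m %*% t(rot), 2, shift, "+")
  })
  trajectory_frames(coords, traj$atoms)
}

# Independent inertia oracle: height of a point set measured along the
# eigenvector of the largest principal moment, computed element by element.
oracle_extent_along_major_moment <- function(coords, masses) {
  com <- colSums(coords * masses) / sum(masses)
  x <- sweep(coords, 2, com)
  I <- matrix(0, 3, 3)
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    I <- I + masses[i] * (sum(r^2) * diag(3) - outer(r, r))
  }
  v <- eigen(I, symmetric = TRUE)$vectors[, 1]
  proj <- x %*% v
  diff(range(proj))
}

# Independent minimal-cylinder oracle for tie-free windows: the face is the
# n-th largest (smallest) z among stiff atoms, or the extreme z if fewer
# than n stiff atoms exist on that side. A non-positive height means the
# faces crossed (threshold too permissive) and the fit must refuse.
oracle_minimal_cylinder <- function(df, thr, n_excl) {
  stiff_z <- sort(df$z[df$rmsf < thr], decreasing = TRUE)
  z_top <- if (length(stiff_z) >= n_excl) stiff_z[n_excl] else max(df$z)
  stiff_z_b <- sort(df$z[df$rmsf < thr])
  z_bot <- if (length(stiff_z_b) >= n_excl) stiff_z_b[n_excl] else min(df$z)
  if (z_top - z_bot <= 0) {
    return(list(collapsed = TRUE, z_top = z_top, z_bottom = z_bot,
                h = z_top - z_bot, r = NA_real_))
  }
  keep <- df$z >= z_bot & df$z <= z_top
  list(collapsed = FALSE, z_top = z_top, z_bottom = z_bot, h = z_top - z_bot,
       r = sqrt(max(df$x[keep]^2 + df$y[keep]^2)))
}

# Independent linear-interpolation quantile (the type-7 convention, written
# out from the definition).
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Brute-force connected components of the distance graph (edges d <= cutoff).
oracle_distance_components <- function(xy, cutoff) {
  n <- nrow(xy)
  adj <- as.matrix(dist(xy)) <= cutoff
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  igraph::components(g)$membership
}

# Small synthetic trajectory for fast end-to-end elasticity tests.
small_breathing_traj <- function(E_true = 10, n_frames = 600, seed = 11) {
  gen_cylinder_trajectory(E_true = E_true, n_frames = n_frames, seed = seed)
}
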