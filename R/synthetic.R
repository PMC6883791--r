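# Run expr with a private, seeded RNG stream; the caller's RNG state is
# untouched, so adding generators never perturbs existing fixtures.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

#' Generate a breathing elastic-cylinder trajectory with known modulus
#'
#' Synthesises the inverse of the minimal-cylinder estimator's model: a
#' cylinder of rest height `h0` and radius `r0` whose height and radius
#' breathe with Gaussian strains of standard deviation
#' `sigma = sqrt(k_b T / (E_true * pi * r0^2 * h0))`, so that
#' [estimate_elasticity()] should recover `E_true`. The cylinder surface is
#' decorated with point particles that ride the breathing rigidly plus
#' small isotropic jitter (low RMSF, hence "stiff"); floppy tail particles
#' with 5-fold jitter sit beyond the faces, exercising the stiff-residue
#' exclusion rule; two heavy equatorial anchor particles break the lateral
#' inertia degeneracy so per-frame principal axes are stable.
#'
#' The breathing strain is redrawn every `frames_per_deformation` frames and
#' held constant in between, emulating the separation between the slow
#' collective breathing mode and fast atomic jitter that windowed-RMSF
#' analysis presumes; atomic jitter is redrawn every frame.
#'
#' @param E_true Target Young's modulus, MPa. `Inf` disables breathing.
#' @param h0,r0 Rest height and radius, nm (defaults 5.5 nm, the scale of a
#'   nucleosome core particle).
#' @param n_surface Lateral-wall particles (default 150).
#' @param n_face_markers Stiff markers per face (default 40).
#' @param n_tails Floppy tail particles (default 20).
#' @param jitter_sd Per-axis jitter SD of stiff particles, nm (default 0.03).
#' @param n_frames Number of frames (default 8000).
#' @param temperature Bath temperature, K (default 300).
#' @param frames_per_deformation Frames per breathing draw (default 10).
#' @param seed RNG seed; same seed, same trajectory, bit for bit.
#'
#' @return A [trajectory_frames()] object whose ground truth is stored in
#'   attribute `"ground_truth"`.
#' @export
gen_cylinder_trajectory <- function(E_true = 10, h0 = 5.5, r0 = 5.5,
                                    n_surface = 150, n_face_markers = 40,
                                    n_tails = 20, jitter_sd = 0.03,
                                    n_frames = 8000, temperature = 300,
                                    frames_per_deformation = 10, seed = 1) {
  stopifnot(E_true > 0, h0 > 0, r0 > 0, n_frames >= 2)
  sigma <- if (is.finite(E_true)) {
    sqrt(.kbT_pN_nm(temperature) / (E_true * pi * r0^2 * h0))
  } else 0
  if (sigma >= 0.5) {
    abort("fluctuation too large for linear elasticity: sigma >= 0.5; increase E_true or the cylinder volume.")
  }
  .with_seed(seed, {
    # Base layout (shared by all frames). z and radius are stored as
    # fractions of h0 / r0 so breathing is a pure scale factor. Every
    # decoration is placed as an antipodal pair (theta, theta + pi) at the
    # same height, so the rest layout is exactly balanced: its centre of
    # mass sits on the cylinder axis and its inertia cross-moments vanish,
    # leaving the per-frame principal axes aligned with the true cylinder
    # axes up to jitter.
    pair <- function(df) {
      dplyr::bind_rows(df, mutate(df, theta = .data$theta + pi))
    }
    wall <- pair(tibble(
      kind = "wall", chain = "A",
      zfrac = runif(ceiling(n_surface / 2), -0.5, 0.5),
      rfrac = 1,
      theta = runif(ceiling(n_surface / 2), 0, 2 * pi),
      mass = 12, jitter = jitter_sd
    ))
    half_face <- ceiling(n_face_markers / 2)
    faces <- dplyr::bind_rows(
      pair(tibble(kind = "face_top", chain = "B", zfrac = 0.5,
                  rfrac = runif(half_face, 0, 0.8),
                  theta = runif(half_face, 0, 2 * pi),
                  mass = 12, jitter = jitter_sd)),
      pair(tibble(kind = "face_bottom", chain = "C", zfrac = -0.5,
                  rfrac = runif(half_face, 0, 0.8),
                  theta = runif(half_face, 0, 2 * pi),
                  mass = 12, jitter = jitter_sd))
    )
    half_tails <- ceiling(n_tails / 2)
    tails <- pair(tibble(
      kind = "tail", chain = "T",
      zfrac = sample(c(-1, 1), half_tails, replace = TRUE) *
        (0.5 + runif(half_tails, 0.05, 0.2)),
      rfrac = runif(half_tails, 0, 0.4),
      theta = runif(half_tails, 0, 2 * pi),
      mass = 12, jitter = 5 * jitter_sd
    ))
    # Heavy equatorial anchors along +/- x: break the transverse inertia
    # degeneracy of the cylinder so principal axes do not wander in x-y.
    anchors <- tibble(
      kind = "anchor", chain = "X", zfrac = 0, rfrac = 1,
      theta = c(0, pi), mass = 600, jitter = jitter_sd
    )
    layout <- dplyr::bind_rows(wall, faces, tails, anchors)
    np <- nrow(layout)
    atoms <- tibble(
      chain = layout$chain,
      resid = seq_len(np),
      resname = "CYL",
      atom = "CA",
      element = "C",
      mass = layout$mass,
      representative = TRUE
    )
    n_blocks <- ceiling(n_frames / frames_per_deformation)
    eta_h <- rep(rnorm(n_blocks, 0, sigma), each = frames_per_deformation)[seq_len(n_frames)]
    eta_r <- rep(rnorm(n_blocks, 0, sigma), each = frames_per_deformation)[seq_len(n_frames)]
    base_r <- layout$rfrac * r0
    base_z <- layout$zfrac * h0
    cth <- cos(layout$theta)
    sth <- sin(layout$theta)
    jit <- layout$jitter
    coords <- lapply(seq_len(n_frames), function(f) {
      rad <- base_r * (1 + eta_r[f])
      zz <- base_z * (1 + eta_h[f])
      cbind(
        rad * cth + rnorm(np, 0, jit),
        rad * sth + rnorm(np, 0, jit),
        zz + rnorm(np, 0, jit)
      )
    })
    traj <- trajectory_frames(coords, atoms)
    attr(traj, "ground_truth") <- list(
      E_true = E_true, h0 = h0, r0 = r0, sigma = sigma,
      jitter_sd = jitter_sd, temperature = temperature,
      frames_per_deformation = frames_per_deformation, seed = seed,
      eta_h = eta_h, eta_r = eta_r
    )
    traj
  })
}

#' Generate a synthetic Hertz force curve with known modulus
#'
#' A zero-force baseline of `baseline_len` samples up to `contact_at`,
#' followed by the spherical-indenter Hertz force law, plus Gaussian force
#' noise. The sample spacing is `contact_at / baseline_len`; indentation
#' runs to `max_indent`.
#'
#' @param E Young's modulus, MPa.
#' @param nu Poisson ratio (default 1/3).
#' @param R Tip radius, nm (default 10).
#' @param contact_at Contact point on the displacement axis, nm (default 20).
#' @param baseline_len Number of pre-contact samples (default 80).
#' @param max_indent Maximum indentation, nm (default 2).
#' @param noise_sd Gaussian force-noise SD, pN (default 0).
#' @param seed RNG seed.
#'
#' @return A [force_curve()] with ground truth in attribute `"ground_truth"`.
#' @export
gen_force_curve <- function(E = 10, nu = 1 / 3, R = 10, contact_at = 20,
                            baseline_len = 80, max_indent = 2,
                            noise_sd = 0, seed = 1) {
  stopifnot(E > 0, R > 0, contact_at > 0, baseline_len >= 2)
  step <- contact_at / baseline_len
  d <- seq(0, contact_at + max_indent, by = step)
  delta <- pmax(d - contact_at, 0)
  f <- hertz_force(delta, E = E, nu = nu, R = R)
  .with_seed(seed, {
    f <- f + rnorm(length(f), 0, noise_sd)
    curve <- force_curve(d, f, tip_radius = R, poisson = nu,
                         note = "synthetic Hertz curve")
    attr(curve, "ground_truth") <- list(
      E = E, nu = nu, R = R, contact_at = contact_at,
      step_nm = step, noise_sd = noise_sd, seed = seed
    )
    curve
  })
}

#' Generate a synthetic AFM height image of Gaussian-bump particles
#'
#' Sums isotropic Gaussian bumps on a flat background and adds pixel noise.
#' Overlapping bumps are allowed (they exercise particle-merging behaviour)
#' and flagged in the ground truth.
#'
#' @param particles A data frame with columns `x_nm`, `y_nm`, `height_nm`,
#'   `sigma_nm`; may have zero rows.
#' @param extent_nm Image extent `c(width, height)` in nm (default 500 x 500).
#' @param pixel_size Pixel size, nm (default 2).
#' @param background Background level, nm (default 0).
#' @param noise_sd Gaussian height-noise SD, nm (default 0).
#' @param seed RNG seed.
#'
#' @return A [height_image()] with the particle table (plus an `overlaps`
#'   flag) in attribute `"ground_truth"`.
#' @export
gen_afm_image <- function(particles = tibble(x_nm = double(), y_nm = double(),
                                             height_nm = double(), sigma_nm = double()),
                          extent_nm = c(500, 500), pixel_size = 2,
                          background = 0, noise_sd = 0, seed = 1) {
  stopifnot(pixel_size > 0, all(extent_nm > 0))
  particles <- as_tibble(particles)
  nx <- max(2L, round(extent_nm[1] / pixel_size))
  ny <- max(2L, round(extent_nm[2] / pixel_size))
  xs <- (seq_len(nx) - 0.5) * pixel_size
  ys <- (seq_len(ny) - 0.5) * pixel_size
  g <- matrix(background, nrow = ny, ncol = nx)
  np <- nrow(particles)
  if (np > 0L) {
    for (k in seq_len(np)) {
      gx <- exp(-(xs - particles$x_nm[k])^2 / (2 * particles$sigma_nm[k]^2))
      gy <- exp(-(ys - particles$y_nm[k])^2 / (2 * particles$sigma_nm[k]^2))
      g <- g + particles$height_nm[k] * outer(gy, gx)
    }
  }
  overlaps <- rep(FALSE, np)
  if (np > 1L) {
    dm <- as.matrix(dist(cbind(particles$x_nm, particles$y_nm)))
    sig <- outer(particles$sigma_nm, particles$sigma_nm, `+`)
    diag(dm) <- Inf
    overlaps <- apply(dm < 3 * sig, 1, any)
  }
  .with_seed(seed, {
    if (noise_sd > 0) g <- g + matrix(rnorm(length(g), 0, noise_sd), nrow(g), ncol(g))
    img <- height_image(g, pixel_size = pixel_size, background = background)
    attr(img, "ground_truth") <- dplyr::bind_cols(particles, tibble(overlaps = overlaps))
    img
  })
}

#' Rasterise a filled ellipse as a height image
#'
#' A flat-topped elliptical particle on a zero background, the canonical
#' test object for the roundness metric: a disc (`axis_ratio = 1`) scores
#' 1, a 2:1 ellipse scores 0.5.
#'
#' @param semi_major_px Semi-major axis in pixels (>= 10 for a faithful
#'   raster).
#' @param axis_ratio Major/minor axis ratio (>= 1; default 1, a disc).
#' @param angle_deg Orientation of the major axis, degrees (default 0).
#' @param height_nm Plateau height, nm (default 3).
#' @param pixel_size Pixel size, nm (default 1).
#' @param pad_px Blank margin around the ellipse, pixels. The default scales
#'   with the ellipse so the background dominates the raster.
#'
#' @return A [height_image()].
#' @export
gen_ellipse_image <- function(semi_major_px, axis_ratio = 1, angle_deg = 0,
                              height_nm = 3, pixel_size = 1,
                              pad_px = ceiling(semi_major_px) + 5) {
  stopifnot(semi_major_px >= 2, axis_ratio >= 1, height_nm > 0)
  a <- semi_major_px
  b <- semi_major_px / axis_ratio
  half <- ceiling(a) + pad_px
  n <- 2L * half + 1L
  ctr <- half + 1L
  th <- angle_deg * pi / 180
  ij <- expand.grid(row = seq_len(n), col = seq_len(n))
  dx <- ij$col - ctr
  dy <- ij$row - ctr
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  g <- matrix(0, n, n)
  g[cbind(ij$row, ij$col)[inside, , drop = FALSE]] <- height_nm
  height_image(g, pixel_size = pixel_size, background = 0)
}
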