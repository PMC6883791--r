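test_that("orient_frame is the identity on an axis-aligned centred set", {
  pts <- axis_aligned_scaffold()
  o <- orient_frame(pts)
  # output equals input up to axis-sign convention
  expect_equal(abs(o$coords), abs(pts), tolerance = 1e-12)
  expect_equal(det(o$rotation), 1, tolerance = 1e-12)
})

test_that("oriented z-extent of a rigidly rotated cylinder matches the inertia oracle", {
  set.seed(42)
  th <- runif(100, 0, 2 * pi)
  zz <- runif(100, -3, 3)
  pts <- cbind(5 * cos(th), 5 * sin(th), zz)
  masses <- runif(100, 10, 14)
  true_extent <- oracle_extent_along_major_moment(pts, masses)
  for (i in 1:5) {
    rot <- random_rotation()
    moved <- sweep(pts %*% t(rot), 2, rnorm(3, 0, 10), "+")
    o <- orient_frame(moved, masses)
    expect_equal(diff(range(o$coords[, 3])), true_extent, tolerance = 1e-9)
  }
})

test_that("orient_frame rejects degenerate geometry", {
  expect_error(orient_frame(rbind(c(0, 0, 0), c(1, 1, 1))), "degenerate")
  line <- cbind(seq_len(10), seq_len(10), seq_len(10))
  expect_error(orient_frame(line), "degenerate")
})

test_that("windowed RMSF is zero for a static trajectory and exact for a known jitter", {
  pts <- axis_aligned_scaffold()
  atoms <- scaffold_atoms(nrow(pts))
  static <- trajectory_frames(rep(list(pts), 8), atoms)
  win <- windowed_rmsf(static, n_windows = 2, selection = "all")
  expect_true(all(win$rmsf < 1e-12))

  # one near-massless atom alternating +/- a along x about its mean:
  # RMSF equals a (mass ~ 0 so it cannot perturb the orientation)
  a <- 0.25
  extra_atoms <- scaffold_atoms(nrow(pts) + 1)
  extra_atoms$mass[nrow(pts) + 1] <- 1e-9
  frames <- lapply(1:2, function(f) {
    rbind(pts, c(2 + ifelse(f == 1, a, -a), 0.5, 0.5))
  })
  traj <- trajectory_frames(frames, extra_atoms)
  win2 <- windowed_rmsf(traj, n_windows = 1, selection = "all")
  expect_equal(win2$rmsf[nrow(pts) + 1], a, tolerance = 1e-6)
})

test_that("windowed RMSF refuses windows with fewer than 2 frames", {
  traj <- small_breathing_traj(n_frames = 10)
  expect_error(windowed_rmsf(traj, n_windows = 800), "insufficient frames")
})

test_that("minimal cylinder follows the stiff-face stopping rule", {
  # 30 atoms at z = 1..30, all stiff: the 10th from each side stops the face
  w <- tibble::tibble(x = 0, y = 0, z = as.numeric(1:30), rmsf = 0.01)
  mc <- minimal_cylinder(w, rmsf_threshold = 0.5, n_exclude = 10)
  expect_equal(mc$z_top, 21)
  expect_equal(mc$z_bottom, 10)
  expect_equal(mc$h, 11)

  # all floppy: faces at the extremes
  w2 <- w
  w2$rmsf <- 1.0
  mc2 <- minimal_cylinder(w2, rmsf_threshold = 0.5, n_exclude = 10)
  expect_equal(mc2$h, 29)

  # radius = largest in-plane distance among in-slab atoms
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  w3 <- tibble::tibble(x = 5 * cos(th), y = 5 * sin(th),
                       z = seq(11, 20, length.out = 12), rmsf = 1.0)
  mc3 <- minimal_cylinder(dplyr::bind_rows(w2, w3), rmsf_threshold = 0.5)
  expect_equal(mc3$r, 5)
})

test_that("minimal cylinder reports a collapse when the threshold empties it", {
  w <- tibble::tibble(x = 0, y = 0, z = rep(5, 25), rmsf = 0.01)
  expect_error(minimal_cylinder(w, rmsf_threshold = 0.5, n_exclude = 10),
               "collapsed")
})

test_that("minimal cylinder equals the slab-search oracle on random windows", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(25:100, 1)
    w <- tibble::tibble(
      x = rnorm(n, 0, 3), y = rnorm(n, 0, 3), z = rnorm(n, 0, 3),
      rmsf = runif(n, 0, 0.2)
    )
    thr <- runif(1, 0.05, 0.15)
    or <- oracle_minimal_cylinder(w, thr, 10)
    if (or$collapsed) {
      expect_error(minimal_cylinder(w, rmsf_threshold = thr, n_exclude = 10),
                   "collapsed")
    } else {
      mc <- minimal_cylinder(w, rmsf_threshold = thr, n_exclude = 10)
      expect_identical(mc$z_top, or$z_top)
      expect_identical(mc$z_bottom, or$z_bottom)
      expect_identical(mc$r, or$r)
    }
  }
})

test_that("cylinder stats are means and population SDs", {
  s <- tibble::tibble(h = c(10, 12), r = c(4, 6))
  st <- cylinder_stats(s)
  expect_equal(st$h_avg, 11)
  expect_equal(st$dh, 1)  # population SD
  expect_equal(st$r_avg, 5)
  expect_equal(st$dr, 1)
  const <- tibble::tibble(h = rep(7, 5), r = rep(3, 5))
  expect_equal(cylinder_stats(const)$dh, 0)
  expect_error(cylinder_stats(tibble::tibble(h = double(), r = double())),
               "at least 2")
})

test_that("equipartition modulus reproduces the closed form and is linear in T", {
  r_avg <- sqrt(414.1947 / (pi * 5.5))
  s <- tibble::tibble(h_avg = 5.5, dh = 0.55, r_avg = r_avg, dr = 0.1 * r_avg)
  est <- youngs_modulus(s, temperature = 300)
  expect_equal(est$V_nm3, 414.1947, tolerance = 1e-12)
  expect_equal(est$E_axial, 1.0, tolerance = 1e-12)
  expect_equal(est$E_radial, 1.0, tolerance = 1e-12)
  expect_equal(est$E, 1.0, tolerance = 1e-12)
  expect_equal(youngs_modulus(s, temperature = 600)$E, 2.0, tolerance = 1e-12)

  s0 <- tibble::tibble(h_avg = 5.5, dh = 0, r_avg = 5.5, dr = 0)
  expect_error(youngs_modulus(s0), "no observable fluctuation")
})

test_that("axial modulus falls as 1/strain^2 when height fluctuations grow", {
  r_avg <- 5.5
  scale <- c(1, 2, 4)
  E_ax <- vapply(scale, function(s) {
    st <- tibble::tibble(h_avg = 5.5, dh = 0.1 * s, r_avg = r_avg, dr = 0.1)
    youngs_modulus(st)$E_axial
  }, numeric(1))
  expect_true(all(diff(E_ax) < 0))
  expect_equal(E_ax[1] / E_ax[2], 4, tolerance = 1e-12)
  expect_equal(E_ax[1] / E_ax[3], 16, tolerance = 1e-12)
})

test_that("a static trajectory yields no observable fluctuation", {
  traj <- gen_cylinder_trajectory(E_true = Inf, jitter_sd = 0, n_frames = 40,
                                  n_surface = 30, n_face_markers = 10,
                                  n_tails = 4, seed = 2)
  expect_error(estimate_elasticity(traj, n_windows = 4, n_subsections = 2),
               "no observable fluctuation")
})

test_that("the full estimator recovers a known modulus end to end", {
  traj <- small_breathing_traj(E_true = 10, n_frames = 1200, seed = 7)
  fit <- estimate_elasticity(traj, n_windows = 120, n_subsections = 3)
  g <- glance(fit)
  expect_lt(abs(g$E / 10 - 1), 0.15)
  expect_gt(g$sd, 0)
  expect_equal(g$E, mean(c(g$E_axial, g$E_radial)))
  expect_equal(nrow(fit$series), 120)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "combined"], g$E)
})
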