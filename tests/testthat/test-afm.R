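test_that("a single Gaussian bump is detected with its ground-truth height", {
  # bump centred exactly on a pixel centre so the peak is sampled
  img <- gen_afm_image(
    tibble::tibble(x_nm = 101, y_nm = 101, height_nm = 3.7, sigma_nm = 8),
    extent_nm = c(200, 200), pixel_size = 2, noise_sd = 0, seed = 1
  )
  parts <- detect_particles(img, height_threshold = 1)
  expect_equal(nrow(parts), 1L)
  expect_equal(parts$height_nm, 3.7, tolerance = 0.02)
  expect_equal(parts$centroid_x_nm, 101, tolerance = 1)
  expect_equal(parts$centroid_y_nm, 101, tolerance = 1)
  # Gaussian bump volume above the cut h0*exp(-r^2/2s^2) > t:
  # integral = 2 pi s^2 (h0 - t) for the part above threshold... compare
  # against a direct numeric sum as ground truth
  expect_equal(parts$volume_nm3,
               sum(pmax(img$grid - img$background, 0) *
                     (img$grid > img$background + 1)) * 4,
               tolerance = 1e-9)

  with_noise <- gen_afm_image(
    tibble::tibble(x_nm = 101, y_nm = 101, height_nm = 3.7, sigma_nm = 8),
    extent_nm = c(200, 200), pixel_size = 2, noise_sd = 0.1, seed = 2
  )
  pn <- detect_particles(with_noise, height_threshold = 1)
  expect_equal(pn$height_nm[which.max(pn$n_pixels)], 3.7, tolerance = 0.3)
})

test_that("well-separated bumps are distinct particles; a blank image has none", {
  img <- gen_afm_image(
    tibble::tibble(x_nm = c(61, 151), y_nm = c(61, 151),
                   height_nm = c(3, 4), sigma_nm = c(6, 6)),
    extent_nm = c(220, 220), pixel_size = 2, noise_sd = 0, seed = 1
  )
  parts <- detect_particles(img, height_threshold = 1)
  expect_equal(nrow(parts), 2L)
  expect_false(any(attr(img, "ground_truth")$overlaps))

  blank <- gen_afm_image(extent_nm = c(100, 100), pixel_size = 2, seed = 1)
  expect_equal(nrow(detect_particles(blank, height_threshold = 1)), 0L)
})

test_that("a threshold below the noise floor warns but proceeds", {
  noisy <- gen_afm_image(extent_nm = c(100, 100), pixel_size = 2,
                         noise_sd = 3, seed = 6)
  expect_warning(detect_particles(noisy, height_threshold = 0.5),
                 "noise floor")
})

test_that("roundness anchors: disc 1.0, 2:1 ellipse 0.5, 4:1 ellipse 0.25", {
  disc <- detect_particles(gen_ellipse_image(20, axis_ratio = 1),
                           height_threshold = 1)
  expect_equal(disc$roundness, 1.00, tolerance = 0.02)

  oval <- detect_particles(gen_ellipse_image(40, axis_ratio = 2, angle_deg = 25),
                           height_threshold = 1)
  expect_equal(oval$roundness, 0.50, tolerance = 0.04)  # +/- 0.02 absolute

  thin <- detect_particles(gen_ellipse_image(40, axis_ratio = 4, angle_deg = 70),
                           height_threshold = 1)
  expect_equal(thin$roundness, 0.25, tolerance = 0.08)  # +/- 0.02 absolute
})

test_that("roundness never exceeds 1 and rejects degenerate footprints", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    rows <- cumsum(sample(c(0L, 1L), n, replace = TRUE)) + 1L
    cols <- cumsum(sample(c(0L, 1L), n, replace = TRUE)) + 1L
    expect_lte(particle_roundness(rows, cols), 1)
  }
  expect_error(particle_roundness(1:3, 1:3), "degenerate")
})

test_that("volume is additive across image tiles", {
  img <- gen_afm_image(
    tibble::tibble(x_nm = c(51, 151), y_nm = c(51, 151),
                   height_nm = c(3, 4), sigma_nm = c(5, 5)),
    extent_nm = c(200, 200), pixel_size = 2, noise_sd = 0, seed = 1
  )
  whole <- detect_particles(img, height_threshold = 1)
  top <- height_image(img$grid[1:50, ], img$pixel_size, background = img$background)
  bottom <- height_image(img$grid[51:100, ], img$pixel_size, background = img$background)
  tiles <- dplyr::bind_rows(
    detect_particles(top, height_threshold = 1),
    detect_particles(bottom, height_threshold = 1)
  )
  expect_equal(sum(tiles$volume_nm3), sum(whole$volume_nm3),
               tolerance = 1e-9 * sum(whole$volume_nm3))
})

test_that("single-linkage grouping matches the stated cluster geometry", {
  # 3 centroids mutually within 0.25 um -> one cluster of 3
  p3 <- tibble::tibble(centroid_x_nm = c(0, 100, 200), centroid_y_nm = 0)
  r3 <- count_clusters(p3, radius_um = 0.25)
  expect_equal(r3$size, 3L)

  # two triplets 2 um apart -> two clusters of 3
  p6 <- tibble::tibble(
    centroid_x_nm = c(0, 100, 200, 2000, 2100, 2200),
    centroid_y_nm = 0
  )
  r6 <- count_clusters(p6, radius_um = 0.25)
  expect_equal(sort(r6$size), c(3L, 3L))
  expect_equal(fraction_clustered(r6), 1)

  single <- count_clusters(p3[1, ], radius_um = 0.25)
  expect_equal(single$size, 1L)
  expect_equal(fraction_clustered(single), 0)

  empty <- count_clusters(p3[0, ], radius_um = 0.25)
  expect_equal(nrow(empty), 0L)
})

test_that("cluster grouping equals brute-force distance-graph components", {
  set.seed(41)
  for (i in 1:5) {
    n <- sample(20:120, 1)
    xy <- cbind(runif(n, 0, 3000), runif(n, 0, 3000))
    parts <- tibble::tibble(centroid_x_nm = xy[, 1], centroid_y_nm = xy[, 2])
    rep_ <- count_clusters(parts, radius_um = 0.25)
    ours <- attr(rep_, "particles")$cluster
    oracle <- oracle_distance_components(xy, 250)
    # same partition up to label permutation
    expect_equal(length(unique(ours)), length(unique(oracle)))
    expect_true(all(tapply(oracle, ours, function(v) length(unique(v))) == 1))
  }
})

test_that("an end-to-end image with a triplet and a loner reports sizes 3 and 1", {
  img <- gen_afm_image(
    tibble::tibble(
      x_nm = c(300, 400, 500, 1800), y_nm = c(300, 380, 300, 1800),
      height_nm = 3.5, sigma_nm = 10
    ),
    extent_nm = c(2000, 2000), pixel_size = 8, noise_sd = 0, seed = 1
  )
  parts <- detect_particles(img, height_threshold = 1)
  expect_equal(nrow(parts), 4L)
  rep_ <- count_clusters(parts, radius_um = 0.25)
  expect_equal(sort(rep_$size), c(1L, 3L))
  g <- glance(rep_)
  expect_equal(g$n_particles, 4L)
  expect_equal(g$fraction_clustered, 0.75)
})
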