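test_that("multi-model PDB parsing gives frames, labels and nm units", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1      10.000  20.000  30.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2      11.000  21.000  31.000  1.00  0.00           C",
    "ATOM      3  P    DA B   1      12.000  22.000  32.000  1.00  0.00           P",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1      10.500  20.500  30.500  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2      11.500  21.500  31.500  1.00  0.00           C",
    "ATOM      3  P    DA B   1      12.500  22.500  32.500  1.00  0.00           P",
    "ENDMDL",
    "END"
  ), f)
  traj <- read_trajectory(f)
  expect_equal(n_frames(traj), 2L)
  expect_equal(n_atoms(traj), 3L)
  # 10 angstrom -> 1 nm
  expect_equal(traj$coords[[1]][1, 1], 1.0)
  expect_true(all(traj$atoms$representative))
  expect_equal(traj$atoms$mass[3], 30.974)
})

test_that("PDB models with differing atom counts are rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1      10.000  20.000  30.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2      11.000  21.000  31.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1      10.500  20.500  30.500  1.00  0.00           C",
    "ENDMDL",
    "END"
  ), f)
  expect_error(read_trajectory(f), "inconsistent topology")
})

test_that("plain trajectory format round-trips to 1e-6 relative", {
  traj <- gen_cylinder_trajectory(E_true = 20, n_surface = 10, n_face_markers = 4,
                                  n_tails = 2, n_frames = 5, seed = 3)
  f <- withr::local_tempfile(fileext = ".txt")
  write_trajectory(traj, f)
  back <- read_trajectory(f)
  expect_equal(n_frames(back), n_frames(traj))
  expect_equal(back$atoms$chain, traj$atoms$chain)
  for (k in seq_len(n_frames(traj))) {
    expect_equal(back$coords[[k]], traj$coords[[k]], tolerance = 1e-6)
  }
})

test_that("PDB writer round-trips coordinates", {
  traj <- gen_cylinder_trajectory(E_true = 20, n_surface = 8, n_face_markers = 4,
                                  n_tails = 2, n_frames = 3, seed = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(traj, f, format = "pdb")
  back <- read_trajectory(f)
  expect_equal(n_frames(back), 3L)
  for (k in 1:3) {
    # PDB stores 3 decimals in angstrom -> 1e-4 nm quantisation
    expect_equal(back$coords[[k]], traj$coords[[k]], tolerance = 1e-3)
  }
})

test_that("trajectory constructor validates topology and masses", {
  atoms <- scaffold_atoms(2)
  expect_error(
    trajectory_frames(list(matrix(0, 2, 3), matrix(0, 3, 3)), atoms),
    "inconsistent topology"
  )
  atoms_bad <- atoms
  atoms_bad$mass <- c(12, -1)
  expect_error(
    trajectory_frames(list(matrix(0, 2, 3)), atoms_bad),
    "masses"
  )
})

test_that("force-curve reader normalises units and isolates the approach", {
  f <- withr::local_tempfile(fileext = ".csv")
  # SI units: 1e-9 m = 1 nm steps, forces in N
  d_m <- seq(0, 99) * 1e-9
  f_N <- seq(0, 99) * 1e-12
  readr::write_csv(tibble::tibble(z = d_m, f = f_N), f)
  cu <- read_force_curve(f, units = "m_N")
  expect_equal(cu$displacement_nm, seq(0, 99))
  expect_equal(cu$force_pN, seq(0, 99))

  # trailing retract: approach = longest strictly monotone prefix
  d <- c(seq(0, 30), seq(29, 10))
  fr <- seq_along(d)
  readr::write_csv(tibble::tibble(d = d, f = fr), f)
  cu2 <- read_force_curve(f)
  drops <- which(diff(d) <= 0)  # oracle: longest monotone prefix
  expect_equal(nrow(cu2), drops[1])
  expect_equal(cu2$displacement_nm, d[seq_len(drops[1])])
})

test_that("force-curve reader rejects short and non-numeric tables", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(d = 1:5, f = 1:5), f)
  expect_error(read_force_curve(f), "too few points")
  writeLines(c("d,f", "1,2", "x,3", paste(3:12, 3:12, sep = ",")), f)
  expect_error(read_force_curve(f), "non-numeric")
})

test_that("force curves round-trip through CSV", {
  cu <- gen_force_curve(E = 12, noise_sd = 1.5, seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_force_curve(cu, f)
  back <- read_force_curve(f)
  expect_equal(back$displacement_nm, cu$displacement_nm, tolerance = 1e-6)
  expect_equal(back$force_pN, cu$force_pN, tolerance = 1e-6)
})

test_that("height-image reader estimates the modal background", {
  f <- withr::local_tempfile(fileext = ".txt")
  g <- matrix(0, 10, 10)
  writeLines(c("pixel_size_nm=2", apply(g, 1, paste, collapse = " ")), f)
  img <- read_height_image(f)
  expect_equal(img$background, 0)
  expect_equal(img$pixel_size, 2)

  # flat 1.0 grid with a single 4.7-nm outlier: mode stays at 1.0
  g2 <- matrix(1.0, 10, 10)
  g2[4, 7] <- 4.7
  writeLines(c("pixel_size_nm=1.5", apply(g2, 1, paste, collapse = " ")), f)
  expect_equal(read_height_image(f)$background, 1.0)
})

test_that("height-image reader rejects bad headers and ragged grids", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 2 3", "1 2 3"), f)
  expect_error(read_height_image(f), "missing pixel size")
  writeLines(c("pixel_size_nm=1", "1 2 3", "1 2"), f)
  expect_error(read_height_image(f), "ragged")
})

test_that("height images round-trip through the ASCII format", {
  img <- gen_afm_image(
    tibble::tibble(x_nm = 50, y_nm = 60, height_nm = 3.7, sigma_nm = 8),
    extent_nm = c(120, 120), pixel_size = 2, noise_sd = 0.05, seed = 4
  )
  f <- withr::local_tempfile(fileext = ".txt")
  write_height_image(img, f)
  back <- read_height_image(f)
  expect_equal(back$pixel_size, img$pixel_size)
  expect_equal(back$grid, img$grid, tolerance = 1e-5)
})
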