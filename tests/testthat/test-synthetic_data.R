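test_that("theta = 0 with no noise leaves open identical to closed", {
  pair <- generate_clamshell(clamshell_spec(theta = 0, noise_sigma = 0))
  expect_identical(pair$open$atom[, c("x", "y", "z")],
                   pair$closed$atom[, c("x", "y", "z")])
})

test_that("lobe-1 displacement follows 2 r sin(theta/2) exactly at sigma = 0", {
  spec <- clamshell_spec(theta = 25, noise_sigma = 0)
  pair <- generate_clamshell(spec)
  closed <- pair$closed$atom[pair$closed$atom$record == "ATOM", ]
  open <- pair$open$atom[pair$open$atom$record == "ATOM", ]
  d <- unname(sqrt(rowSums((as.matrix(open[, c("x", "y", "z")]) -
                            as.matrix(closed[, c("x", "y", "z")]))^2)))
  r <- sqrt(closed$x^2 + closed$y^2)  # axis is z through the origin
  lobe1 <- closed$resno %in% 1:spec$n_lobe1
  expect_lt(max(abs(d[lobe1] - 2 * r[lobe1] * sin(25 * pi / 360))), 1e-9)
  expect_lt(max(d[!lobe1]), 1e-12)
  expect_equal(pair$truth$displacement$displacement[lobe1],
               d[lobe1], tolerance = 1e-9)
})

test_that("generation is deterministic: same spec and seed give identical files", {
  spec <- clamshell_spec(theta = 25, noise_sigma = 0.2, seed = 1)
  f1 <- file.path(tempdir(), "run1"); f2 <- file.path(tempdir(), "run2")
  cmd_simulate(spec, f1)
  cmd_simulate(spec, f2)
  for (f in c("closed.pdb", "open.pdb", "truth.json"))
    expect_identical(readLines(file.path(f1, f)),
                     readLines(file.path(f2, f)))
  # a different seed changes the coordinates
  pair_a <- generate_clamshell(spec)
  pair_b <- generate_clamshell(clamshell_spec(theta = 25, noise_sigma = 0.2,
                                              seed = 2))
  expect_false(identical(pair_a$closed$atom$x, pair_b$closed$atom$x))
})

test_that("noise magnitude scales as expected against the noise-free ideal", {
  for (sigma in c(0.2, 0.5)) {
    ideal <- generate_clamshell(clamshell_spec(noise_sigma = 0, seed = 10))
    noisy <- generate_clamshell(clamshell_spec(noise_sigma = sigma, seed = 10))
    d <- sqrt(rowSums((as.matrix(noisy$closed$atom[, c("x", "y", "z")]) -
                       as.matrix(ideal$closed$atom[, c("x", "y", "z")]))^2))
    expect_gt(mean(d), 1.3 * sigma)
    expect_lt(mean(d), 1.9 * sigma)
  }
})

test_that("interface metal rotates with lobe 1 and matches the closed form", {
  spec <- clamshell_spec(theta = 40, noise_sigma = 0, metal_offset = c(5, 1, 2))
  pair <- generate_clamshell(spec)
  zn_c <- hetero_atoms(pair$closed, "ZN"); zn_o <- hetero_atoms(pair$open, "ZN")
  d <- sqrt((zn_c$x - zn_o$x)^2 + (zn_c$y - zn_o$y)^2 + (zn_c$z - zn_o$z)^2)
  r <- sqrt(zn_c$x^2 + zn_c$y^2)
  expect_equal(d, 2 * r * sin(40 * pi / 360), tolerance = 1e-9)
  expect_equal(pair$truth$metal_displacement, d, tolerance = 1e-9)
})

test_that("an arbitrary axis placement still satisfies the analytic field", {
  spec <- clamshell_spec(theta = 15, noise_sigma = 0,
                         axis_direction = c(1, 1, 0.5),
                         axis_point = c(5, -3, 2))
  pair <- generate_clamshell(spec)
  closed <- pair$closed$atom[pair$closed$atom$record == "ATOM", ]
  open <- pair$open$atom[pair$open$atom$record == "ATOM", ]
  d <- unname(sqrt(rowSums((as.matrix(open[, c("x", "y", "z")]) -
                            as.matrix(closed[, c("x", "y", "z")]))^2)))
  expect_equal(d, pair$truth$displacement$displacement, tolerance = 1e-9)
  # hinge residues sit on the axis: zero displacement
  expect_lt(max(d[closed$resno %in% pair$truth$hinge_range]), 1e-9)
})

test_that("evaluate_recovery reports zero error for a perfect estimate", {
  pair <- generate_clamshell(clamshell_spec(theta = 25, noise_sigma = 0))
  perfect <- screw_decompose(pair$truth$transform)
  calls <- data.frame(start_resno = min(pair$truth$hinge_range),
                      end_resno = max(pair$truth$hinge_range), n = 4L,
                      mean_displacement = 0, flank_max = 5, score = 25)
  rec <- evaluate_recovery(pair$truth, perfect, calls)
  expect_lt(rec$angle_error_deg, 1e-9)
  expect_gt(rec$axis_dot, 1 - 1e-12)
  expect_identical(rec$hinge_error_residues, 0)
  # a displaced call is scored by its residue gap
  calls$start_resno <- calls$end_resno <- max(pair$truth$hinge_range) + 5L
  expect_identical(evaluate_recovery(pair$truth, perfect,
                                     calls)$hinge_error_residues, 5)
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(clamshell_spec(n_lobe1 = 5), "n_lobe1")
  expect_error(clamshell_spec(theta = 120), "theta")
  expect_error(clamshell_spec(noise_sigma = -1), "noise_sigma")
})
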