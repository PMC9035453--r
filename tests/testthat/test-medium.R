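# Scattering-phantom simulator: calibration, propagation, reciprocity.

test_that("screen-strength calibration realizes the optical depth", {
  expect_identical(calibrate_screen_strength(0, 4), 0)
  # per-screen DC attenuation multiplies: total is independent of the split
  expect_equal(calibrate_screen_strength(1, 1)^2,
               4 * calibrate_screen_strength(1, 4)^2)
  expect_error(calibrate_screen_strength(-1, 2), "depth")
  expect_error(calibrate_screen_strength(1, 0), "n_screens")
})

test_that("stack ballistic transmission matches exp(-depth) (Monte Carlo)", {
  bt <- ballistic_transmission(1, grid = grid_spec(32), n_real = 80, seed = 11)
  expect_lt(abs(bt$power - exp(-1)), 3 * bt$se)
  # splitting the same depth over more screens preserves the attenuation
  bt4 <- ballistic_transmission(1, n_screens = 4, grid = grid_spec(32),
                                n_real = 80, seed = 12)
  expect_lt(abs(bt4$power - exp(-1)), 3 * bt4$se)
})

test_that("phantom construction is deterministic and records geometry", {
  g <- grid_spec(32)
  p1 <- make_phantom(g, smfp = 52.8, depth_smfp = 14.4, seed = 5)
  p2 <- make_phantom(g, smfp = 52.8, depth_smfp = 14.4, seed = 5)
  expect_identical(p1$screens, p2$screens)
  expect_equal(p1$thickness, 760.32)           # 14.4 SMFP at 52.8 um
  expect_equal(p1$n_screens, 29L)              # two screens per SMFP
  p0 <- make_phantom(g, depth_smfp = 0, seed = 1)
  expect_true(all(p0$screens == 0))
  expect_error(make_phantom(g, smfp = -1, depth_smfp = 1, seed = 1), "smfp")
  expect_error(make_phantom(g, depth_smfp = NaN, seed = 1), "depth")
})

test_that("propagation through free space and unit-modulus screens conserves power", {
  g <- grid_spec(32)
  set.seed(3)
  u <- cmat(32, 32)
  # zero-depth phantom: exact identity
  p0 <- make_phantom(g, depth_smfp = 0, seed = 1)
  expect_identical(field_values(propagate(u, p0)), u + 0i)
  # scattering stack without absorbers: unitary to 1e-6 relative
  ph <- make_phantom(g, depth_smfp = 4.8, seed = 2, taper_px = 0)
  out <- propagate(u, ph)
  expect_lt(abs(field_power(out) - field_power(u)) / field_power(u), 1e-6)
  # absorbed power is reported when the taper is on
  ph2 <- make_phantom(g, depth_smfp = 4.8, seed = 2, taper_px = 8)
  out2 <- propagate(u, ph2)
  loss <- field_power(u) - field_power(out2)
  expect_equal(attr(out2, "absorbed"), loss, tolerance = 1e-8)
})

test_that("free-space Gaussian beam growth matches the Rayleigh-range formula", {
  g <- grid_spec(64, fov = 64, wavelength = 0.8)   # 1 um pitch
  w0 <- 8
  x <- (seq_len(64) - 32.5)
  beam <- exp(-outer(x^2, x^2, `+`) / w0^2)        # amplitude waist w0
  zr <- pi * w0^2 / g$wavelength
  ph <- make_phantom(g, smfp = zr, depth_smfp = 1, n_screens = 1, seed = 1,
                     taper_px = 0)
  ph$screens[] <- 0                                # free space over one zr
  out <- Mod(field_values(propagate(beam, ph)))^2
  # beam radius from the intensity second moment: w = 2 * sigma
  tot <- sum(out)
  mu <- sum(x * rowSums(out)) / tot
  w_meas <- 2 * sqrt(sum((x - mu)^2 * rowSums(out)) / tot)
  expect_equal(w_meas, w0 * sqrt(2), tolerance = 0.01)
})

test_that("double-pass reflection is reciprocal: monostatic pixel RM is symmetric", {
  g <- grid_spec(16, fov = 17.5)
  ph <- make_phantom(g, depth_smfp = 2.4, seed = 7, taper_px = 0)
  R <- acquire_rm(ph, input_basis = "pixel")$matrix
  expect_lt(cfrob(R - t(R)) / cfrob(R), 1e-6)
  # and with absorbing boundaries (real diagonal masks keep symmetry)
  ph2 <- make_phantom(g, depth_smfp = 2.4, seed = 7, taper_px = 3)
  R2 <- acquire_rm(ph2, input_basis = "pixel")$matrix
  expect_lt(cfrob(R2 - t(R2)) / cfrob(R2), 1e-6)
})

test_that("reflection honors the target reflectivity map", {
  g <- grid_spec(32)
  set.seed(8)
  u <- cmat(32, 32)
  dark <- make_phantom(g, depth_smfp = 1.2, seed = 3,
                       target_reflectivity = matrix(0, 32, 32))
  expect_equal(max(Mod(field_values(reflect_from_target(u, dark)))), 0)
  mirror0 <- make_phantom(g, depth_smfp = 0, seed = 3)
  expect_equal(field_values(reflect_from_target(u, mirror0)), u + 0i)
})

test_that("bead and disk-lattice targets sit on their scan points", {
  g <- grid_spec(32)
  sc <- scan_grid(17)
  probes <- rbind(c(4, 4), c(9, 9), c(14, 14))
  rho <- beads_target(g, sc, probes)
  for (i in seq_len(nrow(probes))) {
    px <- scan_to_pixel(sc, g, probes[i, ])
    expect_gt(rho[px[1], px[2]], 0)
  }
  lat <- disk_lattice_target(g, sc, period = 5, offset = 4, radius = 0.5)
  expect_true(all(rho <= lat))   # probe beads are a subset of the lattice
})
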