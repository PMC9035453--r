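# Scanning basis, RM assembly, lock-in demodulation, pitch resampling.

test_that("phase ramps address the scan grid through an ideal lens", {
  g <- grid_spec(64)
  sc <- scan_grid(31)
  ramps <- make_phase_ramps(sc, g)
  expect_equal(dim(ramps)[3], 961L)
  # centre scan point of the odd grid: flat map
  ic <- (16 - 1) * 31 + 16
  expect_equal(max(abs(ramps[, , ic])), 0)
  # Fourier-shift oracle: focal centroid lands on the scan position
  for (pt in list(c(16, 20), c(6, 26), c(26, 6))) {
    i <- (pt[1] - 1) * 31 + pt[2]
    I <- ideal_lens_focus(ramps[, , i], g)
    cx <- sum(col(I) * I)
    cy <- sum(row(I) * I)
    exp_row <- 33 + sc$positions$y[i] / g$pitch
    exp_col <- 33 + sc$positions$x[i] / g$pitch
    expect_lt(abs(cy - exp_row), 0.5)
    expect_lt(abs(cx - exp_col), 0.5)
  }
  # steering beyond the grid range is refused
  sc_wide <- scan_grid(5, fov = 300)
  expect_error(make_phase_ramps(sc_wide, g), "steerable")
})

test_that("free-space RM is near-diagonal and columns round-trip", {
  geo <- aligned_geometry()
  ph <- make_phantom(geo$grid, depth_smfp = 0, seed = 1)
  rm_ <- acquire_rm(ph, scan = geo$scan)
  M <- rm_$matrix
  expect_equal(dim(M), c(1024L, 256L))
  # each column's peak sits on its own scan pixel
  for (i in c(1, 77, 256)) {
    p <- geo$scan$positions[i, ]
    px <- scan_to_pixel(geo$scan, geo$grid, c(p$row, p$col))
    peak <- which.max(Mod(M[, i]))
    expect_equal(peak, (px[1] - 1L) * 32L + px[2])
    # reshape recovers the stored camera field exactly
    expect_identical(fill_rm_column(reshape_to_2d(M[, i])), M[, i])
  }
  # zero-reflectivity target gives an all-zero matrix
  dark <- make_phantom(geo$grid, depth_smfp = 0, seed = 1,
                       target_reflectivity = matrix(0, 32, 32))
  expect_equal(max(Mod(acquire_rm(dark, scan = geo$scan)$matrix)), 0)
  expect_error(acquire_rm(ph), "scan")
})

test_that("acquisition is linear in the input field", {
  g <- grid_spec(32)
  ph <- make_phantom(g, depth_smfp = 2.4, seed = 4)
  set.seed(9)
  u1 <- cmat(32, 32); u2 <- cmat(32, 32)
  a <- 0.3 - 1.2i; b <- -0.7 + 0.4i
  y1 <- field_values(reflect_from_target(u1, ph))
  y2 <- field_values(reflect_from_target(u2, ph))
  y12 <- field_values(reflect_from_target(a * u1 + b * u2, ph))
  expect_lt(cfrob(y12 - (a * y1 + b * y2)) / cfrob(y12), 1e-10)
})

test_that("acquisition with a fixed seed is reproducible", {
  geo <- aligned_geometry()
  ph <- make_phantom(geo$grid, depth_smfp = 2.4, seed = 21)
  r1 <- acquire_rm(ph, scan = geo$scan, noise_sd = 1e-3, noise_seed = 5)
  r2 <- acquire_rm(ph, scan = geo$scan, noise_sd = 1e-3, noise_seed = 5)
  expect_identical(r1$matrix, r2$matrix)
  r3 <- acquire_rm(ph, scan = geo$scan, noise_sd = 1e-3, noise_seed = 6)
  expect_false(identical(r1$matrix, r3$matrix))
})

test_that("lock-in demodulation inverts the synthetic beat exactly", {
  g <- grid_spec(16, fov = 16)
  set.seed(2)
  field <- matrix(complex(modulus = runif(256, 0.1, 2),
                          argument = runif(256, -pi, pi)), 16, 16)
  # 40 kHz beat from 40.00 vs 40.04 MHz modulators, 8 samples per period
  f_beat <- 4e4
  frames <- beat_frames(field, f_beat, frame_rate = 8 * f_beat,
                        n_frames = 16, reference_power = 2.5)
  rec <- lockin_demodulate(frames, f_beat, frame_rate = 8 * f_beat,
                           reference_power = 2.5)
  expect_lt(max(abs(Mod(rec) - Mod(field))), 1e-12)
  expect_lt(max(abs(Arg(rec * Conj(field)))), 1e-12)
  expect_error(lockin_demodulate(frames, f_beat, frame_rate = 3 * f_beat),
               "aliasing")
})

test_that("lock-in phase noise averages down as one over sqrt(periods)", {
  set.seed(31)
  f_beat <- 4e4; spp <- 8
  field <- matrix(1 + 0i, 4, 4)
  rms_phase <- sapply(c(4, 64), function(n_periods) {
    errs <- replicate(300, {
      frames <- beat_frames(field, f_beat, spp * f_beat, spp * n_periods)
      frames <- frames + array(rnorm(length(frames), sd = 0.3), dim(frames))
      rec <- lockin_demodulate(frames, f_beat, spp * f_beat)
      Arg(rec[1, 1])
    })
    sqrt(mean(errs^2))
  })
  # 16x the periods -> 4x lower phase error
  expect_equal(rms_phase[1] / rms_phase[2], 4, tolerance = 0.35)
})

test_that("camera-to-SLM resampling is phasor-based and wrap-safe", {
  const <- matrix(1.3, 31, 31)
  up <- resample_camera_to_slm(const, 5L)
  expect_equal(dim(up), c(155L, 155L))
  expect_equal(max(abs(up - 1.3)), 0, tolerance = 1e-12)
  # a wrapped linear ramp keeps its physical slope
  slope <- 2.0                       # rad per coarse pixel, wraps every ~3
  ramp <- matrix(rep(slope * (1:31), each = 31), 31, 31)
  ramp <- Arg(exp(1i * ramp))
  up <- resample_camera_to_slm(ramp, 5L)
  # phase at sample-aligned fine pixels is preserved exactly (wrap-safe)
  expect_equal(Arg(exp(1i * (up[78, 5 * (5:25) - 2] - ramp[16, 5:25]))),
               rep(0, 21), tolerance = 1e-9)
  # unwrapped mean slope over whole coarse periods equals slope / factor
  d <- Arg(exp(1i * diff(up[78, 33:123])))
  expect_equal(mean(d), slope / 5, tolerance = 1e-9)
  expect_error(resample_camera_to_slm(ramp, 2.5), "integer")
})
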