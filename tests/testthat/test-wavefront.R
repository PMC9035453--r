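# Matched wavefronts, reshaping, phase-only modulation.

test_that("reshaping is the exact inverse of the column fill", {
  for (m in c(3, 16, 31)) {
    k <- cmat(m^2, 1, seed = m)[, 1]
    expect_identical(fill_rm_column(reshape_to_2d(k)), k)
  }
  # convention anchor: first vector element lands at (1, 1)
  k <- complex(real = c(1, rep(0, 8)))
  expect_equal(reshape_to_2d(k)[1, 1], 1 + 0i)
  expect_equal(dim(reshape_to_2d(complex(length.out = 961))), c(31L, 31L))
  expect_error(reshape_to_2d(complex(length.out = 10)), "square")
})

test_that("phase-only projection keeps the argument and is idempotent", {
  w <- matrix(2 * exp(1i * pi / 4), 5, 5)
  p <- phase_only_project(w)
  expect_equal(max(abs(p - pi / 4)), 0, tolerance = 1e-12)
  w2 <- cmat(6, 6, seed = 1)
  w2[2, 3] <- 0
  p2 <- phase_only_project(w2)
  expect_equal(p2[2, 3], 0)
  expect_equal(phase_only_project(exp(1i * p2)), p2, tolerance = 1e-12)
  expect_error(phase_only_project(matrix(0i, 3, 3)), "degenerate")
})

test_that("inverting a unitary map is digital phase conjugation", {
  U <- runitary(24, seed = 3)
  trd <- tr_decompose(U)
  for (i in c(1, 13)) {
    e <- rep(0i, 24); e[i] <- 1
    k <- regularized_invert(trd, 0, e)
    expect_lt(max(Mod(k - Conj(U[i, ]))), 1e-10)
  }
})

test_that("matched wavefronts concentrate the forward output on the target", {
  # well-conditioned random map: R k places >= 99% of the output energy
  # on the target's camera pixel
  R <- runitary(16, seed = 5) + 0.1 * cmat(16, 16, seed = 6)
  trd <- tr_decompose(R)
  for (i in c(2, 11)) {
    e <- rep(0i, 16); e[i] <- 1
    k <- regularized_invert(trd, 0, e)
    out <- R %*% k
    expect_gte(Mod(out[i])^2 / sum(Mod(out)^2), 0.99)
  }
})

test_that("phase-only modulation retains about pi/4 of the focal intensity", {
  set.seed(17)
  n <- 256
  ratios <- replicate(40, {
    U <- runitary(n)
    row <- U[sample(n, 1), ]
    full <- Conj(row) / sqrt(sum(Mod(row)^2))
    po <- exp(-1i * Arg(row)) / sqrt(n)
    Mod(sum(row * po))^2 / Mod(sum(row * full))^2
  })
  expect_equal(mean(ratios), pi / 4, tolerance = 0.1 * pi / 4)
  # the phase-only focus never beats full conjugation
  expect_true(all(ratios <= 1))
})

test_that("free-space shaping reproduces the scanning inputs", {
  geo <- aligned_geometry()
  ph <- make_phantom(geo$grid, depth_smfp = 0, seed = 9)
  ramps <- make_phase_ramps(geo$scan, geo$grid)
  rm_ <- acquire_rm(ph, scan = geo$scan, ramps = ramps)
  fit <- tr_fit(rm_, lambda = 0)
  targets <- rbind(c(4, 4), c(8, 8))
  wf <- wavefront_set(fit, ph, targets, ramps = ramps, scan = geo$scan,
                      modulation = "complex")
  for (t in 1:2) {
    iu <- (targets[t, 1] - 1) * 16 + targets[t, 2]
    u_ref <- lens_input_fields(ramps[, , iu], ph)[, , 1]
    ov <- Mod(sum(wf$fields[, , t] * Conj(u_ref)))^2 /
      (sum(Mod(wf$fields[, , t])^2) * sum(Mod(u_ref)^2))
    expect_gt(ov, 1 - 1e-8)    # same mode up to a global phase
  }
})

test_that("the staleness guard refuses mismatched phantom realizations", {
  geo <- aligned_geometry()
  ph <- make_phantom(geo$grid, depth_smfp = 1.2, seed = 9)
  rm_ <- acquire_rm(ph, scan = geo$scan)
  fit <- tr_fit(rm_)
  wf <- wavefront_set(fit, ph, rbind(c(8, 8)), scan = geo$scan)
  other <- make_phantom(geo$grid, depth_smfp = 1.2, seed = 10)
  expect_error(shaped_reacquire(other, wf), "stale")
  expect_error(wavefront_set(fit, other, rbind(c(8, 8)), scan = geo$scan),
               "stale")
})

test_that("phase-only delivery never beats full complex modulation", {
  geo <- aligned_geometry()
  ph <- make_phantom(geo$grid, depth_smfp = 4.8, seed = 12)
  ramps <- make_phase_ramps(geo$scan, geo$grid)
  rm_ <- acquire_rm(ph, scan = geo$scan, ramps = ramps)
  fit0 <- tr_fit(rm_)
  fit <- tr_fit(rm_, lambda = max(coef(fit0)) / 2)
  tg <- rbind(c(8, 8), c(4, 12))
  wf_po <- wavefront_set(fit, ph, tg, ramps = ramps, scan = geo$scan)
  wf_cx <- wavefront_set(fit, ph, tg, ramps = ramps, scan = geo$scan,
                         modulation = "complex")
  for (t in 1:2) {
    px <- scan_to_pixel(geo$scan, geo$grid, tg[t, ])
    rpx <- 1.5 * geo$scan$pitch / geo$grid$pitch
    m_po <- internal_intensity(ph, wf_po$fields[, , t])
    m_cx <- internal_intensity(ph, wf_cx$fields[, , t])
    e_po <- enhancement(m_po, m_cx, px, rpx)
    expect_lte(e_po, 1 + 1e-6)
  }
})
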