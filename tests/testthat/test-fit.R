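# Time-reversal decomposition, Tikhonov filtering, lambda selection,
# photon classification.

test_that("decomposition reconstructs R and matches the Gram-matrix oracle", {
  R <- cmat(12, 9, seed = 1)
  trd <- tr_decompose(R)
  expect_lt(cfrob(trd$u %*% (trd$s * t(trd$v)) - R) / cfrob(R), 1e-8)
  # independent oracle: singular values from eigenvalues of R^H R
  ev <- sqrt(rev(sort(Re(eigen(Conj(t(R)) %*% R, only.values = TRUE)$values))))
  expect_lt(max(abs(trd$s - ev)), 1e-10)
  expect_true(all(diff(trd$s) <= 0))
  # orthonormality
  expect_lt(cfrob(Conj(t(trd$u)) %*% trd$u - diag(9)), 1e-10)
  expect_lt(cfrob(Conj(t(trd$v)) %*% trd$v - diag(9)), 1e-10)
  # diagonal example
  t2 <- tr_decompose(diag(c(3, 1)) + 0i)
  expect_equal(t2$s, c(3, 1))
  expect_equal(Mod(t2$v), diag(2), tolerance = 1e-12)
  expect_error(tr_decompose(matrix(c(1, NaN), 1, 2)), "finite")
})

test_that("phase convention makes the decomposition reproducible", {
  R <- cmat(10, 10, seed = 2)
  t1 <- tr_decompose(R)
  t2 <- tr_decompose(R * 1)   # fresh copy
  expect_identical(t1$v, t2$v)
  # largest entry of each V column is real positive
  for (j in 1:10) {
    k <- which.max(Mod(t1$v[, j]))
    expect_gt(Re(t1$v[k, j]), 0)
    expect_lt(abs(Im(t1$v[k, j])), 1e-12)
  }
})

test_that("Tikhonov filter factors follow s^2/(s^2+lambda^2)", {
  expect_equal(tikhonov_filter(c(2, 1), 0), c(1, 1))
  expect_equal(tikhonov_filter(3, 3), 0.5)
  expect_equal(tikhonov_filter(1, 1e8), 1e-16, tolerance = 1e-22)
  s <- sort(runif(20, 0, 5), decreasing = TRUE)
  f <- tikhonov_filter(s, 0.7)
  expect_true(all(diff(f) <= 0))      # monotone along the spectrum
  expect_true(all(f > 0 & f <= 1))
  expect_error(tikhonov_filter(1, -1), "lambda")
})

test_that("regularized inversion equals the dense ridge solve", {
  for (n in c(16, 48)) {
    R <- cmat(n, n, seed = n)
    y <- cmat(n, 1)
    lam <- 0.3
    x1 <- regularized_invert(tr_decompose(R), lam, y)
    x2 <- drop(solve(Conj(t(R)) %*% R + lam^2 * diag(n), Conj(t(R)) %*% y))
    expect_lt(cfrob(x1 - x2) / cfrob(x2), 1e-10)
  }
  # identity, lambda = 0: exact inversion
  y <- cmat(8, 1, seed = 4)
  expect_equal(regularized_invert(tr_decompose(diag(8) + 0i), 0, y), drop(y))
  # huge lambda: total suppression
  R <- cmat(12, 12, seed = 5); R <- R / cfrob(R)
  x <- regularized_invert(tr_decompose(R), 1e8, y <- cmat(12, 1))
  expect_lt(cfrob(x) / cfrob(y), 1e-14)
  expect_error(regularized_invert(tr_decompose(R), 1, cmat(5, 1)), "dimension")
})

test_that("deviation criterion picks the smallest lambda for noiseless probes", {
  R <- cmat(8, 8, seed = 6)
  X <- cmat(8, 3)
  sel <- select_lambda(tr_decompose(R), X, R %*% X)
  expect_equal(sel$lambda, 1e-8)
  expect_lt(sel$eta, 1e-8)
  # default grid spans 1e-8 .. 1e8 on a log scale
  grd <- lambda_grid_default()
  expect_equal(range(grd), c(1e-8, 1e8))
  expect_equal(sd(diff(log10(grd))), 0, tolerance = 1e-12)
  # eta is non-decreasing above the selected value in the noiseless limit
  expect_true(all(diff(sel$curve$eta[sel$curve$lambda >= sel$lambda]) >= -1e-12))
  expect_error(select_lambda(tr_decompose(R), X[, 0], R %*% X), "non-empty")
  expect_error(select_lambda(tr_decompose(R), 0 * X, R %*% X), "degenerate")
})

test_that("selected lambda grows with probe noise (median over 20 seeds)", {
  lam_med <- sapply(c(1e-4, 1e-2, 1e-1), function(sg) {
    median(sapply(1:20, function(s) {
      R <- cmat(24, 24, seed = 100 + s)
      X <- cmat(24, 4)
      Y <- R %*% X
      Y <- Y + sg * cfrob(Y) / sqrt(length(Y)) * cmat(24, 4)
      select_lambda(tr_decompose(R), X, Y)$lambda
    }))
  })
  expect_true(all(diff(lam_med) >= 0))
  expect_gt(lam_med[3], lam_med[1])
})

test_that("photon classification partitions the reflected energy", {
  expect_equal(classify_photons(c(1, 1, 1, 1), 2)$frac_above, 0)
  cls <- classify_photons(c(3, 1), 2)
  expect_equal(cls$frac_above, 90)           # 9/10 of the energy
  expect_equal(cls$frac_above + cls$frac_below, 100)
  # count mode
  expect_equal(classify_photons(c(3, 1), 2, mode = "count")$frac_above, 50)
  expect_error(classify_photons(numeric(0), 1), "empty")
  expect_error(classify_photons(c(1, 2), -1), "threshold")
})

test_that("planted spike is recovered within 1% of its energy weight", {
  set.seed(41)
  n <- 300; m <- 150
  for (w in c(0.3, 0.6)) {
    noise <- cmat(n, m)
    uu <- cmat(n, 1); uu <- uu / cfrob(uu)
    vv <- cmat(m, 1); vv <- vv / cfrob(vv)
    s_spike <- sqrt(w / (1 - w)) * cfrob(noise)   # energy ratio w : (1-w)
    M <- noise + s_spike * uu %*% t(vv)
    s <- tr_decompose(M)$s
    thr <- mp_threshold(s, n, m)
    got <- classify_photons(s, thr)$frac_above / 100
    expect_equal(got, w, tolerance = 0.015)
  }
})

test_that("squared singular values of an i.i.d. matrix follow Marchenko-Pastur", {
  ps <- sapply(1:10, function(s) {
    M <- cmat(240, 120, seed = 200 + s)       # entry variance 2
    stats::ks.test(tr_decompose(M)$s^2 / 240,
                   function(x) mp_cdf(x, 0.5, 2))$p.value
  })
  expect_gt(min(ps), 0.01)
  # the MP-edge threshold sits at the bulk edge
  M <- cmat(400, 200, seed = 7)
  thr <- mp_threshold(tr_decompose(M)$s, 400, 200)
  edge <- sqrt(400 * 2) * (1 + sqrt(0.5))
  expect_equal(thr, edge, tolerance = 0.05)
})

test_that("open-channel gain is the signed change in the strong-channel share", {
  b <- classify_photons(c(3, 1), 2)
  expect_equal(open_channel_gain(b, b), 0)
  a <- classify_photons(c(3, 2.5), 2)
  expect_gt(open_channel_gain(b, a), 0)
  # the paper-style bookkeeping: 1.14% before, 8.84% after -> 7.70 points
  before <- list(frac_above = 1.14); after <- list(frac_above = 8.84)
  expect_equal(open_channel_gain(before, after), 7.70)
  fr <- photon_fractions(b, a)
  expect_equal(fr$frac_ss + fr$frac_ms1 + fr$frac_ms2, 100, tolerance = 0.01)
})

test_that("tr_fit bundles decomposition, calibration and classification", {
  geo <- aligned_geometry()
  ph <- make_phantom(geo$grid, depth_smfp = 2.4, seed = 31)
  rm_ <- acquire_rm(ph, scan = geo$scan, noise_sd = 1e-3)
  pr <- reacquire_probes(ph, geo$scan, noise_sd = 1e-3, seed = 8)
  fit <- tr_fit(rm_, probes = pr)
  expect_s3_class(fit, "tr_fit")
  expect_true(fit$lambda %in% lambda_grid_default())
  expect_gt(fit$lambda, 1e-8)         # noise pushes lambda up
  expect_equal(coef(fit), fit$trd$s)
  expect_equal(fit$classification$frac_above + fit$classification$frac_below, 100)
  # predict = regularized inversion at the fitted lambda
  y <- rm_$matrix[, 3]
  expect_equal(predict(fit, y), regularized_invert(fit$trd, fit$lambda, y))
  # residuals hold the filtered-away part: full matrix = kept + residual
  kept <- fit$trd$u %*% ((fit$filter * fit$trd$s) * t(fit$trd$v))
  expect_lt(cfrob(kept + residuals(fit) - rm_$matrix) / cfrob(rm_$matrix), 1e-8)
  s <- summary(fit)
  expect_s3_class(s, "summary.tr_fit")
  expect_output(print(fit), "tr_fit")
})
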