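# Time-reversal decomposition of the reflection matrix with Tikhonov
# filter-factor calibration.
#
# The fitted object is the package's central model: a thin SVD
# R = U diag(s) V^T (the time-reversal decomposition; the transpose is the
# plain transpose, with the conjugation carried by U when inverting), a
# Tikhonov regularization state (lambda, filter factors, deviation-criterion
# curve) and a photon classification of the singular spectrum.

frob <- function(x) sqrt(sum(Mod(x)^2))

#' Time-reversal (singular value) decomposition of a reflection matrix
#'
#' Computes the thin SVD `R = U %*% diag(s) %*% t(V)` with singular values
#' sorted in decreasing order.  Note the plain (not conjugate) transpose on
#' `V`: `V` here stores the conjugate of the right singular vectors, so the
#' reconstruction reads exactly `U S V^T` and the regularized inverse reads
#' `V F S^+ U^H`.  For reproducibility the phase of each column of `V` is
#' fixed by making its largest-magnitude entry real and positive.
#'
#' @param R A [acquire_rm()] object or a complex matrix.
#' @return A list of class `tr_decomposition` with `u`, `s`, `v` (such that
#'   `u %*% (s * t(v))` reconstructs `R`), and the originating dimensions.
#' @export
tr_decompose <- function(R) {
  M <- rm_matrix(R)
  if (any(!is.finite(Re(M)) | !is.finite(Im(M))))
    stop("reflection matrix contains non-finite entries", call. = FALSE)
  sv <- svd(M)
  # svd() returns M = u diag(d) Conj(t(v)); store V = Conj(v) so that
  # M = u diag(d) t(V)
  V <- Conj(sv$v)
  U <- sv$u
  # phase convention: largest-|.| entry of each V column real-positive
  for (j in seq_along(sv$d)) {
    k <- which.max(Mod(V[, j]))
    ph <- V[k, j] / Mod(V[k, j])
    V[, j] <- V[, j] / ph
    U[, j] <- U[, j] * ph      # keeps u_j s_j v_j^T invariant
  }
  structure(list(u = U, s = sv$d, v = V,
                 n_out = nrow(M), n_in = ncol(M)),
            class = "tr_decomposition")
}

#' Tikhonov filter factors
#'
#' The diagonal damping factors `f = s^2 / (s^2 + lambda^2)` applied to the
#' singular spectrum in the regularized pseudoinverse: factors near 1 keep a
#' channel, factors near 0 suppress it.
#'
#' @param s Non-negative singular values.
#' @param lambda Regularization parameter, `lambda >= 0`.
#' @return Numeric vector of filter factors in `(0, 1]` (1 where both `s`
#'   and `lambda` are 0 is returned as 1 for `s > 0`, 0 otherwise).
#' @examples
#' tikhonov_filter(c(2, 1), 0)    # c(1, 1)
#' tikhonov_filter(1, 1)          # 0.5
#' @export
tikhonov_filter <- function(s, lambda) {
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0)
    stop("'lambda' must be a single finite value >= 0", call. = FALSE)
  if (any(s < 0)) stop("singular values must be non-negative", call. = FALSE)
  if (lambda == 0) return(as.numeric(s > 0))
  s^2 / (s^2 + lambda^2)
}

#' Tikhonov-regularized inversion of the reflection map
#'
#' Applies the filtered pseudoinverse `V F S^+ U^H` to a measured output
#' field, estimating the incident mode coefficients.  This equals the ridge
#' closed form `solve(R^H R + lambda^2 I, R^H e_out)`.
#'
#' @param trd A [tr_decompose()] object (or a `tr_fit`).
#' @param lambda Regularization parameter (>= 0).
#' @param e_out Complex output vector (length `n_out`) or matrix with one
#'   output per column.
#' @return Complex vector/matrix of estimated input coefficients
#'   (length `n_in`).
#' @export
regularized_invert <- function(trd, lambda, e_out) {
  trd <- as_trd(trd)
  e_out <- as.matrix(e_out)
  if (nrow(e_out) != trd$n_out) stop("output dimension mismatch", call. = FALSE)
  f <- tikhonov_filter(trd$s, lambda)
  sp <- ifelse(trd$s > 0, 1 / trd$s, 0)
  coeff <- (f * sp) * (Conj(t(trd$u)) %*% e_out)
  # stored V satisfies R = U S V^T (plain transpose), so the pseudoinverse
  # direction carries the conjugate of V
  out <- Conj(trd$v) %*% coeff
  if (ncol(out) == 1L) drop(out) else out
}

as_trd <- function(x) {
  if (inherits(x, "tr_decomposition")) return(x)
  if (inherits(x, "tr_fit")) return(x$trd)
  stop("expected a tr_decomposition or tr_fit", call. = FALSE)
}

#' Default logarithmic grid of regularization parameters
#'
#' Log-spaced candidate values from `1e-8` to `1e8`.
#'
#' @param n Number of grid points.
#' @return Numeric vector of candidate `lambda` values.
#' @export
lambda_grid_default <- function(n = 33L) 10^seq(-8, 8, length.out = n)

#' Deviation-criterion selection of the regularization parameter
#'
#' For each candidate `lambda`, applies the filtered pseudoinverse to the
#' measured probe outputs and scores the normalized deviation
#' `eta(lambda) = mean ||estimate - reference|| / ||reference||` against the
#' paired probe references.  Returns the `lambda` minimizing `eta`, with the
#' whole curve retained.  In the noiseless limit the smallest grid value
#' wins; with increasing measurement noise the minimum moves to larger
#' `lambda`, trading fidelity for noise suppression.
#'
#' @param trd A [tr_decompose()] object.
#' @param probe_in Complex matrix of reference input coefficient vectors,
#'   one probe per column (`n_in x n_probe`).
#' @param probe_out Complex matrix of paired measured outputs
#'   (`n_out x n_probe`).
#' @param lambda_grid Candidate values (default [lambda_grid_default()]).
#' @return A list of class `tr_regularization`: `lambda` (selected), `eta`
#'   (minimum deviation), `curve` (data frame `lambda`, `eta`).
#' @export
select_lambda <- function(trd, probe_in, probe_out,
                          lambda_grid = lambda_grid_default()) {
  trd <- as_trd(trd)
  probe_in <- as.matrix(probe_in)
  probe_out <- as.matrix(probe_out)
  if (ncol(probe_in) == 0L || ncol(probe_out) == 0L)
    stop("probe sets must be non-empty", call. = FALSE)
  if (ncol(probe_in) != ncol(probe_out))
    stop("probe sets must be paired", call. = FALSE)
  if (length(lambda_grid) == 0L) stop("lambda grid is empty", call. = FALSE)
  ref_norm <- sqrt(colSums(Mod(probe_in)^2))
  if (any(ref_norm == 0)) stop("degenerate (all-zero) probe reference", call. = FALSE)
  uy <- Conj(t(trd$u)) %*% probe_out          # shared across lambdas
  sp <- ifelse(trd$s > 0, 1 / trd$s, 0)
  eta <- vapply(lambda_grid, function(l) {
    f <- tikhonov_filter(trd$s, l)
    est <- Conj(trd$v) %*% ((f * sp) * uy)
    mean(sqrt(colSums(Mod(est - probe_in)^2)) / ref_norm)
  }, numeric(1))
  i <- which.min(eta)
  structure(list(lambda = lambda_grid[i], eta = eta[i],
                 curve = data.frame(lambda = lambda_grid, eta = eta)),
            class = "tr_regularization")
}

#' @export
print.tr_regularization <- function(x, ...) {
  cat(sprintf("<tr_regularization> lambda = %.3g (eta = %.3g over %d grid points)\n",
              x$lambda, x$eta, nrow(x$curve)))
  invisible(x)
}

# ---- Marchenko-Pastur reference for the singular-value bulk ---------------

#' Marchenko-Pastur density, CDF and median
#'
#' Distribution of the eigenvalues of `X^H X / n_out` for an
#' `n_out x n_in` matrix with i.i.d. entries of variance `sigma2`, aspect
#' ratio `c = n_in / n_out <= 1`.  Used as the random-matrix baseline for
#' the photon-classification threshold.
#'
#' @param x Evaluation points (eigenvalue scale).
#' @param c Aspect ratio in `(0, 1]`.
#' @param sigma2 Entry variance.
#' @return `mp_density`/`mp_cdf`: numeric vector; `mp_median`: scalar.
#' @export
mp_density <- function(x, c, sigma2 = 1) {
  a <- sigma2 * (1 - sqrt(c))^2
  b <- sigma2 * (1 + sqrt(c))^2
  d <- numeric(length(x))
  ok <- x > a & x < b
  d[ok] <- sqrt((b - x[ok]) * (x[ok] - a)) / (2 * pi * c * sigma2 * x[ok])
  d
}

#' @rdname mp_density
#' @export
mp_cdf <- function(x, c, sigma2 = 1) {
  a <- sigma2 * (1 - sqrt(c))^2
  b <- sigma2 * (1 + sqrt(c))^2
  vapply(x, function(xi) {
    if (xi <= a) return(0)
    if (xi >= b) return(1)
    stats::integrate(mp_density, a, xi, c = c, sigma2 = sigma2,
                     rel.tol = 1e-9)$value
  }, numeric(1))
}

#' @rdname mp_density
#' @export
mp_median <- function(c, sigma2 = 1) {
  a <- sigma2 * (1 - sqrt(c))^2
  b <- sigma2 * (1 + sqrt(c))^2
  stats::uniroot(function(x) mp_cdf(x, c, sigma2) - 0.5, c(a + 1e-12, b - 1e-12),
                 tol = 1e-10)$root
}

#' Random-matrix threshold for the singular spectrum
#'
#' Estimates the bulk edge of the singular-value spectrum under the
#' Marchenko-Pastur null: the noise scale is fitted from the median squared
#' singular value (robust to a few strong channels), and the threshold is
#' the corresponding bulk edge `sigma * (1 + sqrt(c))` on the
#' singular-value scale.
#'
#' @param s Singular values.
#' @param n_out,n_in Matrix dimensions behind the spectrum.
#' @return Threshold on the singular-value scale.
#' @export
mp_threshold <- function(s, n_out, n_in) {
  c <- min(n_in, n_out) / max(n_in, n_out)
  med <- stats::median(s^2) / max(n_in, n_out)
  sigma2 <- med / mp_median(c)
  sqrt(max(n_in, n_out) * sigma2) * (1 + sqrt(c))
}

# ---- photon classification -------------------------------------------------

#' Partition reflected energy by a singular-value threshold
#'
#' Splits the total reflected energy `sum(s^2)` into the share carried by
#' channels with singular values above the threshold (single-scattering-like
#' photons before shaping; single-scattering plus redirected
#' multiple-scattering photons after shaping) and the remainder.
#'
#' @param trd A [tr_decompose()], `tr_fit`, or a numeric vector of singular
#'   values.
#' @param threshold Singular-value cutoff (>= 0).
#' @param mode `"energy"` (shares of `sum(s^2)`, default) or `"count"`
#'   (shares of the number of eigenstates).
#' @return A list of class `photon_classification` with `threshold`,
#'   `frac_above`, `frac_below` (percentages summing to 100) and `mode`.
#' @examples
#' classify_photons(c(3, 1), threshold = 2)$frac_above  # 90
#' @export
classify_photons <- function(trd, threshold, mode = c("energy", "count")) {
  mode <- match.arg(mode)
  s <- if (is.numeric(trd)) trd else as_trd(trd)$s
  if (length(s) == 0L) stop("empty singular spectrum", call. = FALSE)
  if (!is.finite(threshold) || threshold < 0)
    stop("'threshold' must be finite and >= 0", call. = FALSE)
  w <- if (mode == "energy") s^2 else rep(1, length(s))
  frac_above <- 100 * sum(w[s > threshold]) / sum(w)
  structure(list(threshold = threshold, frac_above = frac_above,
                 frac_below = 100 - frac_above, mode = mode),
            class = "photon_classification")
}

#' @export
print.photon_classification <- function(x, ...) {
  cat(sprintf("<photon_classification> %.2f%% above / %.2f%% below threshold %.4g (%s)\n",
              x$frac_above, x$frac_below, x$threshold, x$mode))
  invisible(x)
}

#' Open-channel gain from wavefront shaping
#'
#' Percentage points of reflected energy moved above the singular-value
#' threshold by wavefront shaping: `frac_above(after) - frac_above(before)`.
#' Under the photon taxonomy this is the share of multiply scattered photons
#' redirected into open channels; it may be negative and is reported as is.
#'
#' @param class_before,class_after [classify_photons()] results sharing the
#'   same threshold convention.
#' @return Gain in percentage points.
#' @export
open_channel_gain <- function(class_before, class_after) {
  class_after$frac_above - class_before$frac_above
}

#' Photon-class fractions before/after shaping
#'
#' Combines the classifications of the unshaped and shaped reflection
#' matrices into the three-class bookkeeping: above-threshold energy before
#' shaping is attributed to single-scattering photons, the additional
#' above-threshold energy after shaping to redirected multiple-scattering
#' photons reaching the target plane, and the rest to multiple-scattering
#' photons never reaching it.
#'
#' @param class_before,class_after [classify_photons()] results.
#' @return A list with `frac_ss`, `frac_ms1`, `frac_ms2` (percentages
#'   summing to 100; `frac_ms1` is clamped below at 0 only in the reported
#'   triple, the signed gain is available via [open_channel_gain()]).
#' @export
photon_fractions <- function(class_before, class_after) {
  frac_ss <- class_before$frac_above
  frac_ms1 <- max(0, open_channel_gain(class_before, class_after))
  list(frac_ss = frac_ss, frac_ms1 = frac_ms1,
       frac_ms2 = 100 - frac_ss - frac_ms1)
}

# ---- the fitted model ------------------------------------------------------

#' Fit the calibrated time-reversal model of a reflection matrix
#'
#' The central fitting function: decomposes the reflection matrix
#' (time-reversal SVD), selects the Tikhonov regularization parameter by the
#' deviation criterion when paired probe measurements are supplied, and
#' classifies the singular spectrum into photon classes.
#'
#' @param R A [acquire_rm()] object or complex matrix.
#' @param lambda Either `"auto"` (deviation-criterion selection from
#'   `probes`, falling back to the smallest grid value when no probes are
#'   given) or a fixed non-negative number.
#' @param probes Optional list with elements `inputs` (`n_in x k` reference
#'   coefficient matrix) and `outputs` (`n_out x k` paired measured
#'   outputs), e.g. from [reacquire_probes()].
#' @param lambda_grid Candidate grid for selection.
#' @param threshold `"mp"` (Marchenko-Pastur bulk edge, default) or a fixed
#'   non-negative cutoff for photon classification.
#' @return An object of class `tr_fit` with components `trd` (the
#'   decomposition), `lambda`, `filter` (factors at the selected `lambda`),
#'   `regularization` (the [select_lambda()] result or `NULL`), `threshold`,
#'   `classification`, and acquisition metadata carried over from `R`.
#'   Methods: [print.tr_fit()], [summary.tr_fit()], [coef.tr_fit()]
#'   (singular values), [predict.tr_fit()] (regularized inversion),
#'   [residuals.tr_fit()], [plot.tr_fit()].
#' @export
tr_fit <- function(R, lambda = "auto", probes = NULL,
                   lambda_grid = lambda_grid_default(), threshold = "mp") {
  trd <- tr_decompose(R)
  reg <- NULL
  if (identical(lambda, "auto")) {
    if (!is.null(probes)) {
      reg <- select_lambda(trd, probes$inputs, probes$outputs, lambda_grid)
      lambda <- reg$lambda
    } else lambda <- min(lambda_grid)
  }
  if (!is.numeric(lambda) || lambda < 0)
    stop("'lambda' must be \"auto\" or a non-negative number", call. = FALSE)
  if (identical(threshold, "mp"))
    threshold <- mp_threshold(trd$s, trd$n_out, trd$n_in)
  cls <- classify_photons(trd, threshold)
  meta <- if (inherits(R, "reflection_matrix"))
    R[c("depth_smfp", "phantom_seed", "scan", "grid", "noise_snr")] else NULL
  structure(list(trd = trd, lambda = lambda,
                 filter = tikhonov_filter(trd$s, lambda),
                 regularization = reg, threshold = threshold,
                 classification = cls, meta = meta),
            class = "tr_fit")
}

#' @export
print.tr_fit <- function(x, ...) {
  cat(sprintf(paste0("<tr_fit> %d x %d reflection matrix, rank %d\n",
                     "  lambda = %.4g, threshold = %.4g, ",
                     "%.2f%% energy above threshold\n"),
              x$trd$n_out, x$trd$n_in, length(x$trd$s), x$lambda,
              x$threshold, x$classification$frac_above))
  if (!is.null(x$meta))
    cat(sprintf("  acquired at depth %.3g SMFP (phantom seed %d)\n",
                x$meta$depth_smfp, x$meta$phantom_seed))
  invisible(x)
}

#' @export
#' @rdname tr_fit
#' @param object,x A `tr_fit` object.
#' @param ... Unused.
summary.tr_fit <- function(object, ...) {
  s <- object$trd$s
  out <- list(n_out = object$trd$n_out, n_in = object$trd$n_in,
              lambda = object$lambda, eta = object$regularization$eta,
              threshold = object$threshold,
              frac_above = object$classification$frac_above,
              s_head = utils::head(s, 5),
              energy_kept = 100 * sum(object$filter * s^2) / sum(s^2))
  class(out) <- "summary.tr_fit"
  out
}

#' @export
print.summary.tr_fit <- function(x, ...) {
  cat(sprintf("Calibrated time-reversal decomposition (%d x %d)\n", x$n_out, x$n_in))
  cat(sprintf("  leading singular values: %s\n",
              paste(signif(x$s_head, 4), collapse = ", ")))
  cat(sprintf("  lambda = %.4g%s\n", x$lambda,
              if (length(x$eta)) sprintf(" (deviation eta = %.3g)", x$eta) else ""))
  cat(sprintf("  filter keeps %.1f%% of reflected energy\n", x$energy_kept))
  cat(sprintf("  threshold %.4g: %.2f%% of energy above\n", x$threshold, x$frac_above))
  invisible(x)
}

#' @export
#' @rdname tr_fit
coef.tr_fit <- function(object, ...) object$trd$s

#' Predict incident fields by regularized inversion
#'
#' Applies the Tikhonov-filtered pseudoinverse of the fitted decomposition
#' to measured (or desired) output fields.
#'
#' @param object A [tr_fit()] object.
#' @param e_out Complex output vector or matrix (one output per column).
#' @param lambda Regularization parameter; defaults to the fitted value.
#' @param ... Unused.
#' @return Estimated input coefficient vector/matrix.
#' @export
predict.tr_fit <- function(object, e_out, lambda = object$lambda, ...) {
  regularized_invert(object$trd, lambda, e_out)
}

#' @export
#' @rdname tr_fit
residuals.tr_fit <- function(object, ...) {
  trd <- object$trd
  # part of R suppressed by the filter: U (1 - F) S V^T
  trd$u %*% (((1 - object$filter) * trd$s) * t(trd$v))
}

#' @export
#' @rdname tr_fit
plot.tr_fit <- function(x, ...) {
  s <- x$trd$s
  op <- graphics::par(mfrow = c(1, if (is.null(x$regularization)) 1 else 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(s), s, log = "y", type = "b", pch = 20,
                 xlab = "eigenstate index", ylab = "singular value",
                 main = "Time-reversal spectrum", ...)
  graphics::abline(h = x$threshold, lty = 2)
  if (!is.null(x$regularization)) {
    cv <- x$regularization$curve
    graphics::plot(cv$lambda, cv$eta, log = "xy", type = "b", pch = 20,
                   xlab = "lambda", ylab = "deviation eta",
                   main = "Deviation criterion")
    graphics::abline(v = x$lambda, lty = 2)
  }
  invisible(x)
}

#' Re-measure a probe subset for deviation-criterion calibration
#'
#' Re-acquires the camera outputs of a random subset of scan inputs with an
#' independent noise realization, pairing them with their unit coefficient
#' vectors.  This is the simulation counterpart of acquiring an independent
#' reference measurement for selecting the regularization parameter: the
#' probes exercise the same scattering realization but carry fresh
#' measurement noise.
#'
#' @param phantom The phantom used for the original acquisition.
#' @param scan The scan grid.
#' @param frac Fraction of scan inputs to probe (default 0.1).
#' @param ramps Optional precomputed ramps.
#' @param noise_snr,noise_sd Probe measurement noise (use the acquisition
#'   settings).
#' @param seed Seed for subset choice and probe noise (use a different seed
#'   than the acquisition noise).
#' @return A list with `inputs` (sparse unit-coefficient matrix), `outputs`
#'   (probe camera fields) and `index` (probed scan indices), suitable for
#'   the `probes` argument of [tr_fit()].
#' @export
reacquire_probes <- function(phantom, scan, frac = 0.1, ramps = NULL,
                             noise_snr = Inf, noise_sd = NULL, seed = 2L) {
  if (is.null(ramps)) ramps <- make_phase_ramps(scan, phantom$grid)
  m <- dim(ramps)[3]
  k <- max(1L, round(frac * m))
  rng <- local_rng(seed)
  idx <- sort(sample.int(m, k))
  restore_rng(rng)
  sub <- acquire_rm(phantom, scan = scan, ramps = ramps[, , idx, drop = FALSE],
                    noise_snr = noise_snr, noise_sd = noise_sd,
                    noise_seed = seed + 1L)
  inputs <- matrix(0i, m, k)
  inputs[cbind(idx, seq_len(k))] <- 1
  list(inputs = inputs, outputs = sub$matrix, index = idx)
}
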