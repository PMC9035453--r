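# Matched incident wavefronts by regularized inversion of the reflection
# matrix, and the phase-only modulation constraint of the SLM.

#' Scan position to camera pixel
#'
#' Nearest pixel `(row, col)` on the camera/field grid to a scan point.
#'
#' @param scan A [scan_grid()].
#' @param grid A [grid_spec()].
#' @param point Scan point `(row, col)`, 1-based.
#' @return Integer `(row, col)` on the pixel grid, 1-based.
#' @export
scan_to_pixel <- function(scan, grid, point) {
  i <- scan_index(scan, point)
  y <- scan$positions$y[i]
  x <- scan$positions$x[i]
  c(round(grid$n / 2 + y / grid$pitch) + 1L,
    round(grid$n / 2 + x / grid$pitch) + 1L)
}

#' Matched incident wavefront for one target point
#'
#' Derives the incident mode-coefficient vector that the regularized
#' inverse of the reflection matrix maps to a camera delta at the target
#' point: `k = V F S^+ U^H e_out` with `e_out` a unit impulse at the
#' target's camera pixel.  The result is normalized to unit coefficient
#' norm, so shaped and unshaped acquisitions inject the same power.
#'
#' @param fit A [tr_fit()] object fitted to the scanning reflection matrix.
#' @param target_point Scan point `(row, col)` to focus on.
#' @param scan,grid Scan and pixel grids (default from the fit metadata).
#' @param lambda Regularization parameter (default the fitted value).
#' @return Complex coefficient vector of length `n_in`.
#' @export
matched_wavefront <- function(fit, target_point, scan = fit$meta$scan,
                              grid = fit$meta$grid, lambda = fit$lambda) {
  K <- matched_wavefronts(fit, matrix(target_point, 1, 2), scan = scan,
                          grid = grid, lambda = lambda)
  drop(K)
}

#' Matched wavefronts for a set of target points
#'
#' Vectorized form of [matched_wavefront()]: one coefficient column per
#' target.
#'
#' @inheritParams matched_wavefront
#' @param targets Two-column matrix (or data frame) of scan points
#'   `(row, col)`.
#' @return Complex `n_in x n_targets` matrix of unit-norm coefficient
#'   vectors.
#' @export
matched_wavefronts <- function(fit, targets, scan = fit$meta$scan,
                               grid = fit$meta$grid, lambda = fit$lambda) {
  if (is.null(scan) || is.null(grid))
    stop("scan/grid metadata required (fit a scanning reflection matrix)", call. = FALSE)
  targets <- as.matrix(targets)
  n_roi <- as.integer(round(sqrt(fit$trd$n_out)))
  E <- matrix(0i, fit$trd$n_out, nrow(targets))
  for (t in seq_len(nrow(targets))) {
    px <- roi_pixel(scan, grid, n_roi, targets[t, ])
    E[(px[1] - 1L) * n_roi + px[2], t] <- 1  # row-major camera fill
  }
  K <- predict(fit, E, lambda = lambda)
  K <- as.matrix(K)
  nrm <- sqrt(colSums(Mod(K)^2))
  if (any(nrm == 0)) stop("degenerate matched wavefront (zero inverse image)", call. = FALSE)
  sweep(K, 2L, nrm, `/`)
}

#' Reshape a coefficient vector to a 2D map
#'
#' Exact inverse of the row-major column fill used when camera fields (or
#' scan-indexed vectors) are stored as reflection-matrix columns.
#'
#' @param k Vector of length `m^2`.
#' @return An `m x m` matrix with `fill_rm_column(reshape_to_2d(k))`
#'   identical to `k`.
#' @examples
#' k <- complex(real = 1:9)
#' all(fill_rm_column(reshape_to_2d(k)) == k)
#' @export
reshape_to_2d <- function(k) {
  m <- sqrt(length(k))
  if (m != round(m)) stop("length is not a perfect square", call. = FALSE)
  matrix(k, m, m, byrow = TRUE)
}

#' @rdname reshape_to_2d
#' @param map A square matrix.
#' @export
fill_rm_column <- function(map) as.vector(t(map))

#' Phase-only projection of a complex wavefront
#'
#' Discards the amplitude of a complex field, keeping only its argument:
#' the constraint imposed by a phase-only spatial light modulator.
#' Zero-amplitude pixels are assigned phase 0.  The projection is
#' idempotent.
#'
#' @param wavefront Complex matrix (or vector).
#' @return Phase map in `(-pi, pi]` with the same shape.
#' @export
phase_only_project <- function(wavefront) {
  v <- if (inherits(wavefront, "complex_field")) wavefront$values else wavefront
  if (all(Mod(v) == 0)) stop("degenerate (all-zero) field", call. = FALSE)
  ph <- Arg(v)
  ph[Mod(v) == 0] <- 0
  ph
}

#' Physical incident fields of a set of matched wavefronts
#'
#' Superposes the scanning input basis with the matched coefficient
#' vectors, giving the complex field to load (after phase projection) on
#' the SLM conjugate plane.  Each output field is normalized to unit total
#' power.
#'
#' @param K Coefficient matrix (`n_in x n_targets`), e.g. from
#'   [matched_wavefronts()].
#' @param ramps Ramp array of the scanning basis ([make_phase_ramps()]).
#' @param phantom The phantom the basis was built for (sets the lens
#'   conjugation distance).
#' @return An `n x n x n_targets` array of complex surface fields.
#' @export
wavefront_fields <- function(K, ramps, phantom) {
  K <- as.matrix(K)
  n <- phantom$grid$n
  m <- dim(ramps)[3]
  if (nrow(K) != m) stop("coefficient/basis dimension mismatch", call. = FALSE)
  Hc <- Conj(angular_spectrum_transfer(phantom$grid, phantom$thickness))
  cb <- checkerboard(n)
  Pk <- exp(1i * ramps)
  dim(Pk) <- c(n^2, m)
  A <- Pk %*% K                               # k-space superposition
  dim(A) <- c(n, n, ncol(K))
  A <- A * as.vector(cb * Hc)
  u <- fft2_batch(A, inverse = TRUE)
  pw <- sqrt(apply(Mod(u)^2, 3, sum))
  u / rep(pw, each = n^2)
}

#' Matched-wavefront set for the three-step shaping protocol
#'
#' Bundles, for a set of target points: the coefficient vectors, the
#' physical incident fields, and their phase-only SLM maps, together with
#' the provenance needed by the staleness guard of [shaped_reacquire()].
#'
#' @inheritParams matched_wavefronts
#' @param phantom The phantom the reflection matrix was measured on.
#' @param ramps Optional precomputed ramps of the scanning basis.
#' @param modulation `"phase_only"` (default) or `"complex"` (retain
#'   amplitude).
#' @return An object of class `wavefront_set`: `k` (coefficients),
#'   `fields` (incident fields after the modulation constraint, unit
#'   power), `phase_maps`, `targets`, `modulation`, `lambda`,
#'   `depth_smfp`, `phantom_seed`.
#' @export
wavefront_set <- function(fit, phantom, targets, ramps = NULL,
                          scan = fit$meta$scan, lambda = fit$lambda,
                          modulation = c("phase_only", "complex")) {
  modulation <- match.arg(modulation)
  if (!is.null(fit$meta$phantom_seed) && fit$meta$phantom_seed != phantom$seed)
    stop("stale wavefronts: fit and phantom come from different scattering realizations",
         call. = FALSE)
  targets <- as.matrix(targets)
  if (is.null(ramps)) ramps <- make_phase_ramps(scan, phantom$grid)
  K <- matched_wavefronts(fit, targets, scan = scan, grid = phantom$grid,
                          lambda = lambda)
  u <- wavefront_fields(K, ramps, phantom)
  n <- phantom$grid$n
  phase_maps <- array(0, dim = dim(u))
  for (t in seq_len(dim(u)[3])) phase_maps[, , t] <- phase_only_project(u[, , t])
  if (modulation == "phase_only") {
    u <- exp(1i * phase_maps) / n            # unit-modulus, unit total power
  }
  structure(list(k = K, fields = u, phase_maps = phase_maps,
                 targets = targets, modulation = modulation, lambda = lambda,
                 n_roi = as.integer(round(sqrt(fit$trd$n_out))),
                 depth_smfp = phantom$depth_smfp, phantom_seed = phantom$seed),
            class = "wavefront_set")
}

#' @export
print.wavefront_set <- function(x, ...) {
  cat(sprintf("<wavefront_set> %d matched wavefronts (%s), depth %.3g SMFP, lambda %.4g\n",
              ncol(x$k), x$modulation, x$depth_smfp, x$lambda))
  invisible(x)
}

#' Re-acquire the reflection matrix with shaped inputs
#'
#' Step three of the shaping protocol: repeats the acquisition against the
#' same frozen phantom realization with the matched (shaped) wavefronts in
#' place of the original ramps.  A staleness guard refuses to mix
#' wavefronts with a different scattering realization than they were
#' optimized for.
#'
#' @param phantom The phantom (same seed as used for the optimization).
#' @param wf A [wavefront_set()].
#' @param noise_snr,noise_sd,noise_seed Detection noise settings as in
#'   [acquire_rm()].
#' @return A `reflection_matrix` whose columns are the camera fields of the
#'   shaped inputs (column order = target order).
#' @export
shaped_reacquire <- function(phantom, wf, noise_snr = Inf, noise_sd = NULL,
                             noise_seed = 1L) {
  if (wf$phantom_seed != phantom$seed || wf$depth_smfp != phantom$depth_smfp)
    stop("stale wavefronts: phantom realization differs from the one optimized for",
         call. = FALSE)
  M <- acquire_columns(phantom, wf$fields, camera = "target",
                       n_roi = wf$n_roi)
  M <- add_detection_noise(M, noise_snr, noise_sd, noise_seed)
  structure(list(matrix = M, grid = phantom$grid, scan = NULL,
                 n_roi = wf$n_roi,
                 depth_smfp = phantom$depth_smfp, phantom_seed = phantom$seed,
                 input_basis = "shaped", camera = "target",
                 noise_snr = noise_snr, noise_sd = noise_sd),
            class = "reflection_matrix")
}

#' Ground-truth internal intensity at the target plane
#'
#' Propagates an incident surface field to the target plane of the phantom
#' and returns the intensity map: the simulation counterpart of a camera
#' embedded inside the sample, used to score actual energy delivery.
#'
#' @param phantom A [make_phantom()] object.
#' @param field Incident surface field (matrix or [complex_field()]).
#' @return An `n x n` non-negative intensity matrix on the pixel grid.
#' @export
internal_intensity <- function(phantom, field) {
  v <- field_values(field)
  a <- propagate_stack(v, phantom, direction = 1L)
  Mod(a[, , 1L])^2
}
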