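# Synthetic layered scattering phantoms.
#
# The medium is modelled as n_screens thin random phase screens with
# Gaussian statistics and Gaussian autocorrelation, separated by free-space
# gaps, spanning a physical thickness depth_smfp * smfp.  For a Gaussian
# random phase of pointwise standard deviation sigma the ensemble-mean
# (ballistic) amplitude transmission of one screen is exp(-sigma^2/2), so
# the stack's ballistic power transmission is exp(-sum(sigma_j^2)); the
# calibration below makes that equal exp(-depth_smfp), realizing the
# scattering-mean-free-path semantics of the optical depth.

#' Per-screen phase standard deviation for a given optical depth
#'
#' Chooses the standard deviation (radians) of each Gaussian random phase
#' screen so that the ballistic (unscattered) power transmission of the
#' whole stack of `n_screens` screens equals `exp(-depth_smfp)`.
#'
#' @param depth_smfp Optical depth in scattering mean free paths
#'   (dimensionless, >= 0).
#' @param n_screens Number of phase screens (>= 1).
#' @return Phase standard deviation per screen, radians.
#' @examples
#' calibrate_screen_strength(9.6, 20)
#' @export
calibrate_screen_strength <- function(depth_smfp, n_screens) {
  if (!is.finite(depth_smfp) || depth_smfp < 0)
    stop("'depth_smfp' must be finite and >= 0", call. = FALSE)
  n_screens <- as.integer(n_screens)
  if (n_screens < 1L) stop("'n_screens' must be >= 1", call. = FALSE)
  sqrt(depth_smfp / n_screens)
}

# One Gaussian-correlated random phase screen with pointwise sd sigma and
# autocorrelation length corr_px pixels, drawn from the current RNG stream.
gaussian_phase_screen <- function(n, sigma, corr_px) {
  if (sigma == 0) return(matrix(0, n, n))
  g <- matrix(stats::rnorm(n * n), n, n)
  f <- c(0:(n / 2 - 1), -(n / 2):-1) / n        # cycles per pixel
  k2 <- outer(f^2, f^2, `+`) * (2 * pi)^2
  K <- exp(-k2 * corr_px^2 / 4)                  # Gaussian spectral filter
  K <- K * sigma / sqrt(sum(K^2) / n^2)          # exact pointwise variance
  phi <- Re(ifft2(fft2(g) * K))
  phi
}

#' Build a synthetic layered scattering phantom
#'
#' Generates `n_screens` frozen Gaussian random phase screens whose combined
#' ballistic attenuation realizes the requested optical depth (see
#' [calibrate_screen_strength()]), together with the target reflectivity
#' map at the back plane.  The construction is deterministic for a fixed
#' `seed`.
#'
#' @param grid A [grid_spec()].
#' @param smfp Scattering mean free path in micrometres (sets the physical
#'   thickness `depth_smfp * smfp`).
#' @param depth_smfp Optical depth of the target plane, in SMFP units
#'   (e.g. 2.4, 4.8, 7.2, 9.6, 14.4).
#' @param n_screens Number of phase screens; default two per SMFP of depth
#'   (`ceiling(2 * depth_smfp)`, at least 1).
#' @param target_reflectivity Real matrix in `[0, 1]` on the grid giving the
#'   field reflectivity of the target plane; default a uniform mirror.
#'   See [disk_lattice_target()] for a structured pattern.
#' @param seed Integer seed for the screen realization.
#' @param corr_px Autocorrelation length of each screen, in pixels.
#' @param taper_px Width of the cosine absorbing boundary frame, pixels
#'   (0 disables it).
#' @return An object of class `scattering_phantom`.
#' @examples
#' ph <- make_phantom(grid_spec(32), smfp = 52.8, depth_smfp = 2.4, seed = 1)
#' ph$thickness  # physical thickness in um
#' @export
make_phantom <- function(grid, smfp = 52.8, depth_smfp = 0,
                         n_screens = NULL, target_reflectivity = NULL,
                         seed = 1L, corr_px = 4, taper_px = 8L) {
  if (!inherits(grid, "grid_spec")) stop("'grid' must be a grid_spec", call. = FALSE)
  if (!is.finite(smfp) || smfp <= 0) stop("'smfp' must be positive", call. = FALSE)
  if (!is.finite(depth_smfp) || depth_smfp < 0)
    stop("'depth_smfp' must be finite and >= 0", call. = FALSE)
  if (is.null(n_screens)) n_screens <- max(1L, ceiling(2 * depth_smfp))
  n_screens <- as.integer(n_screens)
  if (n_screens < 1L) stop("'n_screens' must be >= 1", call. = FALSE)
  if (is.null(target_reflectivity)) target_reflectivity <- matrix(1, grid$n, grid$n)
  target_reflectivity <- as.matrix(target_reflectivity)
  if (!all(dim(target_reflectivity) == grid$n))
    stop("target reflectivity map does not match grid", call. = FALSE)
  if (any(!is.finite(target_reflectivity)) ||
      any(target_reflectivity < 0) || any(target_reflectivity > 1))
    stop("target reflectivity must lie in [0, 1]", call. = FALSE)

  sigma <- calibrate_screen_strength(depth_smfp, n_screens)
  screens <- array(0, dim = c(grid$n, grid$n, n_screens))
  rng <- local_rng(seed)
  for (j in seq_len(n_screens))
    screens[, , j] <- gaussian_phase_screen(grid$n, sigma, corr_px)
  restore_rng(rng)

  structure(list(grid = grid, smfp = smfp, depth_smfp = depth_smfp,
                 thickness = depth_smfp * smfp, n_screens = n_screens,
                 screens = screens,
                 screen_sigma = rep(sigma, n_screens), corr_px = corr_px,
                 taper_px = as.integer(taper_px),
                 target_reflectivity = target_reflectivity, seed = as.integer(seed)),
            class = "scattering_phantom")
}

#' @export
print.scattering_phantom <- function(x, ...) {
  cat(sprintf(paste0("<scattering_phantom> depth %.3g SMFP (%.4g um), ",
                     "%d screens (sigma %.3g rad), grid %d px, seed %d\n"),
              x$depth_smfp, x$thickness, x$n_screens, x$screen_sigma[1],
              x$grid$n, x$seed))
  invisible(x)
}

# Seed handling: run a block under a private RNG state without disturbing
# the caller's stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Reflective disk-lattice target pattern
#'
#' A repeating pattern of reflective disks at the target plane, centred on
#' scan-grid positions `(row, col)` with both indices congruent to `offset`
#' modulo `period`.  This emulates a phantom target carrying repeating
#' circular features aligned with the probe points of the scan.
#'
#' @param grid A [grid_spec()].
#' @param scan A [scan_grid()] giving the scan-point layout.
#' @param period Lattice period in scan points.
#' @param offset Scan index (1-based) of the first disk row/column.
#' @param radius Disk radius in scan-point units.
#' @return Reflectivity matrix on the pixel grid with 1 inside the disks,
#'   0 elsewhere.
#' @export
disk_lattice_target <- function(grid, scan, period = 10L, offset = 6L,
                                radius = 2) {
  centres_idx <- seq(offset, scan$n_side, by = period)
  if (length(centres_idx) == 0L) stop("no disk centres inside scan grid", call. = FALSE)
  coord <- function(i) (i - (scan$n_side + 1) / 2) * scan$pitch
  cx <- coord(centres_idx)
  # pixel coordinates follow the FFT convention: 1-based index n/2 + 1 is
  # the optical axis (where a flat ramp focuses)
  px <- (seq_len(grid$n) - (grid$n / 2 + 1)) * grid$pitch
  rho <- matrix(0, grid$n, grid$n)
  r_um <- radius * scan$pitch
  for (yc in cx) for (xc in cx) {
    d2 <- outer((px - yc)^2, (px - xc)^2, `+`)
    rho[d2 <= r_um^2] <- 1
  }
  rho
}

#' Discrete bead reflectors at chosen scan points
#'
#' A target plane carrying small circular reflectors ("beads") centred on
#' the given scan points, emulating discrete scatterers examined at known
#' probe positions.
#'
#' @param grid A [grid_spec()].
#' @param scan A [scan_grid()].
#' @param points Two-column matrix of scan points `(row, col)`.
#' @param radius Bead radius in scan-point units.
#' @return Reflectivity matrix on the pixel grid (1 on the beads, 0
#'   elsewhere).
#' @export
beads_target <- function(grid, scan, points, radius = 0.5) {
  points <- as.matrix(points)
  coord <- function(i) (i - (scan$n_side + 1) / 2) * scan$pitch
  px <- (seq_len(grid$n) - (grid$n / 2 + 1)) * grid$pitch
  rho <- matrix(0, grid$n, grid$n)
  r_um <- radius * scan$pitch
  for (i in seq_len(nrow(points))) {
    d2 <- outer((px - coord(points[i, 1]))^2, (px - coord(points[i, 2]))^2, `+`)
    rho[d2 <= r_um^2] <- 1
  }
  rho
}

#' Monte-Carlo estimate of ballistic transmission
#'
#' Estimates the coherent (unscattered) power transmission of the phantom's
#' screen stack by propagating a plane wave through independent screen
#' realizations and averaging the complex on-axis (DC) amplitude across
#' realizations.  Averaging the complex amplitude before squaring removes
#' the diffuse speckle contribution at the DC frequency, whose phase is
#' random across realizations.
#'
#' @param depth_smfp Optical depth in SMFP units.
#' @param n_screens Number of screens (default as in [make_phantom()]).
#' @param grid A [grid_spec()].
#' @param n_real Number of independent realizations (>= 2).
#' @param seed Integer seed.
#' @param smfp Scattering mean free path in micrometres.
#' @return A list with `power` (estimate of the ballistic power
#'   transmission, debiased), `se` (its standard error), `expected`
#'   (`exp(-depth_smfp)`) and `n_real`.
#' @export
ballistic_transmission <- function(depth_smfp, n_screens = NULL,
                                   grid = grid_spec(64), n_real = 100L,
                                   seed = 1L, smfp = 52.8) {
  if (is.null(n_screens)) n_screens <- max(1L, ceiling(2 * depth_smfp))
  u0 <- matrix(1 / grid$n, grid$n, grid$n)  # unit-power plane wave
  z <- complex(length.out = n_real)
  for (r in seq_len(n_real)) {
    ph <- make_phantom(grid, smfp = smfp, depth_smfp = depth_smfp,
                       n_screens = n_screens, seed = seed + r - 1L,
                       taper_px = 0L)
    out <- propagate_stack(u0, ph, direction = 1L)
    # DC projection: overlap with the incident plane wave
    z[r] <- sum(out[, , 1L] * Conj(u0))
  }
  zbar <- mean(z)
  v <- stats::var(Re(z)) + stats::var(Im(z))
  power <- Mod(zbar)^2 - v / n_real          # debias |mean|^2
  # error in the amplitude along the mean direction dominates
  s_proj <- stats::sd(Re(z * exp(-1i * Arg(zbar))))
  se <- 2 * Mod(zbar) * s_proj / sqrt(n_real) + v / n_real
  list(power = power, se = se, expected = exp(-depth_smfp), n_real = n_real)
}
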