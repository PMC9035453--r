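# Scanning acquisition of the reflection matrix.
#
# Input basis: each scan point is addressed by a linear phase ramp on the
# SLM conjugate (Fourier) plane.  An ideal lens model turns ramp i into a
# converging beam whose free-space focus lands on scan position i at the
# target depth; the phantom then scatters it on the way in and out.  The
# camera is conjugated to the target plane through free space, so in the
# absence of scattering the reflection matrix is diagonal.

# Checkerboard factor implementing the fftshift that puts the focus of a
# flat ramp at the grid centre.
checkerboard <- function(n) outer((-1)^(0:(n - 1)), (-1)^(0:(n - 1)))

#' Linear phase ramps addressing the scan grid
#'
#' Generates the `n_side^2` SLM phase maps of the scanning input basis, in
#' row-major scan order.  Ramp `i` is a linear phase whose slope steers the
#' focal spot of an ideal lens to scan position `i`; the centre scan point
#' of an odd-sized scan grid gets a flat (zero-slope) map.
#'
#' @param scan A [scan_grid()].
#' @param grid A [grid_spec()].
#' @return An `n x n x n_side^2` array of phase maps in `(-pi, pi]`.
#' @examples
#' r <- make_phase_ramps(scan_grid(31), grid_spec(64))
#' dim(r)[3]  # 961
#' @export
make_phase_ramps <- function(scan, grid) {
  kx <- k_axis(grid)
  pos <- scan$positions
  # steerable range: focus must stay within the FOV sampled by the grid
  half <- grid$n / 2 * grid$pitch
  if (any(abs(pos$x) > half) || any(abs(pos$y) > half))
    stop("scan position outside the steerable range of the grid", call. = FALSE)
  m <- nrow(pos)
  ramps <- array(0, dim = c(grid$n, grid$n, m))
  for (i in seq_len(m)) {
    phi <- -(outer(kx * pos$y[i], kx * pos$x[i], `+`))
    ramps[, , i] <- Arg(exp(1i * phi))
  }
  ramps
}

#' Focal intensity of a phase ramp under an ideal lens
#'
#' Applies the package's ideal lens model (a Fourier transform centred on
#' the grid) to an SLM phase map and returns the focal-plane intensity.
#' Used to verify the Fourier-shift relation between ramp slope and focal
#' position.
#'
#' @param phase_map An `n x n` phase matrix.
#' @param grid A [grid_spec()].
#' @return An `n x n` intensity matrix (unit total energy).
#' @export
ideal_lens_focus <- function(phase_map, grid) {
  n <- grid$n
  u <- ifft2(exp(1i * phase_map) * checkerboard(n))
  Mod(u)^2 / sum(Mod(u)^2)
}

#' Physical surface fields of the scanning input basis
#'
#' For each SLM phase ramp, the unit-power converging beam at the phantom
#' surface: the free-space back-propagation (over the phantom thickness) of
#' the band-limited focal spot the ramp addresses through the ideal lens.
#'
#' @param ramps Phase-map array from [make_phase_ramps()] (an `n x n`
#'   matrix is treated as a single ramp).
#' @param phantom A [make_phantom()] object (sets the conjugation
#'   distance).
#' @return An `n x n x m` array of complex surface fields, unit power each.
#' @export
lens_input_fields <- function(ramps, phantom) {
  grid <- phantom$grid
  n <- grid$n
  if (length(dim(ramps)) == 2L) dim(ramps) <- c(n, n, 1L)
  m <- dim(ramps)[3]
  Hc <- Conj(angular_spectrum_transfer(grid, phantom$thickness))
  cb <- checkerboard(n)
  a <- exp(1i * ramps) * as.vector(cb * Hc)
  # ifft of a unit-modulus spectrum has unit total power (Parseval)
  fft2_batch(a, inverse = TRUE)
}

# Camera conjugation: free-space back-propagation of the returned surface
# field to the target plane (the imaging optics undo the free-space part of
# the return trip, not the scattering).
camera_conjugate <- function(a, phantom) {
  Hc <- Conj(angular_spectrum_transfer(phantom$grid, phantom$thickness))
  A <- fft2_batch(a)
  fft2_batch(A * as.vector(Hc), inverse = TRUE)
}

# Double-pass acquisition of one output column per input field.
# input_fields: n x n x m array of surface fields; returns complex matrix
# of camera fields cropped to the central n_roi x n_roi camera region
# (camera = "target") or raw full-grid surface returns.
# Columns are filled row-major (see fill_rm_column / reshape_to_2d).
acquire_columns <- function(phantom, input_fields, camera = "target",
                            n_roi = NULL) {
  n <- phantom$grid$n
  if (length(dim(input_fields)) == 2L) dim(input_fields) <- c(n, n, 1L)
  m <- dim(input_fields)[3]
  a <- propagate_stack(input_fields, phantom, direction = 1L)
  a <- a * as.vector(phantom$target_reflectivity)
  a <- propagate_stack(a, phantom, direction = -1L)
  if (camera == "target") {
    a <- camera_conjugate(a, phantom)
    if (!is.null(n_roi) && n_roi < n) {
      o <- (n - n_roi) %/% 2
      a <- a[o + seq_len(n_roi), o + seq_len(n_roi), , drop = FALSE]
      n <- n_roi
    }
  }
  a <- aperm(a, c(2L, 1L, 3L))   # row-major column fill
  dim(a) <- c(n^2, m)
  a
}

# side of the central camera region covering the scanned FOV
default_roi <- function(grid, scan) {
  if (is.null(scan)) return(grid$n)
  min(grid$n, 2L * round(scan$fov / grid$pitch / 2))
}

# camera-ROI pixel (row, col), 1-based, of a scan point
roi_pixel <- function(scan, grid, n_roi, point) {
  i <- scan_index(scan, point)
  c(round(n_roi / 2 + scan$positions$y[i] / grid$pitch) + 1L,
    round(n_roi / 2 + scan$positions$x[i] / grid$pitch) + 1L)
}

#' Acquire a scanning reflection matrix
#'
#' Runs the point-by-point acquisition: for every input phase ramp, the
#' corresponding converging beam is propagated through the phantom,
#' reflected at the target plane, propagated back out through the same
#' frozen screens, imaged by the camera, and the reshaped complex camera
#' field is stored as one column of the reflection matrix.  Column order
#' equals input order (row-major over the scan grid).
#'
#' @param phantom A [make_phantom()] object.
#' @param scan A [scan_grid()]; ignored when `ramps` is given together with
#'   `input_basis = "pixel"`.
#' @param ramps Optional precomputed ramp array from [make_phase_ramps()].
#' @param input_basis `"scan"` (focused-spot basis addressed by phase
#'   ramps, the canonical basis) or `"pixel"` (delta inputs on the pixel
#'   grid with raw surface-field output; used for reciprocity checks).
#' @param camera `"target"` (camera conjugated to the target plane,
#'   default) or `"surface"` (raw returned field).
#' @param noise_snr Signal-to-noise ratio of additive complex Gaussian
#'   detection noise per column (total signal power over total noise
#'   power); `Inf` (default) disables noise.
#' @param noise_sd Alternative absolute noise model: per-pixel complex
#'   standard deviation of the detection noise floor, in units of the
#'   (unit) incident field amplitude.  A fixed floor makes the effective
#'   SNR fall with depth as the returned signal weakens, as in a real
#'   heterodyne detector.  Overrides `noise_snr` when given.
#' @param noise_seed Integer seed for the noise draw.
#' @param n_roi Side of the central camera region recorded per column
#'   (camera region of interest); defaults to the pixels covering the
#'   scanned FOV, so `N_out = n_roi^2`.
#' @return An object of class `reflection_matrix`: a list with the complex
#'   `matrix` (`N_out x N_in`), `grid`, `scan`, `n_roi`, `depth_smfp`,
#'   `phantom_seed`, `input_basis`, `camera` and `noise_snr`.
#' @export
acquire_rm <- function(phantom, scan = NULL, ramps = NULL,
                       input_basis = c("scan", "pixel"),
                       camera = c("target", "surface"),
                       noise_snr = Inf, noise_sd = NULL, noise_seed = 1L,
                       n_roi = NULL) {
  input_basis <- match.arg(input_basis)
  camera <- match.arg(camera)
  n <- phantom$grid$n
  if (input_basis == "scan") {
    if (is.null(ramps)) {
      if (is.null(scan)) stop("either 'scan' or 'ramps' must be given", call. = FALSE)
      ramps <- make_phase_ramps(scan, phantom$grid)
    }
    if (dim(ramps)[3] < 1L) stop("empty input set", call. = FALSE)
    inputs <- lens_input_fields(ramps, phantom)
  } else {
    inputs <- array(0i, dim = c(n, n, n^2))
    # delta inputs in row-major pixel order, matching the column fill
    idx <- cbind(rep(seq_len(n), each = n), rep(seq_len(n), times = n),
                 seq_len(n^2))
    inputs[idx] <- 1
    camera <- "surface"
  }
  if (is.null(n_roi)) n_roi <- if (camera == "target")
    default_roi(phantom$grid, scan) else phantom$grid$n
  M <- acquire_columns(phantom, inputs, camera = camera, n_roi = n_roi)
  M <- add_detection_noise(M, noise_snr, noise_sd, noise_seed)
  structure(list(matrix = M, grid = phantom$grid, scan = scan,
                 n_roi = as.integer(n_roi), depth_smfp = phantom$depth_smfp,
                 phantom_seed = phantom$seed, input_basis = input_basis,
                 camera = camera, noise_snr = noise_snr, noise_sd = noise_sd),
            class = "reflection_matrix")
}

add_detection_noise <- function(M, noise_snr = Inf, noise_sd = NULL, seed = 1L) {
  if (is.null(noise_sd) && !is.finite(noise_snr)) return(M)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  if (!is.null(noise_sd)) {
    if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
    if (noise_sd == 0) return(M)
    sd_px <- rep(noise_sd / sqrt(2), ncol(M))
  } else {
    if (noise_snr <= 0) stop("'noise_snr' must be positive", call. = FALSE)
    sd_px <- sqrt(colMeans(Mod(M)^2) / noise_snr / 2)
  }
  noise <- matrix(complex(real = stats::rnorm(length(M)),
                          imaginary = stats::rnorm(length(M))),
                  nrow(M), ncol(M))
  M + sweep(noise, 2L, sd_px, `*`)
}

#' @export
print.reflection_matrix <- function(x, ...) {
  cat(sprintf(paste0("<reflection_matrix> %d x %d (%s basis, camera at %s), ",
                     "depth %.3g SMFP, phantom seed %d\n"),
              nrow(x$matrix), ncol(x$matrix), x$input_basis, x$camera,
              x$depth_smfp, x$phantom_seed))
  invisible(x)
}

rm_matrix <- function(R) {
  if (inherits(R, "reflection_matrix")) R$matrix else as.matrix(R)
}

#' Synthetic heterodyne beat frames
#'
#' Generates the idealized lock-in camera record: intensity frames of the
#' interference between a static sample field and a frequency-shifted
#' reference, `I(t) = P_ref + |E|^2 + 2 sqrt(P_ref) |E| cos(2 pi f t + arg E)`.
#'
#' @param field Complex sample field (matrix).
#' @param f_beat Beat frequency, Hz.
#' @param frame_rate Camera frame rate, Hz.
#' @param n_frames Number of frames; choose an integer number of beat
#'   periods for exact demodulation.
#' @param reference_power Reference beam power per pixel.
#' @return An `n x n x n_frames` array of real intensity frames.
#' @export
beat_frames <- function(field, f_beat, frame_rate, n_frames,
                        reference_power = 1) {
  v <- field_values(field)
  t <- (seq_len(n_frames) - 1) / frame_rate
  frames <- array(0, dim = c(dim(v), n_frames))
  for (k in seq_len(n_frames))
    frames[, , k] <- reference_power + Mod(v)^2 +
      2 * sqrt(reference_power) * Mod(v) * cos(2 * pi * f_beat * t[k] + Arg(v))
  frames
}

#' Lock-in quadrature demodulation of heterodyne frames
#'
#' Recovers the complex sample field per pixel from a time series of
#' intensity frames of the heterodyne beat, by quadrature projection at the
#' beat frequency.  Exact for noiseless synthetic beats sampled over an
#' integer number of periods.
#'
#' @param frames Real `n x n x T` array of intensity frames.
#' @param f_beat Beat frequency, Hz (e.g. 40 kHz for reference and sample
#'   modulators offset by 40.00 and 40.04 MHz).
#' @param frame_rate Camera frame rate, Hz; must provide at least 4 frames
#'   per beat period.
#' @param reference_power Reference beam power per pixel (> 0).
#' @return Complex matrix of the demodulated sample field
#'   (`amplitude * exp(1i * phase)`).
#' @export
lockin_demodulate <- function(frames, f_beat, frame_rate, reference_power = 1) {
  if (frame_rate < 4 * f_beat)
    stop("aliasing: fewer than 4 frames per beat period", call. = FALSE)
  if (reference_power <= 0) stop("'reference_power' must be positive", call. = FALSE)
  d <- dim(frames)
  T_ <- d[3]
  t <- (seq_len(T_) - 1) / frame_rate
  cw <- cos(2 * pi * f_beat * t)
  sw <- sin(2 * pi * f_beat * t)
  dim(frames) <- c(d[1] * d[2], T_)
  Ic <- frames %*% cw
  Is <- -(frames %*% sw)
  amp <- sqrt(Ic^2 + Is^2) / (2 * sqrt(reference_power) * (T_ / 2))
  phase <- atan2(Is, Ic)
  matrix(complex(modulus = amp, argument = phase), d[1], d[2])
}

#' Upsample a camera-pitch phase map to SLM pitch
#'
#' The camera pixel pitch is an integer multiple of the SLM pixel pitch, so
#' phase maps derived from camera data must be upsampled before loading on
#' the SLM.  Interpolation acts on the unit-modulus complex phasor, not the
#' raw phase, so it is safe across the +/- pi branch cut; constant maps are
#' preserved exactly.
#'
#' @param phase_map Real `n x n` phase matrix.
#' @param factor Integer upsampling factor (default 5: camera pitch five
#'   times the SLM pitch).
#' @return An `(n * factor) x (n * factor)` phase matrix in `(-pi, pi]`.
#' @export
resample_camera_to_slm <- function(phase_map, factor = 5L) {
  if (length(factor) != 1L || !is.finite(factor) || factor != round(factor) ||
      factor < 1L)
    stop("'factor' must be a positive integer", call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) return(phase_map)
  n <- nrow(phase_map)
  z <- exp(1i * phase_map)
  # fine-grid sample positions in coarse pixel units (centres aligned)
  p <- (seq_len(n * factor) - 0.5) / factor + 0.5
  i0 <- pmin(pmax(floor(p), 1L), n - 1L)
  w <- pmin(pmax(p - i0, 0), 1)
  interp_rows <- function(M) {
    M[i0, , drop = FALSE] * (1 - w) + M[i0 + 1L, , drop = FALSE] * w
  }
  z2 <- interp_rows(z)
  z2 <- t(interp_rows(t(z2)))
  Arg(z2)
}
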