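#' Pixel grid specification
#'
#' Defines the square sampling grid shared by the spatial light modulator
#' (SLM) conjugate plane, the phantom planes and the camera: `n` pixels per
#' side over a physical field of view `fov` (micrometres), at vacuum
#' wavelength `wavelength` (micrometres).
#'
#' The defaults (64 px over 70 um at 0.8 um) keep the full angular spectrum
#' of the grid propagating (pixel pitch > wavelength/sqrt(2)), so free-space
#' transfer is exactly unitary.
#'
#' @param n Pixels per side; even integer, at least 16.
#' @param fov Physical side length of the field of view, in micrometres.
#' @param wavelength Vacuum wavelength, in micrometres.
#' @return An object of class `grid_spec` with elements `n`, `fov`,
#'   `pitch` (= `fov / n`) and `wavelength`.
#' @examples
#' g <- grid_spec(32)
#' g$pitch
#' @export
grid_spec <- function(n = 64L, fov = 70, wavelength = 0.8) {
  n <- as.integer(n)
  if (length(n) != 1L || !is.finite(n) || n < 16L || n %% 2L != 0L)
    stop("'n' must be a single even integer >= 16", call. = FALSE)
  if (!is.finite(fov) || fov <= 0) stop("'fov' must be positive", call. = FALSE)
  if (!is.finite(wavelength) || wavelength <= 0)
    stop("'wavelength' must be positive", call. = FALSE)
  structure(list(n = n, fov = fov, pitch = fov / n, wavelength = wavelength),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d px, %.3g um pitch, FOV %.3g um, lambda %.3g um\n",
              x$n, x$n, x$pitch, x$fov, x$wavelength))
  invisible(x)
}

#' Scan grid of focal target points
#'
#' The point-by-point scanning basis: `n_side` x `n_side` focal targets
#' covering the field of view.  Scan positions are indexed `(row, col)` with
#' 1-based indices, row-major, and are mapped to physical coordinates
#' centred on the optical axis.
#'
#' @param n_side Scan points per side (default 31, i.e. 961 inputs).
#' @param fov Field of view covered by the scan, in micrometres.
#' @return An object of class `scan_grid` with elements `n_side`, `fov`,
#'   `pitch` (scan-point spacing) and `positions`, a data frame of
#'   `(row, col, x, y)` in row-major order.
#' @examples
#' s <- scan_grid(31)
#' nrow(s$positions)  # 961
#' @export
scan_grid <- function(n_side = 31L, fov = 70) {
  n_side <- as.integer(n_side)
  if (n_side < 2L) stop("'n_side' must be at least 2", call. = FALSE)
  idx <- expand.grid(col = seq_len(n_side), row = seq_len(n_side))
  pitch <- fov / n_side
  # centred physical coordinates of scan point (row, col)
  coord <- function(i) (i - (n_side + 1) / 2) * pitch
  positions <- data.frame(row = idx$row, col = idx$col,
                          x = coord(idx$col), y = coord(idx$row))
  structure(list(n_side = n_side, fov = fov, pitch = pitch,
                 positions = positions),
            class = "scan_grid")
}

#' @export
print.scan_grid <- function(x, ...) {
  cat(sprintf("<scan_grid> %d x %d scan points (%d inputs), FOV %.3g um\n",
              x$n_side, x$n_side, x$n_side^2, x$fov))
  invisible(x)
}

scan_index <- function(scan, point) {
  point <- as.integer(point)
  if (length(point) != 2L || any(point < 1L) || any(point > scan$n_side))
    stop("scan point out of range", call. = FALSE)
  (point[1] - 1L) * scan$n_side + point[2]
}

#' Complex optical field on a pixel grid
#'
#' A light wrapper pairing a complex amplitude matrix with its grid and a
#' plane label.  Most package functions accept either a `complex_field` or a
#' bare complex matrix.
#'
#' @param values Complex (or numeric) matrix, `grid$n` x `grid$n`.
#' @param grid A [grid_spec()].
#' @param plane Plane label, one of `"slm"`, `"surface"`, `"target"`,
#'   `"camera"`.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(values, grid, plane = "surface") {
  plane <- match.arg(plane, c("slm", "surface", "target", "camera"))
  values <- as.matrix(values)
  if (!all(dim(values) == grid$n)) stop("field does not match grid", call. = FALSE)
  if (!all(is.finite(Re(values)) & is.finite(Im(values))))
    stop("field contains non-finite entries", call. = FALSE)
  structure(list(values = values + 0i, grid = grid, plane = plane),
            class = "complex_field")
}

field_values <- function(field) {
  if (inherits(field, "complex_field")) field$values else as.matrix(field) + 0i
}

#' Total optical power of a field
#'
#' Sum of squared moduli over all pixels.
#'
#' @param field A `complex_field` or complex matrix.
#' @return A single non-negative number.
#' @export
field_power <- function(field) {
  v <- field_values(field)
  sum(Re(v)^2 + Im(v)^2)
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d at plane '%s', power %.6g\n",
              nrow(x$values), ncol(x$values), x$plane, field_power(x)))
  invisible(x)
}

# Angular frequencies (rad/um) of the FFT grid, unshifted ordering.
k_axis <- function(grid) {
  n <- grid$n
  f <- c(0:(n / 2 - 1), -(n / 2):-1) / (n * grid$pitch)
  2 * pi * f
}
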