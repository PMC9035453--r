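# Split-step angular-spectrum propagation.
#
# Fields live on the grid_spec pixel grid; free-space transfer is applied in
# the spatial-frequency domain with the exact non-paraxial kernel
# exp(i * dz * sqrt(k0^2 - kx^2 - ky^2)).  For the default grids every
# discrete frequency is propagating, so the kernel is unit-modulus and the
# step is unitary.

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Batch 2D FFT of m fields stored as an n x n x m array, via column FFTs
# (one C call per dimension for the whole batch).
fft2_batch <- function(a, inverse = FALSE) {
  d <- dim(a)
  n <- d[1]; m <- if (length(d) == 3L) d[3] else 1L
  dim(a) <- c(n, n * m)
  a <- stats::mvfft(a, inverse = inverse)
  dim(a) <- c(n, n, m)
  a <- aperm(a, c(2L, 1L, 3L))
  dim(a) <- c(n, n * m)
  a <- stats::mvfft(a, inverse = inverse)
  dim(a) <- c(n, n, m)
  a <- aperm(a, c(2L, 1L, 3L))
  if (inverse) a / n^2 else a
}

#' Free-space angular-spectrum transfer function
#'
#' @param grid A [grid_spec()].
#' @param dz Propagation distance in micrometres (may be 0).
#' @return Complex `n x n` matrix of per-frequency transfer factors
#'   (unit modulus for propagating components, 0 for evanescent ones).
#' @keywords internal
angular_spectrum_transfer <- function(grid, dz) {
  k0 <- 2 * pi / grid$wavelength
  kx <- k_axis(grid)
  k2 <- outer(kx^2, kx^2, `+`)
  kz2 <- k0^2 - k2
  H <- matrix(0i, grid$n, grid$n)
  prop <- kz2 > 0
  H[prop] <- exp(1i * dz * sqrt(kz2[prop]))
  H
}

# Cosine-taper absorbing frame (1 in the interior, smoothly to 0 at the
# edge) used to suppress periodic wrap-around of scattered light.
taper_mask <- function(n, taper_px) {
  if (taper_px <= 0) return(matrix(1, n, n))
  w <- rep(1, n)
  ramp <- 0.5 * (1 - cos(pi * (seq_len(taper_px) - 0.5) / taper_px))
  w[seq_len(taper_px)] <- ramp
  w[n + 1 - seq_len(taper_px)] <- rev(ramp)
  outer(w, w)
}

# Propagate a batch of fields (n x n x m array) through the phantom's screen
# stack from the surface to the target plane (direction = +1) or back
# (direction = -1).  The same frozen screen realization is traversed in
# reversed order on the way back, so the medium is reciprocal.
# Returns the field array with attribute "absorbed": total power removed by
# the boundary taper.
propagate_stack <- function(a, phantom, direction = 1L) {
  n <- phantom$grid$n
  if (length(dim(a)) == 2L) dim(a) <- c(n, n, 1L)
  ns <- phantom$n_screens
  if (phantom$thickness == 0 && all(phantom$screen_sigma == 0)) {
    attr(a, "absorbed") <- 0
    return(a)
  }
  dz <- phantom$thickness / ns
  H_half <- angular_spectrum_transfer(phantom$grid, dz / 2)
  H_full <- angular_spectrum_transfer(phantom$grid, dz)
  mask <- taper_mask(n, phantom$taper_px)
  order <- if (direction >= 0) seq_len(ns) else rev(seq_len(ns))
  absorbed <- 0
  step <- function(a, H) {
    A <- fft2_batch(a)
    A <- A * as.vector(H)   # recycled over the batch dimension
    fft2_batch(A, inverse = TRUE)
  }
  a <- step(a, H_half)
  for (j in seq_len(ns)) {
    phase <- phantom$screens[, , order[j]]
    a <- a * as.vector(exp(1i * phase))
    if (phantom$taper_px > 0) {
      p0 <- sum(Re(a)^2 + Im(a)^2)
      a <- a * as.vector(mask)
      absorbed <- absorbed + p0 - sum(Re(a)^2 + Im(a)^2)
    }
    a <- step(a, if (j < ns) H_full else H_half)
  }
  attr(a, "absorbed") <- absorbed
  a
}

#' Propagate a field through a scattering phantom
#'
#' Split-step angular-spectrum propagation between the phantom's planes,
#' alternating free-space transfer with multiplication by the frozen random
#' phase screens.  The phase screens are unit-modulus, so total power is
#' conserved except for losses in the absorbing boundary frame, which are
#' reported separately in the `"absorbed"` attribute.
#'
#' @param field A [complex_field()] or complex matrix on the phantom grid.
#' @param phantom A [make_phantom()] object.
#' @param from,to Plane labels; one of `"surface"`, `"target"`.  Propagation
#'   from `"surface"` to `"target"` traverses the screens in order; the
#'   reverse traverses them in reversed order (reciprocal medium).
#' @return A [complex_field()] at the destination plane, with attribute
#'   `"absorbed"` giving the power removed by the boundary taper.
#' @export
propagate <- function(field, phantom, from = "surface", to = "target") {
  from <- match.arg(from, c("surface", "target"))
  to <- match.arg(to, c("surface", "target"))
  v <- field_values(field)
  if (!all(dim(v) == phantom$grid$n)) stop("field/grid dimension mismatch", call. = FALSE)
  if (from == to) {
    out <- complex_field(v, phantom$grid, plane = from)
    attr(out, "absorbed") <- 0
    return(out)
  }
  dir <- if (from == "surface") 1L else -1L
  a <- propagate_stack(v, phantom, direction = dir)
  out <- complex_field(a[, , 1L], phantom$grid, plane = to)
  attr(out, "absorbed") <- attr(a, "absorbed")
  out
}

#' Double-pass reflection from the target plane
#'
#' Propagates the incident field from the surface to the target plane
#' through the phantom, multiplies by the target reflectivity map, and
#' propagates back out through the same frozen screen realization in
#' reversed order.  The round trip through unit-modulus screens makes the
#' monostatic pixel-basis reflection operator symmetric (optical
#' reciprocity).
#'
#' @param field Incident [complex_field()] (or complex matrix) at the
#'   surface plane.
#' @param phantom A [make_phantom()] object.
#' @return Reflected [complex_field()] at the surface plane.
#' @export
reflect_from_target <- function(field, phantom) {
  v <- field_values(field)
  if (!all(dim(v) == phantom$grid$n)) stop("field/grid dimension mismatch", call. = FALSE)
  a <- propagate_stack(v, phantom, direction = 1L)
  absorbed <- attr(a, "absorbed")
  a <- a * as.vector(phantom$target_reflectivity)
  a <- propagate_stack(a, phantom, direction = -1L)
  out <- complex_field(a[, , 1L], phantom$grid, plane = "surface")
  attr(out, "absorbed") <- absorbed + attr(a, "absorbed")
  out
}
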