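# The model energy matrix and focus metrics.
#
# E_m = V F S V^T of the calibrated time-reversal decomposition acts as a
# virtual camera inside the sample: the squared moduli of its column for
# scan point i, reshaped to the scan grid, map how the energy launched
# toward point i is distributed over the target plane.

#' Model energy matrix
#'
#' Computes `E_m = V %*% diag(F * S) %*% Conj(t(V))` from a calibrated
#' decomposition: the Hermitian filtered time-reversal form whose
#' per-column intensity maps visualize the internal energy distribution per
#' scan point.  The conjugate transpose makes `E_m` independent of the
#' per-column phase ambiguity of the decomposition; for an identity
#' reflection matrix every scan point's map is a delta at itself.
#'
#' @param fit A [tr_fit()] object (or a [tr_decompose()] plus `lambda`).
#' @param lambda Regularization parameter; defaults to the fitted value.
#' @return An object of class `energy_matrix`: list with `em`
#'   (`n_in x n_in` complex), `lambda`, `scan` and `depth_smfp` (when
#'   available from the acquisition metadata).
#' @export
model_energy_matrix <- function(fit, lambda = NULL) {
  if (inherits(fit, "tr_fit")) {
    trd <- fit$trd
    if (is.null(lambda)) lambda <- fit$lambda
    scan <- fit$meta$scan
    depth <- fit$meta$depth_smfp
  } else {
    trd <- as_trd(fit)
    if (is.null(lambda)) stop("'lambda' required for a bare decomposition", call. = FALSE)
    scan <- NULL
    depth <- NA_real_
  }
  f <- tikhonov_filter(trd$s, lambda)
  em <- trd$v %*% ((f * trd$s) * Conj(t(trd$v)))
  structure(list(em = em, lambda = lambda, scan = scan, depth_smfp = depth),
            class = "energy_matrix")
}

#' @export
print.energy_matrix <- function(x, ...) {
  cat(sprintf("<energy_matrix> %d x %d, lambda = %.4g\n",
              nrow(x$em), ncol(x$em), x$lambda))
  invisible(x)
}

#' Internal energy map at one scan point
#'
#' The squared moduli of the model-energy-matrix column for the given scan
#' point, reshaped row-major to the scan grid: the modelled energy
#' distribution over the target plane when the scan addresses that point.
#'
#' @param em An [model_energy_matrix()] object.
#' @param point Scan point `(row, col)`, 1-based.
#' @param scan The [scan_grid()] (defaults to the one stored in `em`).
#' @param normalize `"none"` (raw energies, default) or `"max"` (peak 1;
#'   for display only).
#' @return An `n_side x n_side` intensity matrix whose entries sum to the
#'   squared norm of the selected column (when `normalize = "none"`).
#' @export
energy_map_at_point <- function(em, point, scan = em$scan,
                                normalize = c("none", "max")) {
  normalize <- match.arg(normalize)
  if (is.null(scan)) stop("no scan grid available", call. = FALSE)
  i <- scan_index(scan, point)
  map <- matrix(Mod(em$em[, i])^2, scan$n_side, scan$n_side, byrow = TRUE)
  if (normalize == "max") {
    if (max(map) == 0) stop("degenerate (all-zero) energy map", call. = FALSE)
    map <- map / max(map)
  }
  map
}

disk_mask <- function(nr, nc, centre, radius) {
  outer((seq_len(nr) - centre[1])^2, (seq_len(nc) - centre[2])^2, `+`) <= radius^2
}

#' Focus-quality metrics of an intensity map
#'
#' Scores an intensity map against the diffraction-limited focusing
#' criterion: the map should show a single central peak at the incident
#' point with about 80% or more of the energy inside the central region
#' (the encircled energy of an ideal Airy pattern inside its first dark
#' ring is about 84%).
#'
#' @param map Non-negative intensity matrix (any grid).
#' @param incident_point `(row, col)` of the addressed point, 1-based, in
#'   map units.
#' @param disk_radius Radius of the central region in map pixels (default
#'   1.5, the first Airy null of the default scan geometry).
#' @param reference_peak Optional reference peak intensity (e.g. the
#'   shallow-depth unshaped peak) for `relative_intensity`.
#' @return An object of class `focus_report`: `peak_position` (row, col),
#'   `peak_shift` (Euclidean distance from the incident point, pixels),
#'   `central_fraction` (energy inside the disk at the incident point over
#'   total), `fwhm` (full width at half maximum through the peak, pixels,
#'   by linear contour interpolation), `is_diffraction_limited`
#'   (`peak_shift == 0` and `central_fraction >= 0.8`), `peak_intensity`
#'   and `relative_intensity`.
#' @export
focus_metrics <- function(map, incident_point, disk_radius = 1.5,
                          reference_peak = NULL) {
  map <- as.matrix(map)
  if (any(map < 0) || any(!is.finite(map)))
    stop("map must be non-negative and finite", call. = FALSE)
  total <- sum(map)
  if (total <= 0) stop("degenerate (all-zero) map", call. = FALSE)
  pk <- which(map == max(map), arr.ind = TRUE)
  pk <- pk[order(pk[, 1], pk[, 2])[1], ]           # lexicographic tie-break
  peak <- c(pk[["row"]], pk[["col"]])
  shift <- sqrt(sum((peak - incident_point)^2))
  mask <- disk_mask(nrow(map), ncol(map), incident_point, disk_radius)
  central_fraction <- sum(map[mask]) / total
  fwhm <- mean(c(profile_fwhm(map[peak[1], ], peak[2]),
                 profile_fwhm(map[, peak[2]], peak[1])), na.rm = TRUE)
  structure(list(peak_position = peak, peak_shift = shift,
                 central_fraction = central_fraction, fwhm = fwhm,
                 is_diffraction_limited = (shift == 0) && central_fraction >= 0.8,
                 peak_intensity = max(map),
                 relative_intensity = if (is.null(reference_peak)) NA_real_
                                      else max(map) / reference_peak),
            class = "focus_report")
}

# half-maximum crossings of a 1D profile around index i0, linear interpolation
profile_fwhm <- function(p, i0) {
  half <- p[i0] / 2
  cross <- function(idx) {
    for (k in idx) {
      if (p[k] < half) {
        prev <- k + if (k < i0) 1L else -1L
        return(abs(k - i0) - (half - p[k]) / (p[prev] - p[k]))
      }
    }
    NA_real_
  }
  left <- cross(rev(seq_len(i0 - 1L)))
  right <- cross(seq(i0 + 1L, length(p), length.out = max(0, length(p) - i0)))
  left + right
}

#' @export
print.focus_report <- function(x, ...) {
  cat(sprintf(paste0("<focus_report> peak (%d,%d), shift %.2f px, ",
                     "central fraction %.3f, FWHM %.2f px%s\n"),
              x$peak_position[1], x$peak_position[2], x$peak_shift,
              x$central_fraction, x$fwhm,
              if (isTRUE(x$is_diffraction_limited)) ", diffraction-limited" else ""))
  invisible(x)
}

#' Sampled Airy intensity pattern
#'
#' The diffraction-limited focal intensity `(2 J1(v)/v)^2` of a circular
#' aperture, sampled on an `n x n` grid with the first dark ring at radius
#' `null_radius` pixels from `centre`.
#'
#' @param n Grid side.
#' @param null_radius Radius of the first Airy null, pixels.
#' @param centre Centre `(row, col)`; defaults to the grid centre.
#' @return An `n x n` intensity matrix with unit peak.
#' @export
airy_pattern <- function(n, null_radius, centre = c((n + 1) / 2, (n + 1) / 2)) {
  j1_zero <- 3.831706
  r <- sqrt(outer((seq_len(n) - centre[1])^2, (seq_len(n) - centre[2])^2, `+`))
  v <- j1_zero * r / null_radius
  I <- ifelse(v == 0, 1, (2 * besselJ(v, 1) / v)^2)
  I
}

#' Energy-delivery enhancement between two intensity maps
#'
#' Ratio of the energy delivered inside the central disk at the incident
#' point, shaped over unshaped.  Both maps must share the same grid and the
#' same acquisition normalization (no per-map rescaling), so the ratio
#' measures physical redistribution of a fixed incident power.
#'
#' @param map_shaped,map_plane Intensity maps on a common grid.
#' @param incident_point `(row, col)` of the addressed point.
#' @param disk_radius Central-disk radius in map pixels.
#' @return The enhancement ratio (dimensionless).
#' @export
enhancement <- function(map_shaped, map_plane, incident_point,
                        disk_radius = 1.5) {
  if (!all(dim(map_shaped) == dim(map_plane)))
    stop("maps must share a grid", call. = FALSE)
  mask <- disk_mask(nrow(map_plane), ncol(map_plane), incident_point, disk_radius)
  ref <- sum(map_plane[mask])
  if (ref <= 0) stop("degenerate reference: no unshaped energy in the disk", call. = FALSE)
  sum(map_shaped[mask]) / ref
}
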