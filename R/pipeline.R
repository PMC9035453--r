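# The three-step shaping protocol on synthetic phantoms:
#   step 1: measure the scanning RM at each depth, calibrate the
#           time-reversal decomposition, compute the model energy matrix
#           and focus metrics with plane (ramp) inputs;
#   step 2: invert the RM for matched wavefronts and apply the phase-only
#           constraint;
#   step 3: re-measure with the shaped wavefronts against the same frozen
#           phantom and compare energy delivery and photon classes.

#' Experiment configuration for the shaping protocol
#'
#' Bundles the study conditions: phantom, grids, probe points, noise floor,
#' regularization and threshold policy.  Two size profiles are provided:
#' `"full"` (80 px field grid, 31 x 31 scan, the probe layout
#' (6,6), (6,26), (16,16), (26,6), (26,26)) and `"desk"` (40 px grid,
#' 17 x 17 scan, probe layout scaled to (4,4), (4,14), (9,9), (14,4),
#' (14,14)).  The scan covers a 70 um field of view; the pixel grid
#' extends 25% further so the absorbing boundary frame lies outside the
#' scanned region.
#'
#' @param profile `"full"` or `"desk"` size profile.
#' @param depths Optical depths (SMFP units) of the study.
#' @param smfp Scattering mean free path, um.
#' @param target `"beads"` (small reflectors at the probe points,
#'   emulating discrete scatterers examined at known positions; the
#'   default for the shaping study), `"disks"` (a periodic lattice of such
#'   reflectors) or `"mirror"` (uniform reflective plane; the default
#'   choice for unshaped depth-degradation mapping).
#' @param disk_radius Reflector radius in scan units (for `"beads"` and
#'   `"disks"`).
#' @param noise_sd Per-pixel complex detection noise floor (see
#'   [acquire_rm()]); 0 disables noise.
#' @param probe_frac Fraction of scan inputs re-measured for the
#'   deviation-criterion selection of lambda.
#' @param lambda `"auto"` (deviation criterion) or a fixed value.
#' @param lambda_grid Candidate grid for the selection.
#' @param threshold `"mp"` or a fixed singular-value cutoff.
#' @param focus_radius Central-region radius for focus metrics, scan px.
#' @param seed Master seed; all per-depth seeds derive from it.
#' @param n_px,n_scan,probes,disk_period,disk_offset Size overrides
#'   (defaults set by `profile`).
#' @param wavelength,fov Optical grid parameters, um.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(profile = c("desk", "full"),
                              depths = c(2.4, 4.8, 7.2, 9.6, 14.4),
                              smfp = 52.8,
                              target = c("beads", "disks", "mirror"),
                              disk_radius = 0.5, noise_sd = 1e-3,
                              probe_frac = 0.1, lambda = "auto",
                              lambda_grid = lambda_grid_default(),
                              threshold = "mp", focus_radius = 1.5,
                              seed = 1L, n_px = NULL, n_scan = NULL,
                              probes = NULL, disk_period = NULL,
                              disk_offset = NULL, wavelength = 0.8,
                              fov = 70) {
  profile <- match.arg(profile)
  target <- match.arg(target)
  if (profile == "full") {
    if (is.null(n_px)) n_px <- 80L
    if (is.null(n_scan)) n_scan <- 31L
    if (is.null(probes))
      probes <- rbind(c(6, 6), c(6, 26), c(16, 16), c(26, 6), c(26, 26))
    if (is.null(disk_period)) disk_period <- 10L
    if (is.null(disk_offset)) disk_offset <- 6L
  } else {
    if (is.null(n_px)) n_px <- 40L
    if (is.null(n_scan)) n_scan <- 17L
    if (is.null(probes))
      probes <- rbind(c(4, 4), c(4, 14), c(9, 9), c(14, 4), c(14, 14))
    if (is.null(disk_period)) disk_period <- 5L
    if (is.null(disk_offset)) disk_offset <- 4L
  }
  # the pixel grid extends 25% beyond the scanned FOV so that the
  # absorbing boundary frame sits outside the measurement region
  grid <- grid_spec(n_px, fov = fov * 1.25, wavelength = wavelength)
  scan <- scan_grid(n_scan, fov = fov)
  taper_px <- max(2L, round(n_px / 10))
  probes <- as.matrix(probes)
  apply(probes, 1, function(p) scan_index(scan, p))  # validates range
  structure(list(profile = profile, grid = grid, scan = scan,
                 depths = depths, smfp = smfp, target = target,
                 disk_period = disk_period, disk_offset = disk_offset,
                 disk_radius = disk_radius, noise_sd = noise_sd,
                 probe_frac = probe_frac, lambda = lambda,
                 lambda_grid = lambda_grid, threshold = threshold,
                 focus_radius = focus_radius, probes = probes,
                 taper_px = taper_px, seed = as.integer(seed)),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(paste0("<experiment_config> profile '%s': %d px grid, %d x %d scan, ",
                     "depths {%s} SMFP, target %s, noise sd %.2g, seed %d\n"),
              x$profile, x$grid$n, x$scan$n_side, x$scan$n_side,
              paste(x$depths, collapse = ", "), x$target, x$noise_sd, x$seed))
  invisible(x)
}

config_target_map <- function(config) {
  switch(config$target,
         mirror = NULL,                        # make_phantom default
         beads = beads_target(config$grid, config$scan, config$probes,
                              radius = config$disk_radius),
         disks = disk_lattice_target(config$grid, config$scan,
                                     period = config$disk_period,
                                     offset = config$disk_offset,
                                     radius = config$disk_radius))
}

config_phantom <- function(config, depth, depth_index) {
  make_phantom(config$grid, smfp = config$smfp, depth_smfp = depth,
               target_reflectivity = config_target_map(config),
               taper_px = config$taper_px,
               seed = config$seed * 1000L + depth_index)
}

#' Step 1: scanning acquisition and calibrated decomposition per depth
#'
#' For each configured depth: builds the phantom, acquires the scanning
#' reflection matrix with ramp inputs, selects the regularization parameter
#' by the deviation criterion on re-measured probe inputs, computes the
#' model energy matrix, and scores focus metrics at the probe points.
#'
#' @param config An [experiment_config()].
#' @return A list of class `protocol_step1`: per depth a list with
#'   `phantom`, `rm`, `fit`, `em` and `focus` (data frame of per-probe
#'   metrics); plus the shared `ramps` and `config`.
#' @export
run_step1 <- function(config) {
  ramps <- make_phase_ramps(config$scan, config$grid)
  ns <- if (config$noise_sd > 0) config$noise_sd else NULL
  per_depth <- lapply(seq_along(config$depths), function(di) {
    d <- config$depths[di]
    ph <- config_phantom(config, d, di)
    rm_ <- acquire_rm(ph, scan = config$scan, ramps = ramps,
                      noise_sd = ns, noise_seed = config$seed * 1000L + di)
    probes_cv <- if (identical(config$lambda, "auto"))
      reacquire_probes(ph, config$scan, frac = config$probe_frac,
                       ramps = ramps, noise_sd = ns,
                       seed = config$seed * 1000L + 500L + di) else NULL
    fit <- tr_fit(rm_, lambda = config$lambda, probes = probes_cv,
                  lambda_grid = config$lambda_grid,
                  threshold = config$threshold)
    em <- model_energy_matrix(fit)
    focus <- do.call(rbind, lapply(seq_len(nrow(config$probes)), function(i) {
      p <- config$probes[i, ]
      fr <- focus_metrics(energy_map_at_point(em, p), p,
                          disk_radius = config$focus_radius)
      data.frame(depth_smfp = d, row = p[1], col = p[2],
                 peak_row = fr$peak_position[1], peak_col = fr$peak_position[2],
                 peak_shift = fr$peak_shift,
                 central_fraction = fr$central_fraction, fwhm = fr$fwhm,
                 diffraction_limited = fr$is_diffraction_limited,
                 peak_intensity = fr$peak_intensity)
    }))
    list(depth_smfp = d, phantom = ph, rm = rm_, fit = fit, em = em,
         focus = focus)
  })
  structure(list(per_depth = per_depth, ramps = ramps, config = config),
            class = "protocol_step1")
}

#' Step 2: matched wavefronts by RM inversion
#'
#' Inverts each depth's calibrated decomposition for the matched incident
#' wavefronts, reshapes them to 2D maps and applies the phase-only
#' constraint.
#'
#' @param step1 A [run_step1()] result.
#' @param targets `"all"` (every scan point; required for the step-3
#'   model-energy comparison) or a two-column matrix of scan points.
#' @return A list of class `protocol_step2`: per depth a
#'   [wavefront_set()].
#' @export
run_step2 <- function(step1, targets = "all") {
  config <- step1$config
  tg <- if (identical(targets, "all"))
    as.matrix(config$scan$positions[, c("row", "col")]) else as.matrix(targets)
  per_depth <- lapply(step1$per_depth, function(sd)
    wavefront_set(sd$fit, sd$phantom, tg, ramps = step1$ramps,
                  scan = config$scan))
  structure(list(per_depth = per_depth, targets = tg, config = config),
            class = "protocol_step2")
}

#' Step 3: shaped re-acquisition and before/after comparison
#'
#' Re-acquires the reflection matrix with the matched wavefronts against
#' the same frozen phantom realizations, recomputes the model energy matrix
#' and photon classification with the step-1 calibration (same lambda and
#' threshold, for comparability), and reports per depth: the energy-
#' delivery enhancement at the probe points (ratio of model-energy maps,
#' plus the simulator's ground-truth internal delivery), and the
#' three-class photon bookkeeping with the open-channel gain.
#'
#' @param step1,step2 Results of the previous steps (same config).
#' @return A list of class `protocol_report` with elements `comparison`
#'   (data frame per depth x probe), `fractions` (per-depth photon-class
#'   triples and gain) and `per_depth` detail.
#' @export
run_step3 <- function(step1, step2) {
  config <- step1$config
  if (!identical(step2$config$seed, config$seed))
    stop("stale protocol: step 1 and step 2 use different seeds", call. = FALSE)
  ns <- if (config$noise_sd > 0) config$noise_sd else NULL
  full_scan <- nrow(step2$targets) == config$scan$n_side^2
  per_depth <- lapply(seq_along(step1$per_depth), function(di) {
    s1 <- step1$per_depth[[di]]
    wf <- step2$per_depth[[di]]
    rm_sh <- shaped_reacquire(s1$phantom, wf, noise_sd = ns,
                              noise_seed = config$seed * 1000L + 750L + di)
    fit_sh <- tr_fit(rm_sh, lambda = s1$fit$lambda,
                     threshold = s1$fit$threshold)
    cls <- photon_fractions(s1$fit$classification, fit_sh$classification)
    gain <- open_channel_gain(s1$fit$classification, fit_sh$classification)
    em_sh <- if (full_scan) {
      e <- model_energy_matrix(fit_sh, lambda = s1$fit$lambda)
      e$scan <- config$scan
      e
    } else NULL
    comparison <- do.call(rbind, lapply(seq_len(nrow(config$probes)), function(i) {
      p <- config$probes[i, ]
      enh_em <- if (!is.null(em_sh)) {
        m1 <- energy_map_at_point(s1$em, p)
        m2 <- energy_map_at_point(em_sh, p)
        enhancement(m2, m1, p, disk_radius = config$focus_radius)
      } else NA_real_
      # ground truth: actual energy arriving in the central disk at the
      # target plane, shaped vs plane input
      px <- scan_to_pixel(config$scan, config$grid, p)
      rpx <- config$focus_radius * config$scan$pitch / config$grid$pitch
      iu <- scan_index(config$scan, p)
      it <- if (full_scan) iu else match(TRUE, step2$targets[, 1] == p[1] &
                                           step2$targets[, 2] == p[2])
      enh_gt <- if (!is.na(it)) {
        u_plane <- lens_input_fields(step1$ramps[, , iu], s1$phantom)[, , 1]
        enhancement(internal_intensity(s1$phantom, wf$fields[, , it]),
                    internal_intensity(s1$phantom, u_plane), px,
                    disk_radius = rpx)
      } else NA_real_
      data.frame(depth_smfp = s1$depth_smfp, row = p[1], col = p[2],
                 enhancement_em = enh_em, enhancement_internal = enh_gt)
    }))
    list(depth_smfp = s1$depth_smfp, rm_shaped = rm_sh, fit_shaped = fit_sh,
         em_shaped = em_sh, comparison = comparison,
         fractions = data.frame(depth_smfp = s1$depth_smfp,
                                frac_ss = cls$frac_ss,
                                frac_ms1 = cls$frac_ms1,
                                frac_ms2 = cls$frac_ms2,
                                gain = gain))
  })
  structure(list(comparison = do.call(rbind, lapply(per_depth, `[[`, "comparison")),
                 fractions = do.call(rbind, lapply(per_depth, `[[`, "fractions")),
                 per_depth = per_depth, config = config),
            class = "protocol_report")
}

#' @export
print.protocol_report <- function(x, ...) {
  cat("Three-step shaping protocol report\n")
  cat(sprintf("  profile '%s', seed %d, target %s\n", x$config$profile,
              x$config$seed, x$config$target))
  agg <- stats::aggregate(enhancement_em ~ depth_smfp, x$comparison, stats::median)
  for (i in seq_len(nrow(x$fractions))) {
    f <- x$fractions[i, ]
    cat(sprintf(paste0("  depth %5.1f SMFP: ss %6.2f%% | ms1 %6.2f%% | ms2 %6.2f%%",
                       " | median E_m enhancement %.2f\n"),
                f$depth_smfp, f$frac_ss, f$frac_ms1, f$frac_ms2,
                agg$enhancement_em[agg$depth_smfp == f$depth_smfp]))
  }
  invisible(x)
}

#' Run the full three-step protocol
#'
#' Convenience wrapper: [run_step1()], [run_step2()] (all targets),
#' [run_step3()].
#'
#' @param config An [experiment_config()].
#' @return The [run_step3()] report, with `step1` and `step2` attached.
#' @export
run_protocol <- function(config) {
  s1 <- run_step1(config)
  s2 <- run_step2(s1)
  rep_ <- run_step3(s1, s2)
  rep_$step1 <- s1
  rep_$step2 <- s2
  rep_
}

#' Read/write an experiment configuration as YAML
#'
#' @param path File path.
#' @param config An [experiment_config()].
#' @return `read_experiment_config` returns an [experiment_config()].
#' @export
write_experiment_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for config serialization", call. = FALSE)
  keep <- c("profile", "depths", "smfp", "target", "disk_period", "disk_offset",
            "disk_radius", "noise_sd", "probe_frac", "threshold",
            "focus_radius", "seed")
  x <- config[keep]
  x$n_px <- config$grid$n
  x$fov <- config$scan$fov
  x$wavelength <- config$grid$wavelength
  x$n_scan <- config$scan$n_side
  x$probes <- apply(config$probes, 1, paste, collapse = ",")
  x$lambda <- if (identical(config$lambda, "auto")) "auto" else config$lambda
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for config serialization", call. = FALSE)
  x <- yaml::read_yaml(path)
  probes <- do.call(rbind, lapply(x$probes, function(p)
    as.integer(strsplit(p, ",")[[1]])))
  experiment_config(profile = x$profile, depths = as.numeric(x$depths),
                    smfp = x$smfp, target = x$target,
                    disk_radius = x$disk_radius, noise_sd = x$noise_sd,
                    probe_frac = x$probe_frac,
                    lambda = if (identical(x$lambda, "auto")) "auto" else as.numeric(x$lambda),
                    threshold = if (identical(x$threshold, "mp")) "mp" else as.numeric(x$threshold),
                    focus_radius = x$focus_radius, seed = x$seed,
                    n_px = x$n_px, n_scan = x$n_scan, probes = probes,
                    disk_period = x$disk_period, disk_offset = x$disk_offset,
                    wavelength = x$wavelength, fov = x$fov)
}
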