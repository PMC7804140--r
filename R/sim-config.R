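#' Simulation configuration for synthetic islet acquisitions
#'
#' Builds and validates the configuration driving [generate_experiment()].
#' The simulator emulates a tiled, burst-captured 12-bit fluorescence
#' time-lapse of a pancreas (or a single-field islet culture): islets are
#' disks of intensity proportional to their remaining fluorescent content,
#' composited over a smooth autofluorescence background, with rigid stage
#' jitter, motion-blur-corrupted burst frames, Poisson-Gaussian camera noise
#' and 12-bit quantization.
#'
#' @param pixel_size_um Length of one pixel side, micrometers (default 0.54).
#' @param tile_grid Integer vector `c(rows, cols)` of the stage tiling.
#' @param tile_shape_px Integer vector `c(height, width)` of one field.
#' @param overlap_fraction Fraction of tile extent shared with the next tile,
#'   in `[0, 1)`.
#' @param burst_size Frames captured in rapid succession at each field and
#'   time point; one is later selected for analysis.
#' @param burst_interval_ms Time between burst frames (metadata only).
#' @param cadence_min Minutes between time points.
#' @param n_islets Number of islets to place.
#' @param diameter_range_um Truncation range for islet diameters.
#' @param diameter_meanlog,diameter_sdlog Parameters of the log-normal
#'   diameter distribution (right-skewed, the accepted shape for islet size).
#' @param diameters_um Optional explicit diameters, bypassing the log-normal
#'   draw (length must equal `n_islets`).
#' @param phase_schedule Data frame with columns `phase`, `duration_min`,
#'   `release_fraction`: each phase releases the given fraction of the
#'   content held at phase start, spread multiplicatively over its imaging
#'   intervals.  Durations must be positive multiples of `cadence_min`.
#' @param response_regime `"homogeneous"` (every islet releases the phase
#'   fraction) or `"heterogeneous"` (per-islet fractions drawn from a
#'   mixture of a barely-secreting component and a responsive Beta
#'   component, independent of size and position; the mixture weight is set
#'   so the expected fraction equals `release_fraction`).
#' @param responsive_beta,basal_beta Beta shape pairs for the responsive and
#'   barely-secreting mixture components of the heterogeneous regime.
#' @param depth_attenuation_range Per-islet multiplicative attenuation of
#'   fluorescence by overlying tissue, drawn uniformly from this range.
#' @param intensity_density_range Baseline fluorophore density per pixel
#'   (arbitrary 12-bit units), drawn uniformly per islet.
#' @param background_mean,background_amplitude Mean level and amplitude of
#'   the smooth low-frequency background field.
#' @param background_texture_amplitude,background_texture_scale_px Amplitude
#'   and correlation scale of the static mid-frequency tissue texture.
#' @param background_fine_amplitude,background_fine_scale_px Amplitude and
#'   correlation scale of the static cellular-scale texture; together with
#'   the mid-frequency component it gives tile registration the same
#'   multi-scale autofluorescence structure real tissue provides.
#' @param background_scale_px Correlation scale of the smooth background.
#' @param jitter_sigma_px SD of the rigid integer-pixel translation applied
#'   independently per time point and tile (stage/tissue motion).
#' @param blur_frame_prob Probability that a burst frame is corrupted by
#'   directional motion blur (breathing).
#' @param blur_length_px Range of the motion-blur kernel length.
#' @param noise_gaussian_sd SD of the additive Gaussian read noise.
#' @param shot_noise If `TRUE`, add shot noise with variance equal to the
#'   pixel mean (normal approximation of the Poisson term, accurate at the
#'   simulated count levels).
#' @param soft_edge If `TRUE`, islet disks are drawn with a 1-px
#'   anti-aliased edge ramp.
#' @param min_separation_px Minimum gap between islet disk rims at
#'   placement.
#' @param edge_placement_margin_px Extra clearance (beyond the radius)
#'   between islet centers and the nominal mosaic border, so simulated
#'   islets are interior objects.
#' @param max_placement_attempts Rejection-sampling budget per islet before
#'   a placement error is raised.
#' @param bit_depth Bits per pixel; emitted values are integers in
#'   `[0, 2^bit_depth - 1]`.
#' @param rng_seed Integer seed; identical config + seed gives bit-identical
#'   output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [sim_preset()], [generate_experiment()]
#' @export
sim_config <- function(pixel_size_um = 0.54,
                       tile_grid = c(2L, 3L),
                       tile_shape_px = c(512L, 640L),
                       overlap_fraction = 0.15,
                       burst_size = 5L,
                       burst_interval_ms = 250,
                       cadence_min = 5,
                       n_islets = 80L,
                       diameter_range_um = c(10, 300),
                       diameter_meanlog = log(25),
                       diameter_sdlog = 0.35,
                       diameters_um = NULL,
                       phase_schedule = data.frame(
                         phase = "high",
                         duration_min = 15,
                         release_fraction = 0.08
                       ),
                       response_regime = c("homogeneous", "heterogeneous"),
                       responsive_beta = c(2, 8),
                       basal_beta = c(1, 99),
                       depth_attenuation_range = c(1, 1),
                       intensity_density_range = c(2400, 3400),
                       background_mean = 20,
                       background_amplitude = 10,
                       background_texture_amplitude = 10,
                       background_fine_amplitude = 12,
                       background_scale_px = 160,
                       background_texture_scale_px = 16,
                       background_fine_scale_px = 3,
                       jitter_sigma_px = 0,
                       blur_frame_prob = 0,
                       blur_length_px = c(5, 15),
                       noise_gaussian_sd = 3,
                       shot_noise = TRUE,
                       soft_edge = TRUE,
                       min_separation_px = 40,
                       edge_placement_margin_px = 30,
                       max_placement_attempts = 5000L,
                       bit_depth = 12L,
                       rng_seed = 1L) {
  response_regime <- match.arg(response_regime)
  cfg <- list(
    pixel_size_um = pixel_size_um,
    tile_grid = as.integer(tile_grid),
    tile_shape_px = as.integer(tile_shape_px),
    overlap_fraction = overlap_fraction,
    burst_size = as.integer(burst_size),
    burst_interval_ms = burst_interval_ms,
    cadence_min = cadence_min,
    n_islets = as.integer(n_islets),
    diameter_range_um = diameter_range_um,
    diameter_meanlog = diameter_meanlog,
    diameter_sdlog = diameter_sdlog,
    diameters_um = diameters_um,
    phase_schedule = phase_schedule,
    response_regime = response_regime,
    responsive_beta = responsive_beta,
    basal_beta = basal_beta,
    depth_attenuation_range = depth_attenuation_range,
    intensity_density_range = intensity_density_range,
    background_mean = background_mean,
    background_amplitude = background_amplitude,
    background_texture_amplitude = background_texture_amplitude,
    background_fine_amplitude = background_fine_amplitude,
    background_scale_px = background_scale_px,
    background_texture_scale_px = background_texture_scale_px,
    background_fine_scale_px = background_fine_scale_px,
    jitter_sigma_px = jitter_sigma_px,
    blur_frame_prob = blur_frame_prob,
    blur_length_px = blur_length_px,
    noise_gaussian_sd = noise_gaussian_sd,
    shot_noise = isTRUE(shot_noise),
    soft_edge = isTRUE(soft_edge),
    min_separation_px = min_separation_px,
    edge_placement_margin_px = edge_placement_margin_px,
    max_placement_attempts = as.integer(max_placement_attempts),
    bit_depth = as.integer(bit_depth),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    "pixel_size_um must be positive" = cfg$pixel_size_um > 0,
    "tile_grid must be >= 1x1" =
      length(cfg$tile_grid) == 2 && all(cfg$tile_grid >= 1L),
    "tile_shape_px must be >= 32 in each dimension" =
      length(cfg$tile_shape_px) == 2 && all(cfg$tile_shape_px >= 32L),
    "overlap_fraction must be in [0, 1)" =
      cfg$overlap_fraction >= 0 && cfg$overlap_fraction < 1,
    "burst_size must be >= 1" = cfg$burst_size >= 1L,
    "cadence_min must be positive" = cfg$cadence_min > 0,
    "n_islets must be >= 0" = cfg$n_islets >= 0L,
    "bit_depth must be in 8..16" =
      cfg$bit_depth >= 8L && cfg$bit_depth <= 16L
  )
  ph <- cfg$phase_schedule
  stopifnot(
    "phase_schedule needs columns phase, duration_min, release_fraction" =
      all(c("phase", "duration_min", "release_fraction") %in% names(ph)),
    "phase durations must be positive" = all(ph$duration_min > 0),
    "phase durations must be multiples of cadence_min" =
      all(abs(ph$duration_min / cfg$cadence_min -
                round(ph$duration_min / cfg$cadence_min)) < 1e-9),
    "release fractions must be in [0, 1]" =
      all(ph$release_fraction >= 0 & ph$release_fraction <= 1)
  )
  if (!is.null(cfg$diameters_um)) {
    stopifnot(
      "diameters_um must have length n_islets" =
        length(cfg$diameters_um) == cfg$n_islets,
      "diameters_um must be positive" = all(cfg$diameters_um > 0)
    )
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  g <- x$tile_grid
  cat(sprintf(
    "<sim_config> %d islet(s), %dx%d tiles of %dx%d px (%.0f%% overlap), burst %d\n",
    x$n_islets, g[1], g[2], x$tile_shape_px[1], x$tile_shape_px[2],
    100 * x$overlap_fraction, x$burst_size
  ))
  cat(sprintf(
    "  %s regime; phases: %s\n", x$response_regime,
    paste(sprintf("%s(%gmin, f=%.4g)", x$phase_schedule$phase,
                  x$phase_schedule$duration_min,
                  x$phase_schedule$release_fraction), collapse = " -> ")
  ))
  invisible(x)
}

#' Preset simulation configurations
#'
#' Canned configurations mirroring the reference experiments:
#' \describe{
#'   \item{`invitro_gsis`}{50 collagen-embedded islets in one field, imaged
#'     every 5 min through low glucose, high glucose (releasing 10% of
#'     content), low glucose, and KCl depolarization (a further release
#'     bringing the cumulative loss to 12.5% of the pre-stimulation value).
#'     Homogeneous response, no motion blur, no depth attenuation.}
#'   \item{`invivo_gsis`}{A 2x3 tiled mosaic of an exteriorized pancreas
#'     under a 15-min glucose challenge.  Heterogeneous per-islet release
#'     fractions with expected whole-field total response of 8%; rigid
#'     stage jitter, 5-frame bursts with motion-blur-corrupted frames, and
#'     per-islet depth attenuation in `[0.4, 1]`.}
#'   \item{`invivo_fullpancreas`}{As `invivo_gsis` but with larger fields
#'     holding 200 well-separated interior islets.}
#'   \item{`stability`}{Unstimulated islets imaged for 45 min; all release
#'     fractions are 0, so traces should stay at 100%.}
#' }
#'
#' @param name Preset name.
#' @param phases Optional integer vector selecting a leading subset of the
#'   preset's phases (e.g. `1:2` to simulate only through the high-glucose
#'   challenge).
#' @param ... Overrides passed on to [sim_config()] (e.g. `rng_seed`).
#' @return A `sim_config`.
#' @export
sim_preset <- function(name = c("invitro_gsis", "invivo_gsis",
                                "invivo_fullpancreas", "stability"),
                       phases = NULL, ...) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("invitro_gsis", "invivo_gsis",
                   "invivo_fullpancreas", "stability")) {
    stop("unknown preset name: ", paste(name, collapse = ", "), call. = FALSE)
  }
  # KCl fraction chosen so the cumulative four-phase loss is exactly 12.5%
  # of the pre-stimulation content: 1 - 0.9 * (1 - f) = 0.125.
  kcl_fraction <- 1 - 0.875 / 0.9
  args <- switch(name,
    invitro_gsis = list(
      tile_grid = c(1L, 1L),
      tile_shape_px = c(800L, 960L),
      burst_size = 1L,
      n_islets = 50L,
      diameter_meanlog = log(25),
      diameter_sdlog = 0.3,
      diameter_range_um = c(20, 300),
      phase_schedule = data.frame(
        phase = c("low", "high", "low", "kcl"),
        duration_min = c(15, 15, 15, 15),
        release_fraction = c(0, 0.10, 0, kcl_fraction)
      ),
      response_regime = "homogeneous",
      depth_attenuation_range = c(1, 1),
      jitter_sigma_px = 0,
      blur_frame_prob = 0
    ),
    stability = list(
      tile_grid = c(1L, 1L),
      tile_shape_px = c(800L, 960L),
      burst_size = 1L,
      n_islets = 50L,
      diameter_meanlog = log(25),
      diameter_sdlog = 0.3,
      diameter_range_um = c(20, 300),
      phase_schedule = data.frame(
        phase = "low",
        duration_min = 45,
        release_fraction = 0
      ),
      response_regime = "homogeneous",
      depth_attenuation_range = c(1, 1),
      jitter_sigma_px = 0,
      blur_frame_prob = 0
    ),
    invivo_gsis = list(
      tile_grid = c(2L, 3L),
      tile_shape_px = c(512L, 640L),
      burst_size = 5L,
      n_islets = 80L,
      diameter_meanlog = log(25),
      diameter_sdlog = 0.35,
      diameter_range_um = c(10, 150),
      phase_schedule = data.frame(
        phase = "high",
        duration_min = 15,
        release_fraction = 0.08
      ),
      response_regime = "heterogeneous",
      depth_attenuation_range = c(0.4, 1),
      jitter_sigma_px = 2,
      blur_frame_prob = 0.3
    ),
    invivo_fullpancreas = list(
      tile_grid = c(2L, 3L),
      tile_shape_px = c(1100L, 1344L),
      burst_size = 5L,
      n_islets = 200L,
      diameter_meanlog = log(25),
      diameter_sdlog = 0.35,
      diameter_range_um = c(15, 150),
      phase_schedule = data.frame(
        phase = "high",
        duration_min = 15,
        release_fraction = 0.08
      ),
      response_regime = "heterogeneous",
      depth_attenuation_range = c(0.4, 1),
      jitter_sigma_px = 2,
      blur_frame_prob = 0.3
    )
  )
  if (!is.null(phases)) {
    ph <- args$phase_schedule
    stopifnot("phases must select a leading subset" =
                all(phases == seq_along(phases)) && max(phases) <= nrow(ph))
    args$phase_schedule <- ph[phases, , drop = FALSE]
  }
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# Time points (minutes) implied by a config's phase schedule: imaging starts
# at t = 0 and repeats every cadence_min through the end of the last phase.
sim_time_points <- function(cfg) {
  seq(0, sum(cfg$phase_schedule$duration_min), by = cfg$cadence_min)
}

# Phase index covering the step (t_k, t_{k+1}]; steps never straddle a
# boundary because durations are multiples of the cadence.
sim_step_phase <- function(cfg) {
  tp <- sim_time_points(cfg)
  ends <- cumsum(cfg$phase_schedule$duration_min)
  vapply(tp[-1], function(t) which(t <= ends + 1e-9)[1], integer(1))
}
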