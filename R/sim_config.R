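#' Configuration for the synthetic amoeboid-cell motility simulator
#'
#' Bundles the acquisition geometry and motion/shape model parameters used by
#' [simulate_shape_series()], [simulate_track()] and [rasterize_movie()].
#' Defaults mirror the study design the pipeline targets: 60 frames at 20-s
#' intervals (20 min of imaging) with a 40x-objective pixel size of
#' 0.25 um/px.
#'
#' The motion model is a persistent random walk whose frame-to-frame step
#' length is fixed at `mean_speed_um_per_min` times the frame interval, so the
#' programmed instantaneous speed is exact. The shape model is a radial
#' Fourier contour `r(theta, t) = base_radius * (1 + sum_k a_k(t) cos(k theta
#' + phi_k))` whose mode amplitudes follow an Ornstein-Uhlenbeck process with
#' stationary scale `protrusion_amplitude / k` and relaxation rate
#' `protrusion_rate_per_min`.
#'
#' @param n_cells number of cells to simulate.
#' @param n_frames number of frames (>= 2).
#' @param frame_interval_s frame interval in seconds (> 0).
#' @param pixel_size_um pixel size in micrometers per pixel.
#' @param field_size_px integer vector `(height, width)` of the field raster.
#' @param mean_speed_um_per_min programmed crawling speed, um/min.
#' @param persistence directional correlation of successive headings, in
#'   [0, 1]; 1 gives ballistic (collinear) motion, 0 gives uncorrelated
#'   headings.
#' @param protrusion_amplitude dimensionless radial shape-noise scale (>= 0);
#'   0 gives a perfect circle at every frame.
#' @param protrusion_rate_per_min relaxation rate of the protrusion process,
#'   1/min.
#' @param base_radius_um resting cell radius, micrometers (> 0).
#' @param n_fourier_modes number of radial Fourier modes.
#' @param seed integer root seed; identical config + seed gives bit-identical
#'   output.
#' @return an object of class `motility_sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- motility_sim_config(n_cells = 2, mean_speed_um_per_min = 1,
#'                            persistence = 0.6, seed = 1)
#' cfg$n_frames
motility_sim_config <- function(n_cells,
                                n_frames = 60L,
                                frame_interval_s = 20,
                                pixel_size_um = 0.25,
                                field_size_px = c(512L, 512L),
                                mean_speed_um_per_min = 1,
                                persistence = 0.5,
                                protrusion_amplitude = 0.2,
                                protrusion_rate_per_min = 2,
                                base_radius_um = 5,
                                n_fourier_modes = 6L,
                                seed = 1L) {
  assert_scalar_number(n_cells, "n_cells", min = 1)
  assert_scalar_number(n_frames, "n_frames", min = 2)
  assert_scalar_number(frame_interval_s, "frame_interval_s", min = 0,
                       strict_min = TRUE)
  assert_scalar_number(pixel_size_um, "pixel_size_um", min = 0,
                       strict_min = TRUE)
  if (length(field_size_px) != 2L || any(field_size_px < 8))
    stopf("'field_size_px' must be (height, width), each >= 8")
  assert_scalar_number(mean_speed_um_per_min, "mean_speed_um_per_min", min = 0)
  assert_scalar_number(persistence, "persistence", min = 0, max = 1)
  assert_scalar_number(protrusion_amplitude, "protrusion_amplitude", min = 0)
  assert_scalar_number(protrusion_rate_per_min, "protrusion_rate_per_min",
                       min = 0, strict_min = TRUE)
  assert_scalar_number(base_radius_um, "base_radius_um", min = 0,
                       strict_min = TRUE)
  assert_scalar_number(n_fourier_modes, "n_fourier_modes", min = 1)
  assert_scalar_number(seed, "seed")
  structure(list(
    n_cells = as.integer(n_cells),
    n_frames = as.integer(n_frames),
    frame_interval_s = frame_interval_s,
    pixel_size_um = pixel_size_um,
    field_size_px = as.integer(field_size_px),
    mean_speed_um_per_min = mean_speed_um_per_min,
    persistence = persistence,
    protrusion_amplitude = protrusion_amplitude,
    protrusion_rate_per_min = protrusion_rate_per_min,
    base_radius_um = base_radius_um,
    n_fourier_modes = as.integer(n_fourier_modes),
    seed = as.integer(seed)
  ), class = "motility_sim_config")
}

#' @export
print.motility_sim_config <- function(x, ...) {
  cat("<motility_sim_config>\n")
  cat(sprintf("  %d cells, %d frames @ %g s (%g min total)\n",
              x$n_cells, x$n_frames, x$frame_interval_s,
              x$n_frames * x$frame_interval_s / 60))
  cat(sprintf("  speed %g um/min, persistence %g, protrusion %g (rate %g/min)\n",
              x$mean_speed_um_per_min, x$persistence,
              x$protrusion_amplitude, x$protrusion_rate_per_min))
  cat(sprintf("  radius %g um, %d Fourier modes, %g um/px, field %dx%d, seed %d\n",
              x$base_radius_um, x$n_fourier_modes, x$pixel_size_um,
              x$field_size_px[1], x$field_size_px[2], x$seed))
  invisible(x)
}
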