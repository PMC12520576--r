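#' Synthetic scene configuration
#'
#' Describes one synthetic high-speed acquisition: the jet run and fluid, the
#' virtual optics, and the stochastic ingredients of the beads-on-a-string
#' breakup model. Defaults reproduce the experimental imaging geometry
#' (12,000 frames/s, 8.5 um/pixel, 2000 frames, nozzle 6 mm upstream of the
#' field of view) and a moderately noisy bright-field rendering.
#'
#' @param run a [jet_run()]; default forces at 1000 Hz
#' @param fluid a [fluid_properties()] for the effective compound jet
#' @param pixel_pitch_um spatial sampling, um/pixel (default 8.5)
#' @param frame_rate_hz frames per second (default 12000)
#' @param frame_rows,frame_cols frame shape; the jet axis runs along columns,
#'   flow left to right (defaults 294 x 1000)
#' @param nozzle_offset_mm axial distance from the nozzle exit to the left
#'   frame edge (default 6 mm)
#' @param n_frames frames per acquisition (default 2000)
#' @param noise_sd additive Gaussian noise SD in 8-bit grey levels (default 5)
#' @param blur_sd_px Gaussian optical blur SD in pixels (default 1)
#' @param satellite_probability Bernoulli probability that a primary bead
#'   spawns a satellite (default 0.1)
#' @param satellite_radius_fraction satellite radius as a fraction of its
#'   primary's (default 0.3)
#' @param wavelength_jitter_sd multiplicative SD of the forced breakup
#'   wavelength (default 0.03)
#' @param velocity_jitter_sd multiplicative SD of per-bead initial velocity,
#'   emulating pump-flow fluctuations (default 0.05)
#' @param relaxation_time_ms time constant of the exponential bead
#'   deceleration from v_jet toward the capillary-retarded velocity
#'   (default 1.5 ms)
#' @param filament_life_factor the trailing filament of a bead pinches at
#'   `filament_life_factor` relaxation times after detachment, defining the
#'   bead's breakup time T_b (default 3)
#' @param filament_ratio jet-to-filament radius ratio (default 10)
#' @param deflection_um transverse deflection scale applied to beads when the
#'   potential exceeds the filament whipping threshold (default 100 um)
#' @param axis_tilt_deg in-plane tilt of the jet axis (default 0)
#' @param gain log-amplification constant of the spatial growth model; see
#'   [spatial_growth_rate()]
#' @param background,foreground 8-bit grey levels of the rendered scene
#'   before blur and noise (defaults 220 and 30, transmission imaging)
#' @param filament_grey grey level of the thin connecting filaments (default
#'   150: at one-pixel scale the filament absorbs far less light than jet or
#'   beads, so it shows in kymographs but stays above the jet/background
#'   binarization threshold)
#' @param seed master integer seed; every stochastic stage derives its own
#'   sub-stream from it
#' @return a list of class `scene_config`
#' @examples
#' scene_config(run = jet_run(frequency_hz = 1400), n_frames = 200)
#' @export
scene_config <- function(run = jet_run(frequency_hz = 1000),
                         fluid = compound_fluid(),
                         pixel_pitch_um = 8.5,
                         frame_rate_hz = 12000,
                         frame_rows = 294, frame_cols = 1000,
                         nozzle_offset_mm = 6,
                         n_frames = 2000,
                         noise_sd = 5, blur_sd_px = 1,
                         satellite_probability = 0.1,
                         satellite_radius_fraction = 0.3,
                         wavelength_jitter_sd = 0.03,
                         velocity_jitter_sd = 0.05,
                         relaxation_time_ms = 1.5,
                         filament_life_factor = 3,
                         filament_ratio = 10,
                         deflection_um = 100,
                         axis_tilt_deg = 0,
                         gain = 7,
                         background = 220, foreground = 30,
                         filament_grey = 150,
                         seed = 1) {
  stopifnot(inherits(run, "jet_run"), inherits(fluid, "fluid_properties"))
  if (pixel_pitch_um <= 0 || frame_rate_hz <= 0)
    abort("pixel pitch and frame rate must be > 0", class = "capsulejet_invalid_configuration")
  for (p in c(satellite_probability))
    if (p < 0 || p > 1) abort("probabilities must lie in [0, 1]",
                              class = "capsulejet_invalid_configuration")
  if (satellite_radius_fraction < 0 || satellite_radius_fraction >= 1)
    abort("`satellite_radius_fraction` must lie in [0, 1)",
          class = "capsulejet_invalid_configuration")
  structure(
    list(
      run = run, fluid = fluid,
      pixel_pitch = um_to_m(pixel_pitch_um),
      frame_rate = frame_rate_hz,
      frame_rows = as.integer(frame_rows), frame_cols = as.integer(frame_cols),
      nozzle_offset = mm_to_m(nozzle_offset_mm),
      n_frames = as.integer(n_frames),
      noise_sd = noise_sd, blur_sd = blur_sd_px,
      satellite_probability = satellite_probability,
      satellite_radius_fraction = satellite_radius_fraction,
      wavelength_jitter_sd = wavelength_jitter_sd,
      velocity_jitter_sd = velocity_jitter_sd,
      relaxation_time = relaxation_time_ms * 1e-3,
      filament_life_factor = filament_life_factor,
      filament_ratio = filament_ratio,
      deflection = um_to_m(deflection_um),
      axis_tilt_deg = axis_tilt_deg,
      gain = gain,
      background = background, foreground = foreground,
      filament_grey = filament_grey,
      seed = as.integer(seed)
    ),
    class = "scene_config"
  )
}

#' @export
print.scene_config <- function(x, ...) {
  cat("<scene_config>\n")
  cat(sprintf("  %d frames of %dx%d px at %g fps, %g um/px, nozzle offset %g mm\n",
              x$n_frames, x$frame_rows, x$frame_cols, x$frame_rate,
              m_to_um(x$pixel_pitch), m_to_mm(x$nozzle_offset)))
  cat(sprintf("  f = %g Hz, U = %g V, fluid '%s', seed %d\n",
              x$run$frequency, x$run$potential, x$fluid$label, x$seed))
  invisible(x)
}

#' Predicted fragmentation length of a scene
#'
#' L_frag = gain / sigma with sigma = omega(k)/v_jet the spatial growth rate
#' of the forced mode (or of the fastest mode when f = 0).
#'
#' @param scene a [scene_config()]
#' @return fragmentation length in m
#' @export
predict_fragmentation_length <- function(scene) {
  stopifnot(inherits(scene, "scene_config"))
  v <- jet_velocity(scene$run)
  if (scene$run$frequency > 0) {
    k <- 2 * pi * scene$run$frequency / v
    if (k * scene$run$jet_radius >= 1)
      abort("forcing frequency outside the unstable band",
            class = "capsulejet_invalid_configuration")
    om <- weber_growth_rate(k, scene$fluid, scene$run$jet_radius)
  } else {
    om <- fastest_growing_mode(scene$fluid, scene$run$jet_radius)$omega_star_per_s
  }
  if (om <= 0) abort("forced mode is stable; jet does not break",
                     class = "capsulejet_invalid_configuration")
  scene$gain * v / om
}

#' Position the virtual camera around the breakup point
#'
#' Adjusts `nozzle_offset` so the predicted fragmentation length sits
#' `margin_mm` into the field of view, as an experimentalist would reposition
#' the camera when the breakup point moves with (f, U).
#'
#' @param scene a [scene_config()]
#' @param margin_mm distance from the left frame edge to the predicted
#'   breakup point (default 2 mm)
#' @return the scene with an updated `nozzle_offset`
#' @export
scene_autoposition <- function(scene, margin_mm = 2) {
  lf <- predict_fragmentation_length(scene)
  scene$nozzle_offset <- max(0, lf - mm_to_m(margin_mm))
  scene
}

# Hash a scene config for provenance stamping.
scene_hash <- function(scene) {
  flat <- unlist(scene, use.names = TRUE)
  s <- paste(names(flat), format(flat, digits = 12), collapse = ";")
  iv <- utf8ToInt(s)
  sprintf("%08x", sum(iv * (seq_along(iv) %% 97 + 1)) %% 4294967296)
}
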