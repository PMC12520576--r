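# Known run-config keys with their defaults (bench units are suffixed in the
# key names to keep units explicit at the file boundary).
run_config_defaults <- function() list(
  input_stack = NA_character_,
  output_dir = "capsulejet-out",
  nozzle_radius_um = 95,
  q_cs_mlh = 45, q_is_mlh = 45, q_as_mlh = 75,
  frequency_hz = 1000, potential_v = 0,
  pixel_pitch_um = 8.5, frame_rate_hz = 12000,
  frame_rows = 294, frame_cols = 1000,
  nozzle_offset_mm = 6, n_frames = 2000,
  fluid_density_kg_m3 = 1000, fluid_surface_tension_mn_m = 59.8,
  fluid_viscosity_mpa_s = 30,
  noise_sd = 5, blur_sd_px = 1,
  satellite_probability = 0.1, satellite_radius_fraction = 0.3,
  wavelength_jitter_sd = 0.03, velocity_jitter_sd = 0.05,
  axis_tilt_deg = 0,
  roi_span_um = 1500, roi_offset_um = 1500,
  radius_window = 0.5, frame_stride = 4,
  selectivity_tolerance = 0.10, gain = 7,
  autoposition = TRUE,
  seed = 1
)

#' Read / write a run configuration
#'
#' Flat, typed key-value configuration (YAML) with units suffixed in the key
#' names (e.g. `nozzle_radius_um`, `q_cs_mlh`). Unknown keys are rejected.
#'
#' @param path config file path
#' @return `read_run_config()`: a named list of class `run_config` with all
#'   defaults filled in
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    abort(sprintf("config file not found: %s", path), class = "capsulejet_config_error")
  vals <- yaml::read_yaml(path)
  as_run_config(vals)
}

#' @rdname read_run_config
#' @param config a named list of overrides (see [run_config_defaults()])
#' @export
as_run_config <- function(config = list()) {
  defaults <- run_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "capsulejet_config_error")
  structure(modifyList(defaults, config), class = "run_config")
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Build scene_config from a run_config.
config_to_scene <- function(cfg) {
  run <- jet_run(nozzle_radius_um = cfg$nozzle_radius_um,
                 q_cs_mlh = cfg$q_cs_mlh, q_is_mlh = cfg$q_is_mlh,
                 q_as_mlh = cfg$q_as_mlh,
                 frequency_hz = cfg$frequency_hz, potential_v = cfg$potential_v)
  fluid <- fluid_properties(cfg$fluid_density_kg_m3,
                            cfg$fluid_surface_tension_mn_m * 1e-3,
                            cfg$fluid_viscosity_mpa_s * 1e-3,
                            "config fluid")
  scene <- scene_config(
    run = run, fluid = fluid,
    pixel_pitch_um = cfg$pixel_pitch_um, frame_rate_hz = cfg$frame_rate_hz,
    frame_rows = cfg$frame_rows, frame_cols = cfg$frame_cols,
    nozzle_offset_mm = cfg$nozzle_offset_mm, n_frames = cfg$n_frames,
    noise_sd = cfg$noise_sd, blur_sd_px = cfg$blur_sd_px,
    satellite_probability = cfg$satellite_probability,
    satellite_radius_fraction = cfg$satellite_radius_fraction,
    wavelength_jitter_sd = cfg$wavelength_jitter_sd,
    velocity_jitter_sd = cfg$velocity_jitter_sd,
    axis_tilt_deg = cfg$axis_tilt_deg, gain = cfg$gain, seed = cfg$seed
  )
  if (isTRUE(cfg$autoposition)) scene <- scene_autoposition(scene) else scene
}

#' Simulate a synthetic acquisition to disk
#'
#' Generates the ground-truthed frame stack for the configured scene and
#' writes `<output_dir>/stack.tif` (+ JSON sidecar) and
#' `<output_dir>/truth.csv` (+ events CSV). Deterministic for a fixed
#' config + seed.
#'
#' @param config a `run_config` (or list of overrides)
#' @return invisibly, a list with `stack_path`, `truth_path`, `truth`,
#'   `scene`
#' @export
simulate_run <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else as_run_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  scene <- config_to_scene(cfg)
  sim <- simulate_scene(scene)
  stack_path <- file.path(cfg$output_dir, "stack.tif")
  truth_path <- file.path(cfg$output_dir, "truth.csv")
  write_frames(sim$frames, stack_path)
  write_truth(sim$truth, truth_path)
  invisible(list(stack_path = stack_path, truth_path = truth_path,
                 truth = sim$truth, scene = scene))
}

#' Analyse an acquisition
#'
#' Runs the full analysis chain on a frame stack: axis alignment,
#' fragmentation length, droplet detection (Canny + circular Hough in a
#' physics-positioned ROI), bead tracking and population statistics, writing
#' `detections.csv`, `tracks.csv` and `report.json` under the configured
#' output directory.
#'
#' @param config a `run_config` (or list of overrides); `input_stack` may
#'   point at a TIFF written by [simulate_run()]
#' @param stack optionally, an in-memory [frame_stack()] (skips reading
#'   `input_stack`)
#' @return a list of class `run_report`: headline numbers (`l_frag_mm`,
#'   `n_events`, `modal_radius_um`, `selectivity`, `r_th_um`,
#'   `n_detections`, `n_coalescence_tracks`), stage outputs (`detections`,
#'   `tracks`, `fragmentation`), output paths, config hash and warnings
#' @export
analyze_run <- function(config = list(), stack = NULL) {
  cfg <- if (inherits(config, "run_config")) config else as_run_config(config)
  if (is.null(stack)) {
    if (is.na(cfg$input_stack))
      abort("no `input_stack` in config and no in-memory stack supplied",
            class = "capsulejet_config_error")
    if (!file.exists(cfg$input_stack))
      abort(sprintf("input stack not found: %s", cfg$input_stack),
            class = "capsulejet_data_error")
    stack <- read_frames(cfg$input_stack)
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  run <- jet_run(nozzle_radius_um = cfg$nozzle_radius_um,
                 q_cs_mlh = cfg$q_cs_mlh, q_is_mlh = cfg$q_is_mlh,
                 q_as_mlh = cfg$q_as_mlh,
                 frequency_hz = cfg$frequency_hz, potential_v = cfg$potential_v)
  warnings <- character(0)

  aligned <- withCallingHandlers(
    align_jet_axis(stack),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  frag <- withCallingHandlers(
    fragmentation_length(aligned$stack),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w)); invokeRestart("muffleWarning")
    })

  r_th <- targeted_radius(cfg$frequency_hz, run)
  detections <- detect_droplets(
    aligned$stack, frag$l_frag_m, r_expected_um = r_th,
    roi_span_m = um_to_m(cfg$roi_span_um),
    roi_offset_m = um_to_m(cfg$roi_offset_um),
    radius_window = cfg$radius_window, frame_stride = cfg$frame_stride)

  beads <- detect_beads(aligned$stack, frag$jet_end)
  tracks <- track_beads(beads, stack$frame_rate, v_expected = jet_velocity(run))

  radii <- detections$r_um
  modal <- NA_real_
  if (length(radii) >= 30) {
    fit <- fit_mixture(radii, "auto")
    modal <- fit$means[which.max(fit$weights)]
  } else if (length(radii) > 0) modal <- median(radii)
  sel <- if (length(radii) > 0) selectivity(radii, r_th, cfg$selectivity_tolerance)$s
         else NA_real_
  n_coal <- if (nrow(tracks) > 0)
    dplyr::n_distinct(tracks$track_id[tracks$termination == "coalescence"])
  else 0L

  det_path <- file.path(cfg$output_dir, "detections.csv")
  trk_path <- file.path(cfg$output_dir, "tracks.csv")
  rep_path <- file.path(cfg$output_dir, "report.json")
  write.csv(detections, det_path, row.names = FALSE)
  write.csv(tracks, trk_path, row.names = FALSE)

  flat <- unlist(unclass(cfg))
  cfg_str <- paste(names(flat), flat, collapse = ";")
  iv <- utf8ToInt(cfg_str)
  cfg_hash <- sprintf("%08x", sum(iv * (seq_along(iv) %% 97 + 1)) %% 4294967296)

  report <- structure(list(
    config_hash = cfg_hash,
    l_frag_mm = m_to_mm(frag$l_frag_m),
    l_frag_sd_mm = m_to_mm(frag$sd_m),
    n_events = frag$n_events,
    axis_angle_deg = aligned$angle_deg,
    r_th_um = r_th,
    modal_radius_um = modal,
    selectivity = sel,
    n_detections = length(radii),
    n_coalescence_tracks = n_coal,
    detections = detections,
    tracks = tracks,
    fragmentation = frag,
    paths = list(detections = det_path, tracks = trk_path, report = rep_path),
    warnings = warnings
  ), class = "run_report")

  jsonlite::write_json(
    report[c("config_hash", "l_frag_mm", "l_frag_sd_mm", "n_events", "axis_angle_deg",
             "r_th_um", "modal_radius_um", "selectivity", "n_detections",
             "n_coalescence_tracks", "warnings")],
    rep_path, auto_unbox = TRUE, digits = NA)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  L_frag = %.3f mm over %d events; axis %.2f deg\n",
              x$l_frag_mm, x$n_events, x$axis_angle_deg))
  cat(sprintf("  %d droplets; modal radius %.1f um (targeted %.1f um); S = %.2f\n",
              x$n_detections, x$modal_radius_um, x$r_th_um, x$selectivity))
  invisible(x)
}

#' Simulate-and-analyse sweep over an (f, U) grid
#'
#' Runs one simulate + analyse cycle per grid point (seeded per point),
#' assembles the results with [assemble_sweep()] and classifies each point in
#' the (kR, Gamma) phase plane. Per-point failures are logged and the sweep
#' continues.
#'
#' @param f_grid_hz,u_grid_v frequency and potential grids
#' @param config base `run_config` overrides applied to every point
#' @param cutoffs a [phase_cutoffs()]
#' @return list: `sweep` (a `sweep_table` with phase labels), `failures`
#'   (named character of per-point errors)
#' @export
sweep_runs <- function(f_grid_hz, u_grid_v, config = list(),
                       cutoffs = phase_cutoffs()) {
  stopifnot(length(f_grid_hz) > 0, length(u_grid_v) > 0)
  grid <- tidyr::expand_grid(f_hz = f_grid_hz, u_v = u_grid_v)
  base <- if (inherits(config, "run_config")) unclass(config) else config
  runs <- list(); failures <- character(0)
  for (i in seq_len(nrow(grid))) {
    f <- grid$f_hz[i]; u <- grid$u_v[i]
    key <- sprintf("f%g_u%g", f, u)
    res <- tryCatch({
      cfg <- as_run_config(modifyList(base, list(
        frequency_hz = f, potential_v = u,
        output_dir = file.path(base$output_dir %||% "capsulejet-out", key),
        seed = (base$seed %||% 1) + i)))
      scene <- config_to_scene(cfg)
      sim <- simulate_scene(scene)
      rep <- analyze_run(cfg, stack = sim$frames)
      list(f_hz = f, u_v = u, l_frag_m = rep$l_frag_mm * 1e-3,
           radii_um = rep$detections$r_um)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) failures[key] <- res else runs[[key]] <- res
  }
  sw <- assemble_sweep(runs, run = jet_run(
    nozzle_radius_um = (base$nozzle_radius_um %||% 95)))
  if (nrow(sw) > 0) {
    run0 <- jet_run(nozzle_radius_um = (base$nozzle_radius_um %||% 95))
    v <- jet_velocity(run0)
    gam <- electric_report(sw$u_v, run0$jet_radius,
                           (base$fluid_surface_tension_mn_m %||% 59.8) * 1e-3)
    sw$kr <- 2 * pi * sw$f_hz / v * run0$jet_radius
    sw$gamma <- gam$bond_number
    sw$region <- classify_phase_point(sw$kr, sw$gamma, cutoffs)
  }
  list(sweep = sw, failures = failures)
}
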