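# Shared synthetic scenes, built once per test run and cached across files.
# Sizes are kept to a few hundred frames so the whole suite stays fast; the
# acceptance tests build their own full-length acquisition.

.scene_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, scene_factory) {
  if (is.null(.scene_cache[[key]])) {
    scene <- scene_factory()
    .scene_cache[[key]] <- c(simulate_scene(scene), list(scene = scene))
  }
  .scene_cache[[key]]
}

# Forced jet at 1000 Hz, no potential: coalescence active.
sim_u0 <- function() cached_sim("u0", function() {
  scene_config(run = jet_run(frequency_hz = 1000), n_frames = 300, seed = 7)
})

# Same forcing above the filament whipping threshold: coalescence suppressed.
sim_whip <- function() cached_sim("whip", function() {
  scene_config(run = jet_run(frequency_hz = 1000, potential_v = 5000),
               n_frames = 200, seed = 3)
})

# Noiseless, blur-only scene for pixel-accurate recovery checks.
sim_clean <- function() cached_sim("clean", function() {
  scene_config(run = jet_run(frequency_hz = 1000), n_frames = 250,
               noise_sd = 0, seed = 5)
})

# Fragmentation result cache (reused by droplet/tracking tests).
cached_frag <- function(key, sim) {
  fkey <- paste0(key, "_frag")
  if (is.null(.scene_cache[[fkey]]))
    .scene_cache[[fkey]] <- fragmentation_length(sim$frames)
  .scene_cache[[fkey]]
}

# Minimal hand-built truth train holding explicit beads (for renderer unit
# tests that need exact geometry).
manual_truth <- function(scene, beads, x_end = -1) {
  structure(
    list(
      beads = beads,
      events = tibble::tibble(time_s = numeric(0), frame = integer(0),
                              id_a = integer(0), id_b = integer(0),
                              new_id = integer(0), x_m = numeric(0)),
      jet = tibble::tibble(frame = 0:(scene$n_frames - 1L),
                           x_end_m = rep(x_end, scene$n_frames)),
      l_frag = max(x_end, 1e-3),
      breakup_period = 1e-3,
      wavelengths = 1e-3,
      whipping = FALSE,
      scene = scene
    ),
    class = "truth_train"
  )
}

bead_row <- function(frame, id, x_m, r_m, y_m = 0, v = 1) {
  tibble::tibble(frame = as.integer(frame), t_s = frame / 12000, id = as.integer(id),
                 x_m = x_m, y_m = y_m, r_m = r_m, v_m_per_s = v,
                 lineage = "primary", n_merged = 1L, filament = FALSE,
                 r_filament_m = 0)
}
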