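# Synthetic beads-on-a-string generator: spectrum, truth train, renderer,
# capsule micrographs, truth serialisation.

test_that("forced spectrum is exact without jitter and seed-reproducible", {
  sc <- scene_config(run = jet_run(frequency_hz = 1000),
                     wavelength_jitter_sd = 0, n_frames = 50, seed = 9)
  lam <- sample_breakup_spectrum(sc)
  v <- 165e-6 / 3600 / (pi * (95e-6)^2)
  expect_true(all(abs(lam - v / 1000) < 1e-15))
  sc2 <- scene_config(run = jet_run(frequency_hz = 1400), n_frames = 50, seed = 4)
  expect_identical(sample_breakup_spectrum(sc2), sample_breakup_spectrum(sc2))
})

test_that("free breakup samples a polydisperse train peaked at the fastest mode", {
  sc0 <- scene_config(run = jet_run(frequency_hz = 0), n_frames = 10, seed = 11)
  lam <- sample_breakup_spectrum(sc0, n = 10000)
  fm <- fastest_growing_mode(compound_fluid(), 95e-6)
  d <- density(lam)
  modal <- d$x[which.max(d$y)]
  expect_equal(modal, 2 * pi / fm$k_star_per_m, tolerance = 0.05)
  expect_gt(sd(lam) / mean(lam), 0.05)   # genuinely polydisperse
})

test_that("truth train conserves volume and logs coalescence correctly", {
  sim <- sim_u0()
  tr <- sim$truth
  run <- sim$scene$run
  # total extruded bead volume per unit time equals Q (volume bookkeeping)
  vol <- sum(pi * run$jet_radius^2 * tr$wavelengths)
  dur <- sum(tr$wavelengths) / (run$total_flow / (pi * run$nozzle_radius^2))
  expect_equal(vol / dur, run$total_flow, tolerance = 0.02)
  # with 5% velocity jitter and no potential, coalescence does occur
  expect_gt(nrow(tr$events), 0)
  # merged radii obey (sum r^3)^(1/3): reconstruct each event from the last
  # appearance of its parents
  b <- tr$beads
  for (i in seq_len(nrow(tr$events))) {
    ev <- tr$events[i, ]
    ra <- utils::tail(b$r_m[b$id == ev$id_a], 1)
    rb <- utils::tail(b$r_m[b$id == ev$id_b], 1)
    rn <- utils::head(b$r_m[b$id == ev$new_id], 1)
    if (length(ra) && length(rb) && length(rn))
      expect_equal(rn, (ra^3 + rb^3)^(1 / 3), tolerance = 1e-9)
  }
  expect_error(build_truth_train(sim$scene, numeric(0)),
               class = "capsulejet_invalid_configuration")
})

test_that("whipping potential suppresses coalescence and deflects beads", {
  sim <- sim_whip()
  expect_equal(nrow(sim$truth$events), 0)
  expect_true(sim$truth$whipping)
  expect_gt(max(abs(sim$truth$beads$y_m)), 0)
  # velocity stays at the (jittered) jet velocity: no capillary retardation
  v <- 165e-6 / 3600 / (pi * (95e-6)^2)
  expect_equal(mean(sim$truth$beads$v_m_per_s), v, tolerance = 0.05)
})

test_that("forced monodisperse scene hits the targeted radius within 0.5%", {
  sc <- scene_config(run = jet_run(frequency_hz = 1000, potential_v = 5000),
                     wavelength_jitter_sd = 0, velocity_jitter_sd = 0,
                     satellite_probability = 0, n_frames = 60, seed = 2)
  tr <- build_truth_train(sc)
  r_th <- targeted_radius(1000, sc$run)
  expect_true(all(abs((tr$beads$r_m * 1e6) / r_th - 1) < 0.005))
})

test_that("renderer draws metrically correct scenes", {
  pitch <- 8.5e-6
  sc <- scene_config(run = jet_run(frequency_hz = 1000), n_frames = 1,
                     noise_sd = 0, blur_sd_px = 1, seed = 1)
  # single in-focus bead of radius 23.5 px: disk area within 3% of pi r^2
  x <- sc$nozzle_offset + 500 * pitch
  tr1 <- manual_truth(sc, bead_row(0, 1, x, 23.5 * pitch))
  st1 <- render_frames(tr1, sc)
  area <- sum(fs_frame(st1, 1) < 128)
  expect_equal(area, pi * 23.5^2, tolerance = 0.03)
  # no beads, no jet: uniform background
  tr0 <- manual_truth(sc, bead_row(0, 1, 1e9, 1e-6))
  st0 <- render_frames(tr0, sc)
  expect_true(all(fs_frame(st0, 1) == sc$background))
  # identical seed + config give byte-identical stacks
  sc2 <- scene_config(run = jet_run(frequency_hz = 1200), n_frames = 20, seed = 8)
  a <- render_frames(build_truth_train(sc2), sc2)
  b <- render_frames(build_truth_train(sc2), sc2)
  expect_identical(a$frames, b$frames)
})

test_that("axis tilt is rendered at the requested angle", {
  sc <- scene_config(run = jet_run(frequency_hz = 1000), n_frames = 40,
                     axis_tilt_deg = 2, seed = 5)
  st <- render_frames(build_truth_train(sc), sc)
  expect_equal(estimate_jet_axis(st), 2, tolerance = 0.1)  # within 0.2 deg
})

test_that("truth train round-trips through CSV at full precision", {
  sim <- sim_whip()
  path <- tempfile(fileext = ".csv")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(nrow(back$beads), nrow(sim$truth$beads))
  for (col in c("x_m", "y_m", "r_m", "v_m_per_s"))
    expect_equal(back$beads[[col]], sim$truth$beads[[col]], tolerance = 1e-9)
  expect_identical(back$beads$lineage, sim$truth$beads$lineage)
  expect_equal(back$l_frag, sim$truth$l_frag, tolerance = 1e-12)
  expect_identical(back$whipping, TRUE)

  # empty train: header-only file round-trips
  sc <- scene_config(run = jet_run(frequency_hz = 1000), n_frames = 2, seed = 1)
  empty <- manual_truth(sc, bead_row(0, 1, 1, 1e-6)[0, ])
  p2 <- tempfile(fileext = ".csv")
  write_truth(empty, p2)
  expect_equal(nrow(read_truth(p2)$beads), 0)

  # missing column is a parse error
  lines <- readLines(path)
  hdr_at <- grep("^frame,", lines)[1]
  lines[hdr_at] <- sub("x_um", "x_wrong", lines[hdr_at])
  p3 <- tempfile(fileext = ".csv")
  writeLines(lines, p3)
  expect_error(read_truth(p3), class = "capsulejet_parse_error")
})

test_that("capsule micrographs round-trip through the segmenter", {
  set.seed(42)
  radii <- runif(12, 150, 220)
  gi <- generate_capsule_image(radii, seed = 4)
  expect_equal(nrow(gi$truth), 12)
  seg <- segment_capsules(gi$image)
  expect_equal(nrow(seg), 12)
  for (i in seq_len(12)) {
    d <- sqrt((seg$row_px - gi$truth$row_px[i])^2 +
                (seg$col_px - gi$truth$col_px[i])^2)
    j <- which.min(d)
    expect_lt(d[j], 2)
    expect_lt(abs(seg$r_px[j] - gi$truth$r_px[i]), 2)
  }
  # empty input: blank image, empty table
  g0 <- generate_capsule_image(numeric(0), seed = 1)
  expect_equal(nrow(g0$truth), 0)
  expect_equal(nrow(segment_capsules(g0$image)), 0)
  # seeded placement reproducible
  g1 <- generate_capsule_image(radii, seed = 9)
  g2 <- generate_capsule_image(radii, seed = 9)
  expect_identical(g1$truth, g2$truth)
  # impossible placement errors out
  expect_error(generate_capsule_image(rep(300, 40), shape = c(400, 400), seed = 1),
               class = "capsulejet_placement_error")
})

test_that("frame stacks round-trip through multi-page TIFF with sidecar", {
  sim <- sim_whip()
  path <- file.path(tempdir(), "stack_io.tif")
  write_frames(sim$frames, path)
  back <- read_frames(path)
  expect_identical(back$frames, sim$frames$frames)
  expect_equal(back$pixel_pitch, sim$frames$pixel_pitch)
  expect_equal(back$frame_rate, sim$frames$frame_rate)
  expect_equal(back$nozzle_offset, sim$frames$nozzle_offset)
})
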