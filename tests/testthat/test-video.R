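# Video analysis chain: axis alignment, fragmentation length, droplet
# detection, kymographs, bead tracking.

test_that("jet axis alignment recovers and removes a synthetic tilt", {
  sc <- scene_config(run = jet_run(frequency_hz = 1000), n_frames = 40,
                     axis_tilt_deg = 2, seed = 5)
  st <- render_frames(build_truth_train(sc), sc)
  al <- align_jet_axis(st)
  expect_equal(al$angle_deg, 2, tolerance = 0.1)
  expect_lt(abs(al$residual_deg), 0.3)
  # zero tilt: the stack passes through untouched
  sim <- sim_u0()
  al0 <- align_jet_axis(sim$frames)
  expect_lt(abs(al0$angle_deg), 0.1)
  d <- max(abs(fs_frame(al0$stack, 1) - fs_frame(sim$frames, 1)))
  expect_lte(d, 2)
  # blank stack: empty-scene error
  blank <- frame_stack(replicate(3, matrix(220, 60, 80), simplify = FALSE),
                       8.5e-6, 12000)
  expect_error(estimate_jet_axis(blank), class = "capsulejet_empty_scene")
})

test_that("fragmentation length recovers the generator truth", {
  sim <- sim_clean()                       # noiseless scene
  fr <- cached_frag("clean", sim)
  expect_lt(abs(fr$l_frag_m - sim$truth$l_frag) / sim$frames$pixel_pitch, 2)
  # noisy scene stays within 5 px
  simn <- sim_u0()
  frn <- cached_frag("u0", simn)
  expect_lt(abs(frn$l_frag_m - simn$truth$l_frag) / simn$frames$pixel_pitch, 5)
  # one breakup event per forcing period
  expect_equal(frn$n_events,
               simn$scene$n_frames / simn$frames$frame_rate * 1000,
               tolerance = 0.15)
  expect_s3_class(tidy(frn), "tbl_df")
  expect_equal(glance(frn)$n_events, frn$n_events)
  # an unbroken jet spanning the frame is a no-breakup error
  full <- matrix(220, 60, 200); full[25:35, ] <- 30
  unbroken <- frame_stack(replicate(5, full, simplify = FALSE), 8.5e-6, 12000)
  expect_error(fragmentation_length(unbroken), class = "capsulejet_no_breakup")
})

test_that("droplet detection finds synthetic drops with sub-pixel radii", {
  pitch <- 8.5e-6
  sc <- scene_config(run = jet_run(frequency_hz = 1000), n_frames = 1,
                     noise_sd = 0, seed = 1)
  # single in-focus drop of 23.5 px at a known position
  x <- sc$nozzle_offset + 500 * pitch
  st <- render_frames(manual_truth(sc, bead_row(0, 1, x, 23.5 * pitch)), sc)
  det <- detect_droplets(st, l_frag_m = x - 3e-3 + 1.5e-3 - 0.75e-3,
                         r_expected_um = 23.5 * 8.5)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$r_px - 23.5), 1)
  expect_lt(abs(det$col_px - 500.5), 1.5)
  # empty ROI: empty sample, not an error
  st0 <- render_frames(manual_truth(sc, bead_row(0, 1, 1e9, 1e-6)), sc)
  det0 <- detect_droplets(st0, l_frag_m = x - 2.25e-3, r_expected_um = 200)
  expect_equal(nrow(det0), 0)
  # ROI outside the frame: geometry error
  expect_error(detect_droplets(st, l_frag_m = 1, r_expected_um = 200),
               class = "capsulejet_geometry_error")
})

test_that("detection on a forced train is nearly complete and unbiased", {
  sim <- sim_u0()
  fr <- cached_frag("u0", sim)
  det <- detect_droplets(sim$frames, fr$l_frag_m,
                         r_expected_um = targeted_radius(1000, sim$scene$run))
  pitch <- sim$frames$pixel_pitch
  roi <- c(fr$l_frag_m + 1.5e-3, fr$l_frag_m + 3e-3)
  r_win <- targeted_radius(1000, sim$scene$run) * c(0.5, 1.5) * 1e-6
  truth <- dplyr::filter(sim$truth$beads,
                         x_m - r_m > roi[1],
                         x_m + r_m < roi[2],
                         r_m > r_win[1], r_m < r_win[2])
  hits <- vapply(seq_len(nrow(truth)), function(i) {
    cand <- det[det$frame == truth$frame[i], ]
    if (nrow(cand) == 0) return(NA_real_)
    x_px <- (truth$x_m[i] - sim$frames$nozzle_offset) / pitch + 0.5
    j <- which.min(abs(cand$col_px - x_px))
    if (abs(cand$col_px[j] - x_px) > 5) return(NA_real_)
    cand$r_px[j] * pitch / truth$r_m[i] - 1
  }, numeric(1))
  expect_gt(mean(!is.na(hits)), 0.95)           # >= 95% of truth drops found
  expect_lt(abs(mean(hits, na.rm = TRUE)), 0.02) # radius bias < 2%
  # detected size distribution matches truth over the same observation
  # window (ROI and radius band): KS below 0.1 at a reference size of 500,
  # converted to this scene's size by the 1/sqrt(n) rate of the KS statistic
  ks <- suppressWarnings(stats::ks.test(det$r_um, truth$r_m * 1e6))
  n_h <- 2 * nrow(det) * nrow(truth) / (nrow(det) + nrow(truth))
  expect_lt(unname(ks$statistic), 0.1 * sqrt(500 / n_h))
})

test_that("kymograph geometry and bead tracks agree with the generator", {
  simw <- sim_whip()
  ky <- build_kymograph(simw$frames)
  expect_equal(dim(ky), c(dim(simw$frames)[3], dim(simw$frames)[1]))
  # static scene: constant columns
  stat <- frame_stack(replicate(4, {
    m <- matrix(220, 40, 60); m[15:25, 20:30] <- 30; m
  }, simplify = FALSE), 8.5e-6, 12000)
  kys <- build_kymograph(stat)
  expect_true(all(apply(kys, 1, function(r) length(unique(r)) == 1)))

  # whipping scene: constant per-bead velocity; tracks flat at the truth value
  frw <- cached_frag("whip", simw)
  bw <- detect_beads(simw$frames, frw$jet_end)
  tkw <- track_beads(bw, simw$frames$frame_rate, v_expected = 1.6165)
  long <- dplyr::filter(dplyr::add_count(tkw, track_id), n >= 15)
  v_meas <- dplyr::summarise(dplyr::group_by(long, track_id),
                             v = median(v_m_per_s, na.rm = TRUE))$v
  v_true_all <- dplyr::summarise(dplyr::group_by(simw$truth$beads, id),
                                 v = median(v_m_per_s))$v
  # each measured track velocity matches some truth bead within 3%
  err <- vapply(v_meas[!is.na(v_meas)], function(v)
    min(abs(v / v_true_all - 1)), numeric(1))
  expect_lt(median(err), 0.03)
  # spacing columns are positive where defined
  expect_true(all(tkw$lambda_m > 0, na.rm = TRUE))
})

test_that("tracker coalescence terminations match the generator event log", {
  sim <- sim_u0()
  fr <- cached_frag("u0", sim)
  beads <- detect_beads(sim$frames, fr$jet_end)
  tk <- track_beads(beads, sim$frames$frame_rate, v_expected = 1.6165)
  n_coal <- dplyr::n_distinct(tk$track_id[tk$termination == "coalescence"])
  expect_lte(abs(n_coal - nrow(sim$truth$events)), 1)
  # whipping scene: suppressed coalescence, at most one spurious termination
  simw <- sim_whip()
  frw <- cached_frag("whip", simw)
  bw <- detect_beads(simw$frames, frw$jet_end)
  tkw <- track_beads(bw, simw$frames$frame_rate, v_expected = 1.6165)
  expect_lte(dplyr::n_distinct(tkw$track_id[tkw$termination == "coalescence"]), 1)
  # times strictly increase within each track
  ok <- dplyr::summarise(dplyr::group_by(tk, track_id),
                         inc = all(diff(t_s) > 0))
  expect_true(all(ok$inc))
  # single bead: one track, no spacing
  one <- tibble::tibble(frame = 0:9, x_m = 1e-3 + (0:9) * 1e-4)
  tk1 <- track_beads(one, 12000, v_expected = 1.2)
  expect_equal(dplyr::n_distinct(tk1$track_id), 1)
  expect_true(all(is.na(tk1$lambda_m)))
  # undersampling: advection exceeding the spacing is an error
  sparse <- dplyr::bind_rows(
    tibble::tibble(frame = 0L, x_m = c(1e-3, 1.2e-3)),
    tibble::tibble(frame = 1L, x_m = c(2e-3, 2.2e-3)))
  expect_error(track_beads(sparse, 100, v_expected = 1.6),
               class = "capsulejet_undersampling")
})
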