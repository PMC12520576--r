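#' Sample the breakup wavelength sequence
#'
#' Under piezo forcing (f > 0) every breakup period extrudes one wavelength
#' v_jet / f, perturbed by multiplicative Gaussian jitter. In free breakup
#' (f = 0) a broad range of modes near the fastest-growing one develops
#' spontaneously: wavelengths are drawn with probability proportional to the
#' growth rate omega(k) times the exponential amplification factor
#' exp(gain (omega/omega* - 1)) accumulated over the transit to the breakup
#' point (mode competition: a perturbation reaching pinch-off amplitude first
#' wins), restricted to modes growing at no less than `omega_fraction` of the
#' peak rate. The modal wavelength is 2 pi / k*; the train is polydisperse.
#'
#' @param scene a [scene_config()]
#' @param n number of wavelengths; default covers the acquisition plus warm-up
#' @param dispersion optional precomputed [dispersion_curve()] (required
#'   implicitly when f = 0; computed from the scene fluid if missing)
#' @param omega_fraction free-breakup band cutoff as a fraction of the peak
#'   growth rate (default 0.2)
#' @return numeric vector of wavelengths (m); seed-reproducible
#' @export
sample_breakup_spectrum <- function(scene, n = NULL, dispersion = NULL,
                                    omega_fraction = 0.2) {
  stopifnot(inherits(scene, "scene_config"))
  v <- jet_velocity(scene$run)
  f <- scene$run$frequency
  if (is.null(n)) {
    duration <- scene$n_frames / scene$frame_rate + warmup_time(scene)
    f_eff <- if (f > 0) f else {
      fm <- fastest_growing_mode(scene$fluid, scene$run$jet_radius)
      v * fm$k_star_per_m / (2 * pi)
    }
    n <- ceiling(duration * f_eff) + 10
  }
  set.seed(sub_seed(scene$seed, "spectrum"))
  if (f > 0) {
    lam <- (v / f) * exp(rnorm(n, 0, scene$wavelength_jitter_sd))
  } else {
    if (is.null(dispersion))
      dispersion <- dispersion_curve(scene$fluid, scene$run$jet_radius, n = 1024)
    band <- dplyr::filter(dispersion,
                          .data$omega_per_s > omega_fraction * max(.data$omega_per_s))
    if (nrow(band) == 0)
      abort("empty unstable band", class = "capsulejet_invalid_configuration")
    # lambda^2 is the k -> lambda Jacobian on the uniform-k grid, so the
    # wavelength density is omega * exp(gain (omega/omega* - 1)), with its
    # mode exactly at 2*pi/k*
    om_star <- max(band$omega_per_s)
    w <- band$omega_per_s *
      exp(scene$gain * (band$omega_per_s / om_star - 1)) *
      (2 * pi / band$k_per_m)^2
    k <- sample(band$k_per_m, n, replace = TRUE, prob = w)
    lam <- 2 * pi / k
  }
  lam
}

# Time needed to fill the field of view with beads before frame 0.
warmup_time <- function(scene) {
  v_d <- schneider_bead_velocity(scene$run, scene$fluid)
  v <- jet_velocity(scene$run)
  v_d <- max(v_d, 0.2 * v)
  span <- scene$nozzle_offset + scene$frame_cols * scene$pixel_pitch
  1.5 * span / v_d
}

#' Simulate a ground-truthed beads-on-a-string train
#'
#' Kinematic simulation of the forced breakup. Each wavelength detaches one
#' bead of volume-conserving radius (3 R_jet^2 lambda / 4)^(1/3) at the
#' fragmentation length (placed by the spatial growth model,
#' L_frag = gain v_jet / omega(k)). Beads start at a jittered jet velocity
#' and, while their trailing filament holds (until T_b, `filament_life_factor`
#' relaxation times after detachment), decelerate exponentially toward the
#' capillary-retarded velocity of [schneider_bead_velocity()]. A trailing
#' bead overtaking a leading one merges on contact (volumes add; the event is
#' logged). Primaries spawn satellites by a Bernoulli draw, carving the
#' satellite volume out of the primary. When the potential U exceeds the
#' filament whipping threshold, filaments break immediately: deceleration and
#' merging are disabled and beads acquire a small transverse deflection.
#'
#' @param scene a [scene_config()]
#' @param wavelengths wavelength sequence from [sample_breakup_spectrum()]
#' @return an object of class `truth_train`: list with `beads` (per-frame
#'   tibble: frame, t_s, id, x_m, y_m, r_m, v_m_per_s, lineage, n_merged,
#'   filament), `events` (coalescence log), `jet` (per-frame jet-end
#'   position), `l_frag`, `breakup_period`, `wavelengths`, `whipping`,
#'   and the scene
#' @export
build_truth_train <- function(scene, wavelengths = sample_breakup_spectrum(scene)) {
  stopifnot(inherits(scene, "scene_config"))
  if (length(wavelengths) == 0)
    abort("`wavelengths` must be nonempty", class = "capsulejet_invalid_configuration")

  run <- scene$run
  fluid <- scene$fluid
  v_jet <- jet_velocity(run)
  l_frag <- predict_fragmentation_length(scene)
  tau <- scene$relaxation_time
  dt <- 1 / scene$frame_rate
  fov_end <- scene$nozzle_offset + scene$frame_cols * scene$pixel_pitch
  r_fil <- run$jet_radius / scene$filament_ratio

  er <- electric_report(run$potential, run$jet_radius, fluid$surface_tension,
                        filament_ratio = scene$filament_ratio)
  whipping <- er$whipping != "none"

  # Per-bead static draws (satellites, velocity jitter, deflection).
  nb <- length(wavelengths)
  set.seed(sub_seed(scene$seed, "satellites"))
  has_sat <- rbinom(nb, 1, scene$satellite_probability) == 1
  set.seed(sub_seed(scene$seed, "velocity"))
  v0 <- v_jet * (1 + rnorm(nb, 0, scene$velocity_jitter_sd))
  set.seed(sub_seed(scene$seed, "deflection"))
  defl <- rnorm(2 * nb, 0, scene$deflection)

  # Primary radii, with satellite volume carved out.
  r_full <- (3 * run$jet_radius^2 * wavelengths / 4)^(1 / 3)
  sat_frac3 <- scene$satellite_radius_fraction^3
  if (sat_frac3 >= 1)
    abort("satellite volume exceeds its primary", class = "capsulejet_invalid_configuration")
  r_prim <- r_full * ifelse(has_sat, (1 - sat_frac3)^(1 / 3), 1)
  r_sat <- r_full * scene$satellite_radius_fraction

  t_start <- -warmup_time(scene)
  detach <- t_start + cumsum(wavelengths) / v_jet

  # Bead state vectors; satellites are appended as their primary detaches.
  id <- integer(0); x <- numeric(0); y <- numeric(0); v <- numeric(0)
  r <- numeric(0); vd <- numeric(0); t0 <- numeric(0); lin <- character(0)
  nm <- integer(0); v0b <- numeric(0); dfl <- numeric(0)
  next_id <- 1L
  next_detach <- 1L
  events <- list(); ev_i <- 0L
  rec <- vector("list", scene$n_frames)
  jet_end <- numeric(scene$n_frames)

  n_steps <- scene$n_frames + ceiling(-t_start / dt)
  t <- t_start
  for (step in seq_len(n_steps)) {
    t <- t + dt
    # Detach beads (and their satellites) whose time has come.
    while (next_detach <= nb && detach[next_detach] <= t) {
      i <- next_detach
      vv <- v0[i]
      vdi <- max(vv - 2 * fluid$surface_tension / (fluid$density * run$jet_radius * vv),
                 0.05 * vv)
      late <- t - detach[i]
      # the collapsed wavelength segment [L_frag - lambda, L_frag] forms a
      # bead centred at L_frag - lambda/2
      id <- c(id, next_id); x <- c(x, l_frag - wavelengths[i] / 2 + vv * late); y <- c(y, 0)
      v <- c(v, vv); r <- c(r, r_prim[i]); vd <- c(vd, vdi)
      t0 <- c(t0, detach[i]); lin <- c(lin, "primary"); nm <- c(nm, 1L)
      v0b <- c(v0b, vv); dfl <- c(dfl, defl[2 * i - 1])
      next_id <- next_id + 1L
      if (has_sat[i]) {
        lam_next <- if (i < nb) wavelengths[i + 1] else wavelengths[i]
        id <- c(id, next_id)
        x <- c(x, l_frag - wavelengths[i] / 2 - lam_next / 2 + vv * late); y <- c(y, 0)
        v <- c(v, vv); r <- c(r, r_sat[i]); vd <- c(vd, vdi)
        t0 <- c(t0, detach[i]); lin <- c(lin, "satellite"); nm <- c(nm, 1L)
        v0b <- c(v0b, vv); dfl <- c(dfl, defl[2 * i])
        next_id <- next_id + 1L
      }
      next_detach <- next_detach + 1L
    }

    if (length(id) > 0) {
      age <- t - t0
      if (whipping) {
        # Filament already broken: no capillary retardation; beads drift
        # sideways with a deflection growing over one relaxation time.
        y <- dfl * pmin(age / tau, 1)
      } else {
        broken <- age > scene$filament_life_factor * tau
        vel <- vd + (v0b - vd) * exp(-age / tau)
        # After the filament pinches (t > T_b) the velocity stays frozen at
        # its breakup value.
        v_tb <- vd + (v0b - vd) * exp(-scene$filament_life_factor)
        v <- ifelse(broken, v_tb, vel)
      }
      x <- x + v * dt

      # Coalescence: contact between consecutive beads (suppressed by
      # whipping, which removes the filament and the deceleration).
      if (!whipping && length(id) > 1) {
        repeat {
          o <- order(x)
          gap <- diff(x[o]) - (r[o][-length(o)] + r[o][-1])
          hit <- which(gap <= 0)
          if (length(hit) == 0) break
          j <- hit[1]
          a <- o[j]; b <- o[j + 1]            # a trails b along the axis
          vol <- r[a]^3 + r[b]^3
          ev_i <- ev_i + 1L
          events[[ev_i]] <- tibble(
            time_s = t, frame = step - (n_steps - scene$n_frames) - 1L,
            id_a = id[a], id_b = id[b], new_id = next_id,
            x_m = (x[a] * r[a]^3 + x[b] * r[b]^3) / vol
          )
          x[a] <- (x[a] * r[a]^3 + x[b] * r[b]^3) / vol
          v[a] <- (v[a] * r[a]^3 + v[b] * r[b]^3) / vol
          vd[a] <- (vd[a] * r[a]^3 + vd[b] * r[b]^3) / vol
          v0b[a] <- v[a]
          nm[a] <- nm[a] + nm[b]
          r[a] <- vol^(1 / 3)
          lin[a] <- paste0("coalesced-", nm[a])
          id[a] <- next_id; next_id <- next_id + 1L
          t0[a] <- min(t0[a], t0[b])
          keep <- seq_along(id) != b
          id <- id[keep]; x <- x[keep]; y <- y[keep]; v <- v[keep]
          r <- r[keep]; vd <- vd[keep]; t0 <- t0[keep]; lin <- lin[keep]
          nm <- nm[keep]; v0b <- v0b[keep]; dfl <- dfl[keep]
        }
      }

      # Drop beads that left the field of view (with a rendering margin).
      keep <- x - r < fov_end + 1e-3
      if (!all(keep)) {
        id <- id[keep]; x <- x[keep]; y <- y[keep]; v <- v[keep]
        r <- r[keep]; vd <- vd[keep]; t0 <- t0[keep]; lin <- lin[keep]
        nm <- nm[keep]; v0b <- v0b[keep]; dfl <- dfl[keep]
      }
    }

    frame <- step - (n_steps - scene$n_frames)
    if (frame >= 1) {
      # Continuous jet tip: advances at v_jet from the last detachment.
      tip <- if (next_detach <= nb) {
        l_frag - (detach[next_detach] - t) * v_jet
      } else l_frag
      jet_end[frame] <- min(tip, l_frag)
      if (length(id) > 0) {
        age <- t - t0
        rec[[frame]] <- tibble(
          frame = frame - 1L, t_s = t, id = id, x_m = x, y_m = y, r_m = r,
          v_m_per_s = v, lineage = lin, n_merged = nm,
          filament = !whipping & (age <= scene$filament_life_factor * tau),
          r_filament_m = ifelse(!whipping & (age <= scene$filament_life_factor * tau),
                                r_fil, 0)
        )
      }
    }
  }

  events <- if (ev_i > 0) {
    ev <- bind_rows(events)
    dplyr::filter(ev, .data$frame >= 0)
  } else {
    tibble(time_s = numeric(0), frame = integer(0), id_a = integer(0),
           id_b = integer(0), new_id = integer(0), x_m = numeric(0))
  }

  structure(
    list(
      beads = bind_rows(rec),
      events = events,
      jet = tibble(frame = 0:(scene$n_frames - 1L), x_end_m = jet_end),
      l_frag = l_frag,
      breakup_period = mean(wavelengths) / v_jet,
      wavelengths = wavelengths,
      whipping = whipping,
      scene = scene
    ),
    class = "truth_train"
  )
}

#' @export
print.truth_train <- function(x, ...) {
  cat("<truth_train>\n")
  cat(sprintf("  %d bead-frames over %d frames; L_frag = %.3f mm; %d coalescence events%s\n",
              nrow(x$beads), x$scene$n_frames, m_to_mm(x$l_frag),
              nrow(x$events), if (x$whipping) " (whipping)" else ""))
  invisible(x)
}
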