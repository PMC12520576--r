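#' Render a truth train into a synthetic bright-field frame stack
#'
#' Draws, per frame, the unbroken jet as a dark band from the nozzle to the
#' jet end with a spatially growing sinusoidal envelope, each bead as a dark
#' disk, and each live filament as a dark line of width 2 r_f; then applies
#' the in-plane axis tilt, Gaussian blur and additive Gaussian noise and
#' quantises to 8 bits. Objects outside the frame are silently clipped.
#'
#' @param truth a [build_truth_train()] result
#' @param scene the [scene_config()] (defaults to the one inside `truth`)
#' @return a [frame_stack()]
#' @export
render_frames <- function(truth, scene = truth$scene) {
  stopifnot(inherits(truth, "truth_train"), inherits(scene, "scene_config"))
  nr <- scene$frame_rows; nc <- scene$frame_cols
  pitch <- scene$pixel_pitch
  bg <- scene$background; fg <- scene$foreground
  center_row <- (nr + 1) / 2
  v_jet <- jet_velocity(scene$run)
  f <- scene$run$frequency
  k <- if (f > 0) 2 * pi * f / v_jet else
    fastest_growing_mode(scene$fluid, scene$run$jet_radius)$k_star_per_m
  om <- 2 * pi * (if (f > 0) f else v_jet * k / (2 * pi))
  rj_px <- scene$run$jet_radius / pitch
  rows <- seq_len(nr)
  col_x <- scene$nozzle_offset + (seq_len(nc) - 0.5) * pitch  # axial position of column centres

  beads_by_frame <- split(truth$beads, truth$beads$frame)
  set.seed(sub_seed(scene$seed, "noise"))

  frames <- vector("list", scene$n_frames)
  for (fr in seq_len(scene$n_frames)) {
    img <- matrix(bg, nr, nc)
    t <- (fr - 1) / scene$frame_rate
    x_end <- truth$jet$x_end_m[fr]

    # Unbroken jet with growing sinusoidal envelope (amplitude reaches the
    # jet radius at L_frag, seeded exp(-gain) at the nozzle).
    hw_full <- rep(-1, nc)
    jcols <- which(col_x <= x_end)
    if (length(jcols) > 0) {
      amp <- pmin(0.7 * exp(scene$gain * (col_x[jcols] / truth$l_frag - 1)), 0.7)
      hw <- rj_px * (1 + amp * sin(k * col_x[jcols] - om * t))
      hw_full[jcols] <- pmax(hw, 0.3 * rj_px)
      mask <- outer(abs(rows - center_row), hw_full, `<=`)
      img[mask] <- fg
    }

    b <- beads_by_frame[[as.character(fr - 1L)]]
    if (!is.null(b) && nrow(b) > 0) {
      b <- arrange(b, .data$x_m)
      ccol <- (b$x_m - scene$nozzle_offset) / pitch + 0.5
      crow <- center_row + b$y_m / pitch
      rpx <- b$r_m / pitch

      # Filaments: thin dark line from each bead with a live trailing
      # filament back to the previous object (bead or jet end).
      fil <- which(b$filament)
      fg_fil <- scene$filament_grey %||% 150
      for (i in fil) {
        x1 <- if (i == 1) (x_end - scene$nozzle_offset) / pitch else ccol[i - 1]
        y1 <- if (i == 1) center_row else crow[i - 1]
        x2 <- ccol[i]; y2 <- crow[i]
        c1 <- max(1L, ceiling(min(x1, x2))); c2 <- min(nc, floor(max(x1, x2)))
        if (c2 >= c1 && x2 > x1) {
          cseq <- c1:c2
          yline <- round(y1 + (y2 - y1) * (cseq - x1) / (x2 - x1))
          w_f <- max(round(b$r_filament_m[i] / pitch), 1)
          for (dr in -w_f:w_f) {
            rr <- yline + dr
            ok <- rr >= 1 & rr <= nr
            if (any(ok)) img[cbind(rr[ok], cseq[ok])] <- fg_fil
          }
        }
      }

      # Beads as dark disks (clipped at frame borders).
      for (i in seq_len(nrow(b))) {
        c1 <- max(1L, ceiling(ccol[i] - rpx[i] - 1)); c2 <- min(nc, floor(ccol[i] + rpx[i] + 1))
        r1 <- max(1L, ceiling(crow[i] - rpx[i] - 1)); r2 <- min(nr, floor(crow[i] + rpx[i] + 1))
        if (c1 > c2 || r1 > r2) next
        sub <- outer((r1:r2 - crow[i])^2, (c1:c2 - ccol[i])^2, `+`) <= rpx[i]^2
        img[r1:r2, c1:c2][sub] <- fg
      }
    }

    if (scene$axis_tilt_deg != 0) {
      eb <- EBImage::rotate(EBImage::Image(t(img) / 255), scene$axis_tilt_deg,
                            output.dim = c(nc, nr), bg.col = bg / 255)
      img <- t(as.array(eb)) * 255
    }
    if (scene$blur_sd > 0) img <- fast_gblur(img, scene$blur_sd)
    if (scene$noise_sd > 0) img <- img + rnorm(nr * nc, 0, scene$noise_sd)
    frames[[fr]] <- matrix(as.raw(pmin(pmax(round(img), 0), 255)), nr, nc)
  }

  frame_stack(frames, pitch, scene$frame_rate,
              nozzle_offset = scene$nozzle_offset,
              provenance = list(config_hash = scene_hash(scene), seed = scene$seed))
}

#' Simulate a full scene (spectrum, truth, frames)
#'
#' Convenience wrapper chaining [sample_breakup_spectrum()],
#' [build_truth_train()] and [render_frames()].
#'
#' @param scene a [scene_config()]
#' @return list with elements `truth` and `frames`
#' @export
simulate_scene <- function(scene) {
  truth <- build_truth_train(scene)
  list(truth = truth, frames = render_frames(truth, scene))
}

#' Render a synthetic capsule micrograph with ground truth
#'
#' Draws gelated capsules as bright-interior disks with a dark rim (phase
#' contrast appearance) at random non-touching positions, plus Gaussian blur
#' and noise. A truth table of centres and radii is returned with the image.
#'
#' @param radii_um capsule radii in um (possibly empty)
#' @param pixel_pitch_um um per pixel (default 2.32)
#' @param shape image shape (rows, cols), default 900 x 1200
#' @param rim_width_px dark rim width (default 4)
#' @param min_gap_px minimum surface-to-surface gap between capsules and to
#'   the border margin (default 6)
#' @param seed integer seed for placement and noise
#' @param max_tries placement attempts per capsule before failing
#' @param centers_px optional n x 2 matrix (row, col) of forced centres,
#'   bypassing random placement (capsules may then touch the border)
#' @return list: `image` (numeric matrix, grey 0-255) and `truth` tibble
#'   (`row_px`, `col_px`, `r_px`, `r_um`)
#' @export
generate_capsule_image <- function(radii_um, pixel_pitch_um = 2.32,
                                   shape = c(900, 1200), rim_width_px = 4,
                                   min_gap_px = 6, seed = 1, max_tries = 200,
                                   centers_px = NULL) {
  if (any(radii_um <= 0)) abort("`radii_um` must be > 0", class = "capsulejet_domain_error")
  nr <- shape[1]; nc <- shape[2]
  bg <- 200; interior <- 235; rim <- 45
  img <- matrix(bg, nr, nc)
  r_px <- radii_um / pixel_pitch_um
  n <- length(radii_um)
  truth <- tibble(row_px = numeric(0), col_px = numeric(0),
                  r_px = numeric(0), r_um = numeric(0))
  set.seed(sub_seed(seed, "capsules"))
  if (n > 0) {
    placed_row <- numeric(0); placed_col <- numeric(0); placed_rad <- numeric(0)
    ord <- order(r_px, decreasing = TRUE)   # place big ones first
    rows_out <- cols_out <- numeric(n)
    for (ii in ord) {
      rp <- r_px[ii]
      if (is.null(centers_px)) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          cr <- runif(1, rp + min_gap_px, nr - rp - min_gap_px)
          cc <- runif(1, rp + min_gap_px, nc - rp - min_gap_px)
          if (length(placed_row) == 0 ||
              all(sqrt((placed_row - cr)^2 + (placed_col - cc)^2) >
                  rp + placed_rad + min_gap_px)) {
            ok <- TRUE; break
          }
        }
        if (!ok) abort("could not place capsules without overlap",
                       class = "capsulejet_placement_error")
      } else {
        cr <- centers_px[ii, 1]; cc <- centers_px[ii, 2]
      }
      placed_row <- c(placed_row, cr); placed_col <- c(placed_col, cc)
      placed_rad <- c(placed_rad, rp)
      rows_out[ii] <- cr; cols_out[ii] <- cc
      r1 <- max(1L, floor(cr - rp - rim_width_px)); r2 <- min(nr, ceiling(cr + rp + rim_width_px))
      c1 <- max(1L, floor(cc - rp - rim_width_px)); c2 <- min(nc, ceiling(cc + rp + rim_width_px))
      d2 <- outer((r1:r2 - cr)^2, (c1:c2 - cc)^2, `+`)
      d <- sqrt(d2)
      block <- img[r1:r2, c1:c2]
      block[d <= rp] <- interior
      block[d <= rp & d > rp - rim_width_px] <- rim
      img[r1:r2, c1:c2] <- block
    }
    truth <- tibble(row_px = rows_out, col_px = cols_out, r_px = r_px,
                    r_um = radii_um)
  }
  img <- fast_gblur(img, 1) + rnorm(nr * nc, 0, 3)
  img <- pmin(pmax(img, 0), 255)
  attr(img, "pixel_pitch_um") <- pixel_pitch_um
  list(image = img, truth = truth)
}
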