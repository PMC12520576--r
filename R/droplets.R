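# --- Canny edge detection -------------------------------------------------
# Sobel gradients, non-maximum suppression along the quantized gradient
# direction, and two-level hysteresis (weak edges survive only in connected
# components containing a strong edge).

sobel_gradients <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  mp <- cbind(m[, 1], m, m[, nc]); mp <- rbind(mp[1, ], mp, mp[nr, ])
  # 3x3 Sobel via shifted sums on the padded matrix
  s <- function(dr, dc) mp[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  gx <- (s(-1, 1) + 2 * s(0, 1) + s(1, 1)) - (s(-1, -1) + 2 * s(0, -1) + s(1, -1))
  gy <- (s(1, -1) + 2 * s(1, 0) + s(1, 1)) - (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Canny edge detector
#'
#' @param m numeric matrix (grey levels)
#' @param sigma Gaussian pre-smoothing SD in px (0 = none)
#' @param low,high hysteresis thresholds as quantiles of the nonzero gradient
#'   magnitude (defaults 0.8 and 0.95), or absolute values if `absolute = TRUE`
#' @param absolute interpret `low`/`high` as absolute gradient magnitudes
#' @return logical matrix of edge pixels
#' @export
canny_edges <- function(m, sigma = 1, low = 0.8, high = 0.95, absolute = FALSE) {
  if (sigma > 0) m <- fast_gblur(m, sigma)
  g <- sobel_gradients(m)
  mag <- g$mag
  nr <- nrow(mag); nc <- ncol(mag)
  # quantize direction to 0, 45, 90, 135 degrees
  ang <- atan2(g$gy, g$gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- (floor((ang + pi / 8) / (pi / 4)) %% 4) # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  shift <- function(mm, dr, dc) {
    out <- matrix(-Inf, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- mm[rs[ok_r], cs[ok_c]]
    out
  }
  nmax <- (sector == 0 & mag >= shift(mag, 0, 1) & mag >= shift(mag, 0, -1)) |
    (sector == 1 & mag >= shift(mag, 1, 1) & mag >= shift(mag, -1, -1)) |
    (sector == 2 & mag >= shift(mag, 1, 0) & mag >= shift(mag, -1, 0)) |
    (sector == 3 & mag >= shift(mag, 1, -1) & mag >= shift(mag, -1, 1))
  nz <- mag[mag > 0]
  if (length(nz) == 0) return(matrix(FALSE, nr, nc))
  thr_lo <- if (absolute) low else quantile(nz, low)
  thr_hi <- if (absolute) high else quantile(nz, high)
  weak <- nmax & mag >= thr_lo
  strong <- nmax & mag >= thr_hi
  if (!any(strong)) return(matrix(FALSE, nr, nc))
  lab <- EBImage::bwlabel(EBImage::Image(t(weak)))
  lab <- t(as.array(lab))
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  weak & (lab %in% keep)
}

# --- Circular Hough transform ---------------------------------------------

#' Circular Hough transform on an edge map
#'
#' Accumulates circle centres over a radius window, extracts accumulator
#' peaks, then refines each candidate: the centre is re-estimated as the
#' centroid of supporting edge pixels and the radius as their mean distance
#' to the centre (sub-pixel). When the image gradient is supplied, voting is
#' gradient-directed (each edge pixel votes only along its gradient line,
#' both ways), which is both faster and more selective than full-circle
#' voting.
#'
#' @param edges logical edge matrix
#' @param gradient optional list with `gx`, `gy` matrices (Sobel gradients of
#'   the same image) enabling directed voting
#' @param r_min,r_max radius window in px
#' @param n_angles accumulator samples around each circle (default 64)
#' @param min_score minimum fraction of the circle perimeter supported by
#'   edge pixels (default 0.5); refined radii drifting outside the search
#'   window are rejected
#' @param max_circles maximum number of circles returned
#' @return tibble: `row_px`, `col_px`, `r_px`, `score`
#' @export
hough_circles <- function(edges, r_min, r_max, gradient = NULL, n_angles = 64,
                          min_score = 0.5, max_circles = 50) {
  nr <- nrow(edges); nc <- ncol(edges)
  pts <- which(edges, arr.ind = TRUE)
  empty <- tibble(row_px = numeric(0), col_px = numeric(0),
                  r_px = numeric(0), score = numeric(0))
  if (nrow(pts) < 8) return(empty)
  radii <- seq(max(2, floor(r_min)), ceiling(r_max), by = 1)
  directed <- !is.null(gradient)
  if (directed) {
    gmag <- sqrt(gradient$gx[pts]^2 + gradient$gy[pts]^2)
    ur <- gradient$gy[pts] / pmax(gmag, 1e-9)   # unit gradient, row component
    uc <- gradient$gx[pts] / pmax(gmag, 1e-9)
  } else {
    theta <- seq(0, 2 * pi, length.out = n_angles + 1)[-1]
    ct <- cos(theta); st <- sin(theta)
  }

  best <- vector("list", length(radii))
  for (ri in seq_along(radii)) {
    r <- radii[ri]
    if (directed) {
      cr <- round(c(pts[, 1] + r * ur, pts[, 1] - r * ur))
      cc <- round(c(pts[, 2] + r * uc, pts[, 2] - r * uc))
      vote_min <- 5
    } else {
      cr <- round(rep(pts[, 1], each = n_angles) + r * rep(st, nrow(pts)))
      cc <- round(rep(pts[, 2], each = n_angles) + r * rep(ct, nrow(pts)))
      vote_min <- max(4, ceiling(min_score * n_angles / 3))
    }
    ok <- cr >= 1 & cr <= nr & cc >= 1 & cc <= nc
    if (!any(ok)) next
    acc_idx <- (cc[ok] - 1L) * nr + cr[ok]
    tab <- tabulate(acc_idx, nbins = nr * nc)
    o <- which(tab >= vote_min)
    if (length(o) == 0) next
    best[[ri]] <- tibble(idx = o, votes = tab[o], r = r)
  }
  cand <- bind_rows(best)
  if (nrow(cand) == 0) return(empty)
  cand <- mutate(cand,
                 row_px = (.data$idx - 1L) %% nr + 1L,
                 col_px = (.data$idx - 1L) %/% nr + 1L,
                 score = .data$votes / n_angles)
  # pool candidates on a coarse grid (keep the best per 4x4 cell) so the
  # refinement loop sees each cluster of accumulator votes once
  cand <- cand |>
    mutate(cell = paste(round(.data$row_px / 4), round(.data$col_px / 4))) |>
    dplyr::group_by(.data$cell) |>
    dplyr::slice_max(.data$votes, n = 1, with_ties = FALSE) |>
    ungroup() |>
    arrange(dplyr::desc(.data$votes)) |>
    head(60)

  # greedy non-maximum suppression across radii and positions
  out <- list()
  taken_r <- numeric(0); taken_c <- numeric(0); taken_rad <- numeric(0)
  tried_r <- numeric(0); tried_c <- numeric(0)
  er <- pts[, 1]; ec <- pts[, 2]
  for (i in seq_len(nrow(cand))) {
    if (length(out) >= max_circles) break
    cr0 <- cand$row_px[i]; cc0 <- cand$col_px[i]; r0 <- cand$r[i]
    if (length(taken_r) > 0 &&
        any(sqrt((taken_r - cr0)^2 + (taken_c - cc0)^2) < 0.5 * pmax(taken_rad, r0)))
      next
    if (length(tried_r) > 0 &&
        any(sqrt((tried_r - cr0)^2 + (tried_c - cc0)^2) < 3))
      next
    tried_r <- c(tried_r, cr0); tried_c <- c(tried_c, cc0)
    # refine on supporting edge pixels within a shell around r0
    d <- sqrt((er - cr0)^2 + (ec - cc0)^2)
    supp <- which(abs(d - r0) <= pmax(2, 0.08 * r0))
    if (length(supp) < 8) next
    ok <- TRUE
    for (iter in 1:3) {
      cr1 <- mean(er[supp]); cc1 <- mean(ec[supp])
      d <- sqrt((er - cr1)^2 + (ec - cc1)^2)
      r1 <- mean(d[supp])
      supp <- which(abs(d - r1) <= pmax(2, 0.08 * r1))
      if (length(supp) < 8 || r1 < r_min - 1 || r1 > r_max + 1) { ok <- FALSE; break }
    }
    if (!ok || length(supp) < 8) next
    # perimeter support fraction with refined parameters
    angles <- atan2(er[supp] - cr1, ec[supp] - cc1)
    coverage <- length(unique(round(angles / (2 * pi / n_angles)))) / n_angles
    if (coverage < min_score) next
    out[[length(out) + 1]] <- tibble(row_px = cr1, col_px = cc1, r_px = r1,
                                     score = coverage)
    taken_r <- c(taken_r, cr1); taken_c <- c(taken_c, cc1)
    taken_rad <- c(taken_rad, r1)
  }
  if (length(out) == 0) return(empty)
  bind_rows(out)
}

#' Detect droplets downstream of the breakup point
#'
#' Re-implements the droplet sizing chain: a region of interest of axial span
#' `roi_span_m`, positioned `roi_offset_m` downstream of the fragmentation
#' length (where drop-shape oscillations have damped out), is scanned with a
#' Canny filter followed by a circular Hough transform over a
#' physics-informed radius window (`r_expected_um` +/- `radius_window`).
#' Detections are focus-filtered by the mean gradient magnitude on the circle
#' and deduplicated per frame (two detections within half a radius keep the
#' higher score).
#'
#' @param stack a [frame_stack()], axis-aligned
#' @param l_frag_m fragmentation length (m), e.g. from
#'   [fragmentation_length()]
#' @param r_expected_um expected droplet radius (um), e.g.
#'   [targeted_radius()]; the Hough window is `r_expected_um * (1 -
#'   radius_window)` to `* (1 + radius_window)`
#' @param roi_span_m,roi_offset_m ROI geometry (defaults 1.5 mm each)
#' @param radius_window half-width of the radius window as a fraction
#'   (default 0.5)
#' @param frame_stride analyse every `frame_stride`-th frame (default 1)
#' @param focus_fraction in-focus criterion: mean gradient magnitude on the
#'   detected circle must reach this fraction of the frame's 95th-percentile
#'   gradient (default 0.5)
#' @param min_score minimum Hough perimeter support (default 0.5)
#' @return tibble of class `droplet_sample`: `frame`, `row_px`, `col_px`
#'   (frame coordinates), `r_px`, `r_um`, `focus_score`, `score`
#' @export
detect_droplets <- function(stack, l_frag_m, r_expected_um,
                            roi_span_m = 1.5e-3, roi_offset_m = 1.5e-3,
                            radius_window = 0.5, frame_stride = 1,
                            focus_fraction = 0.5, min_score = 0.5) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack)
  pitch <- stack$pixel_pitch
  c_start <- floor((l_frag_m + roi_offset_m - stack$nozzle_offset) / pitch) + 1
  c_end <- ceiling((l_frag_m + roi_offset_m + roi_span_m - stack$nozzle_offset) / pitch)
  if (c_start < 1 || c_start >= d[3])
    abort("ROI falls outside the frame", class = "capsulejet_geometry_error")
  c_end <- min(c_end, d[3])
  r_exp_px <- um_to_m(r_expected_um) / pitch
  r_min <- r_exp_px * (1 - radius_window)
  r_max <- r_exp_px * (1 + radius_window)

  res <- vector("list", d[1])
  for (i in seq(1, d[1], by = frame_stride)) {
    roi <- fs_frame(stack, i)[, c_start:c_end, drop = FALSE]
    roi_s <- fast_gblur(roi, 1)
    g <- sobel_gradients(roi_s)
    edges <- canny_edges(roi_s, sigma = 0)
    if (!any(edges)) next
    circ <- hough_circles(edges, r_min, r_max, gradient = g,
                          min_score = min_score)
    if (nrow(circ) == 0) next
    # focus score: mean gradient magnitude on the circle vs the frame's
    # 95th-percentile gradient
    g95 <- quantile(g$mag[g$mag > 0], 0.95)
    theta <- seq(0, 2 * pi, length.out = 32)
    circ$focus_score <- vapply(seq_len(nrow(circ)), function(j) {
      rr <- pmin(pmax(round(circ$row_px[j] + circ$r_px[j] * sin(theta)), 1), nrow(roi))
      cc <- pmin(pmax(round(circ$col_px[j] + circ$r_px[j] * cos(theta)), 1), ncol(roi))
      mean(g$mag[cbind(rr, cc)]) / g95
    }, numeric(1))
    circ <- dplyr::filter(circ, .data$focus_score >= focus_fraction)
    if (nrow(circ) == 0) next
    # require the full circle inside the ROI (clipped arcs bias the radius)
    circ <- dplyr::filter(circ,
                          .data$row_px - .data$r_px >= 0.5,
                          .data$row_px + .data$r_px <= nrow(roi) + 0.5,
                          .data$col_px - .data$r_px >= 0.5,
                          .data$col_px + .data$r_px <= ncol(roi) + 0.5)
    if (nrow(circ) == 0) next
    # sub-pixel radius from the radial intensity profile of the raw ROI (the
    # Hough/edge estimate carries NMS digitisation and the analysis blur; the
    # profile midpoint carries neither)
    circ$r_px <- vapply(seq_len(nrow(circ)), function(j)
      refine_radius_profile(roi, circ$row_px[j], circ$col_px[j], circ$r_px[j]),
      numeric(1))
    circ$frame <- i - 1L
    circ$col_px <- circ$col_px + c_start - 1
    res[[i]] <- circ
  }
  out <- bind_rows(res)
  if (nrow(out) == 0)
    return(structure(tibble(frame = integer(0), row_px = numeric(0),
                            col_px = numeric(0), r_px = numeric(0),
                            r_um = numeric(0), focus_score = numeric(0),
                            score = numeric(0)),
                     class = c("droplet_sample", class(tibble()))))
  out <- mutate(out, r_um = .data$r_px * m_to_um(pitch))
  out <- select(out, "frame", "row_px", "col_px", "r_px", "r_um",
                "focus_score", "score")
  class(out) <- c("droplet_sample", class(out))
  out
}
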