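#' Kymograph of an acquisition
#'
#' Builds the space-time representation of the jet: each kymograph column is
#' one frame's transverse-minimum (darkest) projection along the axial
#' coordinate, so moving beads appear as dark sloped traces whose slope is
#' their velocity.
#'
#' @param stack a [frame_stack()], axis-aligned
#' @return a numeric matrix of class `kymograph` (rows = axial positions,
#'   columns = frames) with attributes `pixel_pitch`, `frame_rate`,
#'   `nozzle_offset`
#' @export
build_kymograph <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack)
  ky <- matrix(0, d[3], d[1])
  for (i in seq_len(d[1])) {
    m <- fs_frame(stack, i)
    ky[, i] <- apply(m, 2, min)
  }
  structure(ky, pixel_pitch = stack$pixel_pitch, frame_rate = stack$frame_rate,
            nozzle_offset = stack$nozzle_offset,
            class = c("kymograph", "matrix", "array"))
}

#' Write a kymograph as an 8-bit TIFF
#'
#' @param ky a [build_kymograph()] matrix
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
write_kymograph <- function(ky, path) {
  stopifnot(inherits(ky, "kymograph"))
  tiff::writeTIFF(unclass(ky) / 255, path, bits.per.sample = 8L,
                  compression = "LZW")
  invisible(path)
}

#' Per-frame bead positions from an aligned stack
#'
#' Detects beads downstream of the continuous jet as contiguous runs of the
#' transverse foreground-count profile, separated by empty columns. Centres
#' are intensity-weighted centroids; an equivalent radius comes from the
#' run's foreground area.
#'
#' @param stack a [frame_stack()], axis-aligned
#' @param jet_end per-frame jet-end axial positions (m), e.g.
#'   `fragmentation_length(stack)$jet_end`; beads are searched downstream of
#'   the jet end plus `margin_px`
#' @param threshold binarization method
#' @param margin_px gap left after the jet end (default 3)
#' @param min_area_px minimum foreground area of a bead (default 20)
#' @return tibble: `frame`, `x_m` (axial bead centre), `r_m` (equivalent
#'   radius)
#' @export
detect_beads <- function(stack, jet_end = NULL, threshold = "otsu",
                         margin_px = 3, min_area_px = 20) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack)
  pitch <- stack$pixel_pitch
  res <- vector("list", d[1])
  for (i in seq_len(d[1])) {
    m <- fs_frame(stack, i)
    mask <- binarize_frame(m, threshold)
    profile <- colSums(mask)
    start_col <- 1L
    if (!is.null(jet_end)) {
      je <- jet_end$x_end_m[i]
      start_col <- min(d[3], max(1L, floor((je - stack$nozzle_offset) / pitch) +
                                   1L + margin_px))
    }
    p <- profile
    if (start_col > 1) p[seq_len(start_col - 1)] <- 0
    on <- p > 0
    if (!any(on)) next
    runs <- rle(on)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    seg <- which(runs$values)
    rows <- lapply(seg, function(s) {
      cols <- starts[s]:ends[s]
      # beads cut by the frame borders have biased centroids; skip them
      if (cols[1] <= 1L || cols[length(cols)] >= d[3]) return(NULL)
      area <- sum(p[cols])
      if (area < min_area_px) return(NULL)
      ctr <- sum(cols * p[cols]) / area
      tibble(frame = i - 1L,
             x_m = stack$nozzle_offset + (ctr - 0.5) * pitch,
             r_m = sqrt(area / pi) * pitch)
    })
    res[[i]] <- bind_rows(rows)
  }
  bind_rows(res)
}

#' Track beads across frames
#'
#' Nearest-neighbour frame-to-frame linking of per-frame bead positions with
#' a displacement gate of `gate_factor` times the expected per-frame
#' advection. Velocities are central finite differences; spacing is the
#' distance to the downstream neighbour in the same frame; each track is
#' aligned on its end time T_b (its last observation: breakup/coalescence/
#' exit), so kinematic curves are functions of t - T_b <= 0. A track whose
#' predicted position falls within the gate of a detection claimed by another
#' track is terminated as a coalescence.
#'
#' @param beads tibble from [detect_beads()] (columns `frame`, `x_m`, and
#'   optionally `r_m`)
#' @param frame_rate frames per second
#' @param v_expected expected bead velocity (m/s) used for the gate
#' @param gate_factor gate = `gate_factor` * `v_expected` / `frame_rate`
#'   (default 1.5)
#' @param min_length minimum track length in frames (default 5)
#' @return tibble of class `bead_tracks`: `track_id`, `frame`, `t_s`,
#'   `t_minus_tb_s`, `x_m`, `v_m_per_s`, `lambda_m`, `termination` (one of
#'   "exit", "coalescence"; constant within a track)
#' @export
track_beads <- function(beads, frame_rate, v_expected,
                        gate_factor = 1.5, min_length = 5) {
  stopifnot(all(c("frame", "x_m") %in% names(beads)))
  gate <- gate_factor * v_expected / frame_rate
  if (nrow(beads) == 0)
    return(tibble(track_id = integer(0), frame = integer(0), t_s = numeric(0),
                  t_minus_tb_s = numeric(0), x_m = numeric(0),
                  v_m_per_s = numeric(0), lambda_m = numeric(0),
                  termination = character(0)))
  frames <- sort(unique(beads$frame))
  # undersampling: if beads advect more than one typical spacing per frame,
  # nearest-neighbour linking is ambiguous
  spacing <- beads |>
    dplyr::group_by(.data$frame) |>
    dplyr::arrange(.data$x_m, .by_group = TRUE) |>
    mutate(d = dplyr::lead(.data$x_m) - .data$x_m) |>
    dplyr::pull(.data$d)
  med_sp <- median(spacing, na.rm = TRUE)
  if (is.finite(med_sp) && v_expected / frame_rate > med_sp)
    abort("frame rate too low: per-frame advection exceeds the bead spacing",
          class = "capsulejet_undersampling")

  by_frame <- split(beads, beads$frame)
  # active tracks: list of (id, last_x, last_frame, rows)
  next_id <- 1L
  active <- list()
  done <- list()
  for (fr in frames) {
    det <- by_frame[[as.character(fr)]]
    xs <- det$x_m
    claimed <- rep(FALSE, length(xs))
    if (length(active) > 0) {
      # advance expected positions; match greedily by distance
      pred <- vapply(active, function(tr)
        tr$last_x + v_expected * (fr - tr$last_frame) / frame_rate, numeric(1))
      assignment <- rep(NA_integer_, length(active))
      dmat <- abs(outer(pred, xs, `-`))
      if (length(xs) == 0) dmat <- matrix(Inf, length(active), 0)
      g <- gate * pmax(1, fr - vapply(active, function(tr) tr$last_frame, numeric(1)))
      while (length(xs) > 0) {
        dmat_masked <- dmat
        dmat_masked[!is.na(assignment), ] <- Inf
        if (any(claimed)) dmat_masked[, claimed] <- Inf
        if (all(!is.finite(dmat_masked))) break
        ij <- arrayInd(which.min(dmat_masked), dim(dmat_masked))
        if (dmat[ij[1], ij[2]] > g[ij[1]]) break
        assignment[ij[1]] <- ij[2]
        claimed[ij[2]] <- TRUE
      }
      still <- list()
      for (ai in seq_along(active)) {
        tr <- active[[ai]]
        j <- assignment[ai]
        if (!is.na(j)) {
          tr$rows[[length(tr$rows) + 1]] <- tibble(frame = fr, x_m = xs[j])
          tr$last_x <- xs[j]; tr$last_frame <- fr
          still[[length(still) + 1]] <- tr
        } else {
          # unmatched: coalescence if the predicted position lies within the
          # gate of a detection another track claimed; otherwise exit/lost
          p <- pred[ai]
          near_claimed <- length(xs) > 0 &&
            any(claimed & abs(xs - p) <= g[ai])
          stale <- fr - tr$last_frame > 3
          if (near_claimed) {
            tr$termination <- "coalescence"
            done[[length(done) + 1]] <- tr
          } else if (stale || p > max(beads$x_m)) {
            tr$termination <- "exit"
            done[[length(done) + 1]] <- tr
          } else {
            still[[length(still) + 1]] <- tr  # allow short gaps
          }
        }
      }
      active <- still
    }
    # unclaimed detections start new tracks
    for (j in which(!claimed)) {
      active[[length(active) + 1]] <- list(
        id = next_id, last_x = xs[j], last_frame = fr,
        rows = list(tibble(frame = fr, x_m = xs[j])), termination = "exit")
      next_id <- next_id + 1L
    }
  }
  for (tr in active) done[[length(done) + 1]] <- tr

  tracks <- purrr::map(done, function(tr) {
    df <- bind_rows(tr$rows)
    df$track_id <- tr$id
    df$termination <- tr$termination %||% "exit"
    df
  })
  out <- bind_rows(tracks)
  out <- dplyr::group_by(out, .data$track_id)
  out <- dplyr::filter(out, dplyr::n() >= min_length)
  out <- mutate(out,
                t_s = .data$frame / frame_rate,
                t_minus_tb_s = (.data$frame - max(.data$frame)) / frame_rate,
                v_m_per_s = central_diff(.data$x_m, .data$t_s))
  out <- ungroup(out)
  # spacing: distance to the downstream neighbour in the same frame
  out <- out |>
    dplyr::group_by(.data$frame) |>
    dplyr::arrange(.data$x_m, .by_group = TRUE) |>
    mutate(lambda_m = dplyr::lead(.data$x_m) - .data$x_m) |>
    ungroup() |>
    arrange(.data$track_id, .data$frame)
  class(out) <- c("bead_tracks", class(out))
  out
}

# central finite differences over possibly non-uniform sample times
# (one-sided at the ends)
central_diff <- function(x, t) {
  n <- length(x)
  if (n == 1) return(NA_real_)
  v <- numeric(n)
  v[1] <- (x[2] - x[1]) / (t[2] - t[1])
  v[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  v
}
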