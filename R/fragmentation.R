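#' Fragmentation length from a frame stack
#'
#' Re-implements the jet-end statistic: each frame is binarized, the
#' foreground mask is summed across the transverse axis to give an axial
#' profile, and the first axial position with zero foreground marks the end
#' of the continuous jet. Peaks of the jet-end time series (each peak is one
#' breakup event) are detected by prominence and averaged, and the nozzle
#' offset added, to give the fragmentation length.
#'
#' @param stack a [frame_stack()], already axis-aligned
#' @param threshold binarization method ("otsu" or fixed grey level)
#' @param prominence_px minimum peak prominence of the jet-end series
#'   (default 3 px)
#' @param min_separation_frames minimum frame separation between peaks
#'   (default 2); ties broken toward the earlier frame
#' @param min_events hard minimum number of breakup events (default 10);
#'   below 100 events per 2000 frames a warning is issued
#' @param band_rows optional row range (length 2) restricting the profile to
#'   the central portion containing the jet
#' @return an object of class `fragmentation_result`: list with `l_frag_m`,
#'   `sd_m`, `n_events`, `events` (tibble: frame, l_frag_m), `jet_end`
#'   (tibble: frame, x_end_m)
#' @export
fragmentation_length <- function(stack, threshold = "otsu",
                                 prominence_px = 3, min_separation_frames = 2,
                                 min_events = 10, band_rows = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack)
  nf <- d[1]; nr <- d[2]; nc <- d[3]
  rows <- if (is.null(band_rows)) seq_len(nr) else seq(band_rows[1], band_rows[2])

  end_px <- numeric(nf)
  for (i in seq_len(nf)) {
    m <- fs_frame(stack, i)[rows, , drop = FALSE]
    mask <- binarize_frame(m, threshold)
    profile <- colSums(mask)
    # Require the jet to be present at the left edge, then find the first
    # axial position where the foreground count drops to zero.
    z <- which(profile == 0)
    end_px[i] <- if (length(z) == 0) NA_real_ else z[1] - 1
  }
  if (all(is.na(end_px)))
    abort("jet never detaches within the frame", class = "capsulejet_no_breakup")
  end_px[is.na(end_px)] <- nc  # unbroken frames: jet spans the frame

  peaks <- find_peaks(end_px, prominence = prominence_px,
                      min_separation = min_separation_frames)
  if (length(peaks) < min_events)
    abort(sprintf("only %d breakup events detected (minimum %d)",
                  length(peaks), min_events),
          class = "capsulejet_insufficient_events")
  if (length(peaks) < 100 * nf / 2000)
    warn(sprintf("only %d breakup events in %d frames", length(peaks), nf))

  # Between two samples the jet tip advances by one frame of advection, so
  # the sampled peak underestimates the true maximum extension by half that
  # advance on average; correct by half the median ramp slope.
  slope <- stats::median(pmax(diff(end_px), 0))
  l_events <- stack$nozzle_offset + (end_px[peaks] + slope / 2) * stack$pixel_pitch
  structure(
    list(
      l_frag_m = mean(l_events),
      sd_m = sd(l_events),
      n_events = length(peaks),
      events = tibble(frame = peaks - 1L, l_frag_m = l_events),
      jet_end = tibble(frame = seq_len(nf) - 1L,
                       x_end_m = stack$nozzle_offset + end_px * stack$pixel_pitch)
    ),
    class = "fragmentation_result"
  )
}

# Local-maximum detection with a prominence criterion. A sample is a peak if
# it is >= its neighbours, its prominence (height above the higher of the two
# bracketing minima) reaches `prominence`, and it is at least
# `min_separation` samples from a stronger accepted peak (earlier peak wins
# ties).
find_peaks <- function(x, prominence = 0, min_separation = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  # collapse plateaus: keep the first sample of each run of equal values
  cand <- cand[c(TRUE, diff(cand) > 1 | x[cand[-1]] != x[cand[-length(cand)]])]
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(i) {
    left <- if (i == 1) x[1] else min(x[max(1, i - 50):i])
    right <- if (i == n) x[n] else min(x[i:min(n, i + 50)])
    x[i] - max(left, right)
  }, numeric(1))
  cand <- cand[prom >= prominence]
  if (length(cand) == 0) return(integer(0))
  # enforce separation, preferring higher peaks, earlier on ties
  ord <- order(-x[cand], cand)
  keep <- logical(length(cand))
  taken <- integer(0)
  for (j in ord) {
    if (all(abs(cand[j] - taken) >= min_separation)) {
      keep[j] <- TRUE
      taken <- c(taken, cand[j])
    }
  }
  sort(cand[keep])
}

#' @export
print.fragmentation_result <- function(x, ...) {
  cat(sprintf("<fragmentation_result: L_frag = %.3f mm (sd %.3f mm, %d events)>\n",
              m_to_mm(x$l_frag_m), m_to_mm(x$sd_m), x$n_events))
  invisible(x)
}

#' @rdname fragmentation_length
#' @param x a `fragmentation_result`
#' @param ... unused
#' @exportS3Method generics::tidy
#' @export
tidy.fragmentation_result <- function(x, ...) x$events

#' @rdname fragmentation_length
#' @exportS3Method generics::glance
#' @export
glance.fragmentation_result <- function(x, ...) {
  tibble(l_frag_mm = m_to_mm(x$l_frag_m), sd_mm = m_to_mm(x$sd_m),
         n_events = x$n_events)
}
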