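# Binarize one frame: foreground = dark objects on a bright background.
# method: "otsu" (per-frame Otsu threshold) or a fixed numeric grey level.
binarize_frame <- function(m, method = "otsu") {
  if (identical(method, "otsu")) {
    thr <- otsu_level(m)
    # guard against unimodal (empty) scenes: Otsu always returns a split, but
    # a real foreground must sit well below the background noise floor
    if (thr > median(m) - 5 * stats::mad(m)) return(m < -Inf)
  } else thr <- as.numeric(method)
  m < thr
}

#' Estimate the jet axis tilt
#'
#' Fits the principal axis of the time-averaged binarized jet mask via image
#' second moments and returns its angle to the column (flow) axis in degrees.
#'
#' @param stack a [frame_stack()]
#' @param threshold binarization method ("otsu" or a fixed grey level)
#' @return angle in degrees (positive = jet tilted toward larger row indices)
#' @export
estimate_jet_axis <- function(stack, threshold = "otsu") {
  stopifnot(inherits(stack, "frame_stack"))
  mf <- fs_mean_frame(stack)
  mask <- binarize_frame(mf, threshold)
  if (!any(mask)) abort("no foreground pixels in the scene",
                        class = "capsulejet_empty_scene")
  idx <- which(mask, arr.ind = TRUE)
  rr <- idx[, 1] - mean(idx[, 1])
  cc <- idx[, 2] - mean(idx[, 2])
  mu20 <- mean(cc^2); mu02 <- mean(rr^2); mu11 <- mean(cc * rr)
  0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
}

#' Rotate a frame stack about its centre
#'
#' Bilinear interpolation, constant background fill (the stack's median
#' border grey).
#'
#' @param stack a [frame_stack()]
#' @param angle_deg rotation angle in degrees
#' @return a rotated `frame_stack`
#' @export
rotate_stack <- function(stack, angle_deg) {
  stopifnot(inherits(stack, "frame_stack"))
  if (angle_deg == 0) return(stack)
  d <- dim(stack)
  bgv <- median(fs_frame(stack, 1)[1, ]) / 255
  frames <- lapply(stack$frames, function(f) {
    m <- matrix(as.integer(f), nrow = nrow(f))
    eb <- EBImage::rotate(EBImage::Image(t(m) / 255), angle_deg,
                          output.dim = c(d[3], d[2]), bg.col = bgv)
    t(as.array(eb)) * 255
  })
  frame_stack(frames, stack$pixel_pitch, stack$frame_rate,
              nozzle_offset = stack$nozzle_offset, provenance = stack$provenance)
}

#' Align the jet axis with the frame columns
#'
#' Estimates the tilt from the time-averaged binarized mask and rotates all
#' frames by its negative, then re-estimates to confirm the residual is below
#' `tol_deg`.
#'
#' @inheritParams estimate_jet_axis
#' @param tol_deg residual-angle warning tolerance (default 0.3)
#' @return list: `stack` (aligned), `angle_deg` (estimated tilt),
#'   `residual_deg`
#' @export
align_jet_axis <- function(stack, threshold = "otsu", tol_deg = 0.3,
                           min_angle_deg = 0.1) {
  ang <- estimate_jet_axis(stack, threshold)
  # below min_angle_deg the interpolation cost/blur outweighs the correction
  if (abs(ang) < min_angle_deg)
    return(list(stack = stack, angle_deg = ang, residual_deg = ang))
  out <- rotate_stack(stack, -ang)
  resid <- estimate_jet_axis(out, threshold)
  if (abs(resid) > tol_deg)
    warn(sprintf("residual axis angle %.2f deg exceeds %.2f deg", resid, tol_deg))
  list(stack = out, angle_deg = ang, residual_deg = resid)
}
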