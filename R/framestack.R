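#' Frame stack container
#'
#' A time-ordered stack of 8-bit grey frames with its physical calibration.
#' Frames are stored as raw matrices (rows x cols) to keep a 2000-frame
#' acquisition within memory; [fs_frame()] returns one frame as a numeric
#' matrix of grey levels 0-255. Background is bright and objects dark
#' (transmission imaging).
#'
#' @param frames list of raw or numeric matrices, all the same shape
#' @param pixel_pitch m per pixel
#' @param frame_rate frames per second
#' @param nozzle_offset axial position (m) of the left frame edge relative to
#'   the nozzle exit
#' @param provenance optional list (config hash, seed)
#' @return an object of class `frame_stack`
#' @export
frame_stack <- function(frames, pixel_pitch, frame_rate,
                        nozzle_offset = 0, provenance = list()) {
  stopifnot(is.list(frames), length(frames) > 0,
            pixel_pitch > 0, frame_rate > 0)
  frames <- lapply(frames, function(f) {
    if (is.raw(f)) return(f)
    matrix(as.raw(pmin(pmax(round(f), 0), 255)), nrow = nrow(f))
  })
  structure(
    list(frames = frames, pixel_pitch = pixel_pitch, frame_rate = frame_rate,
         nozzle_offset = nozzle_offset, provenance = provenance),
    class = "frame_stack"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname frame_stack
#' @param stack a `frame_stack`
#' @param i frame index (1-based)
#' @return `fs_frame()`: numeric matrix of grey levels in 0-255
#' @export
fs_frame <- function(stack, i) {
  f <- stack$frames[[i]]
  matrix(as.integer(f), nrow = nrow(f))
}

#' @rdname frame_stack
#' @export
n_frames <- function(stack) length(stack$frames)

#' @export
dim.frame_stack <- function(x) c(length(x$frames), dim(x$frames[[1]]))

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<frame_stack: %d frames of %dx%d px, %g um/px, %g fps>\n",
              d[1], d[2], d[3], m_to_um(x$pixel_pitch), x$frame_rate))
  invisible(x)
}

# Internal: mean frame as numeric matrix (used for axis estimation).
fs_mean_frame <- function(stack, max_frames = 50) {
  idx <- unique(round(seq(1, n_frames(stack), length.out = min(max_frames, n_frames(stack)))))
  acc <- Reduce(`+`, lapply(idx, function(i) fs_frame(stack, i)))
  acc / length(idx)
}

#' Write / read a frame stack as multi-page TIFF
#'
#' Pixel pitch, frame rate, nozzle offset and provenance travel in a JSON
#' sidecar (`<path>.json`) so the stack round-trips losslessly.
#'
#' @param stack a [frame_stack()]
#' @param path output TIFF path
#' @param compression TIFF compression (default "LZW")
#' @return `write_frames()`: `path`, invisibly. `read_frames()`: a
#'   `frame_stack`.
#' @export
write_frames <- function(stack, path, compression = "LZW") {
  stopifnot(inherits(stack, "frame_stack"))
  imgs <- lapply(stack$frames, function(f) matrix(as.integer(f), nrow = nrow(f)) / 255)
  tiff::writeTIFF(imgs, path, bits.per.sample = 8L, compression = compression)
  meta <- list(pixel_pitch_um = m_to_um(stack$pixel_pitch),
               frame_rate_hz = stack$frame_rate,
               nozzle_offset_mm = m_to_mm(stack$nozzle_offset),
               provenance = stack$provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frames
#' @param pixel_pitch_um,frame_rate_hz,nozzle_offset_mm calibration overrides
#'   used when no sidecar is present
#' @export
read_frames <- function(path, pixel_pitch_um = NULL, frame_rate_hz = NULL,
                        nozzle_offset_mm = NULL) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  pp <- pixel_pitch_um %||% meta$pixel_pitch_um %||%
    abort("pixel pitch unknown: no sidecar and no override", class = "capsulejet_data_error")
  fr <- frame_rate_hz %||% meta$frame_rate_hz %||%
    abort("frame rate unknown: no sidecar and no override", class = "capsulejet_data_error")
  off <- nozzle_offset_mm %||% meta$nozzle_offset_mm %||% 0
  frames <- lapply(imgs, function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]
    m * 255
  })
  frame_stack(frames, um_to_m(as.numeric(pp)), as.numeric(fr),
              nozzle_offset = mm_to_m(as.numeric(off)),
              provenance = meta$provenance %||% list())
}
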