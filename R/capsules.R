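#' Segment capsules in a micrograph
#'
#' Classical segmentation of gelated capsules: background flattening by a
#' large-scale median offset, thresholding of the dark rims, hole filling to
#' recover full disks, connected-component labelling with a watershed split
#' of touching objects, and exclusion of anything touching the image border.
#' The reported radius is the equivalent-circle radius sqrt(area / pi).
#'
#' @param image numeric matrix (grey 0-255), e.g. from
#'   [generate_capsule_image()]
#' @param pixel_pitch_um um per pixel (default: the image's
#'   `pixel_pitch_um` attribute, else 2.32)
#' @param min_radius_um discard objects smaller than this (default 20)
#' @param split_touching apply a distance-map watershed to separate touching
#'   capsules (default TRUE)
#' @return tibble of class `droplet_sample`: `row_px`, `col_px`, `r_px`,
#'   `r_um`, `area_px`
#' @export
segment_capsules <- function(image, pixel_pitch_um = NULL,
                             min_radius_um = 20, split_touching = TRUE) {
  pp <- pixel_pitch_um %||% attr(image, "pixel_pitch_um") %||% 2.32
  nr <- nrow(image); nc <- ncol(image)
  empty <- structure(tibble(row_px = numeric(0), col_px = numeric(0),
                            r_px = numeric(0), r_um = numeric(0),
                            area_px = numeric(0)),
                     class = c("droplet_sample", class(tibble())))
  # rims are the darkest structures; keep pixels well below background
  thr <- otsu_level(image)
  # unimodal (capsule-free) images: Otsu splits the noise, not objects
  if (thr > median(image) - 5 * stats::mad(image)) return(empty)
  rim <- image < thr
  if (!any(rim)) return(empty)
  filled <- EBImage::fillHull(EBImage::Image(t(rim)))
  if (split_touching) {
    dm <- EBImage::distmap(filled)
    lab <- EBImage::watershed(dm, tolerance = 3)
  } else {
    lab <- EBImage::bwlabel(filled)
  }
  lab <- t(as.array(lab))
  ids <- setdiff(unique(as.vector(lab)), 0)
  if (length(ids) == 0) return(empty)
  border_ids <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  rows <- lapply(ids, function(id) {
    if (id %in% border_ids) return(NULL)   # only capsules entirely in frame
    px <- which(lab == id, arr.ind = TRUE)
    area <- nrow(px)
    r_px <- sqrt(area / pi)
    if (r_px * pp < min_radius_um) return(NULL)
    tibble(row_px = mean(px[, 1]), col_px = mean(px[, 2]),
           r_px = r_px, r_um = r_px * pp, area_px = area)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  class(out) <- c("droplet_sample", class(out))
  out
}
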