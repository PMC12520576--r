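#' Write / read a truth train as CSV
#'
#' The per-frame bead table is written with fixed columns (`frame`, `id`,
#' `x_um`, `y_um`, `r_um`, `v_m_per_s`, `lineage`, `n_merged`, `filament`,
#' `r_filament_um`); scalar truth (fragmentation length, breakup period,
#' whipping flag) travels in commented header lines, and coalescence events in
#' a companion `<path>.events.csv`. Numeric fields round-trip to at least
#' 1e-9 relative.
#'
#' @param truth a [build_truth_train()] result
#' @param path CSV output path
#' @return `write_truth()`: `path`, invisibly
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "truth_train"))
  b <- truth$beads
  out <- data.frame(
    frame = b$frame, id = b$id,
    x_um = format(m_to_um(b$x_m), digits = 15, scientific = FALSE, trim = TRUE),
    y_um = format(m_to_um(b$y_m), digits = 15, scientific = FALSE, trim = TRUE),
    r_um = format(m_to_um(b$r_m), digits = 15, scientific = FALSE, trim = TRUE),
    v_m_per_s = format(b$v_m_per_s, digits = 15, trim = TRUE),
    lineage = b$lineage, n_merged = b$n_merged,
    filament = b$filament,
    r_filament_um = format(m_to_um(b$r_filament_m), digits = 15, trim = TRUE),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# l_frag_um=%s", format(m_to_um(truth$l_frag), digits = 15)), con)
  writeLines(sprintf("# breakup_period_s=%s", format(truth$breakup_period, digits = 15)), con)
  writeLines(sprintf("# whipping=%s", truth$whipping), con)
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  if (nrow(truth$events) > 0 || TRUE) {
    ev <- truth$events
    ev$time_s <- format(ev$time_s, digits = 15, trim = TRUE)
    ev$x_m <- format(ev$x_m, digits = 15, trim = TRUE)
    write.csv(ev, paste0(path, ".events.csv"), row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_truth
#' @return `read_truth()`: a `truth_train` (without the scene and wavelength
#'   sequence, which are not serialised)
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", lines[h])
    key <- sub("=.*", "", kv); val <- sub(".*=", "", kv)
    meta[[key]] <- val
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  required <- c("frame", "id", "x_um", "y_um", "r_um", "v_m_per_s",
                "lineage", "n_merged", "filament", "r_filament_um")
  header_fields <- strsplit(body[1], ",")[[1]]
  missing <- setdiff(required, header_fields)
  if (length(missing) > 0)
    abort(sprintf("truth CSV line 1: missing column(s) %s",
                  paste(missing, collapse = ", ")),
          class = "capsulejet_parse_error")
  nfield <- lengths(strsplit(body, ",", fixed = TRUE))
  bad <- which(nfield != nfield[1])
  if (length(bad) > 0)
    abort(sprintf("malformed truth CSV '%s' at line %d: expected %d fields, got %d",
                  path, bad[1] + length(hdr), nfield[1], nfield[bad[1]]),
          class = "capsulejet_parse_error")
  df <- tryCatch(
    read.csv(text = body, stringsAsFactors = FALSE),
    error = function(e) abort(sprintf("malformed truth CSV '%s': %s", path,
                                      conditionMessage(e)),
                              class = "capsulejet_parse_error")
  )
  beads <- tibble(
    frame = as.integer(df$frame), id = as.integer(df$id),
    x_m = um_to_m(as.numeric(df$x_um)), y_m = um_to_m(as.numeric(df$y_um)),
    r_m = um_to_m(as.numeric(df$r_um)), v_m_per_s = as.numeric(df$v_m_per_s),
    lineage = as.character(df$lineage), n_merged = as.integer(df$n_merged),
    filament = as.logical(df$filament),
    r_filament_m = um_to_m(as.numeric(df$r_filament_um))
  )
  ev_path <- paste0(path, ".events.csv")
  events <- if (file.exists(ev_path)) {
    e <- read.csv(ev_path, stringsAsFactors = FALSE)
    tibble(time_s = as.numeric(e$time_s), frame = as.integer(e$frame),
           id_a = as.integer(e$id_a), id_b = as.integer(e$id_b),
           new_id = as.integer(e$new_id), x_m = as.numeric(e$x_m))
  } else {
    tibble(time_s = numeric(0), frame = integer(0), id_a = integer(0),
           id_b = integer(0), new_id = integer(0), x_m = numeric(0))
  }
  structure(
    list(beads = beads, events = events, jet = NULL,
         l_frag = um_to_m(as.numeric(meta$l_frag_um)),
         breakup_period = as.numeric(meta$breakup_period_s),
         wavelengths = NULL, whipping = identical(meta$whipping, "TRUE"),
         scene = NULL),
    class = "truth_train"
  )
}
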