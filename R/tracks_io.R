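#' Read a TrackMate-style spot table
#'
#' Consumes the CSV dialect exported by particle-tracking software:
#' required columns `TRACK_ID`, `FRAME`, `POSITION_X`, `POSITION_Y`, plus
#' optional `POSITION_T` and `AREA`.  Extra non-numeric header rows (as
#' emitted by some exporters between the header and the data) are skipped
#' automatically.  Frames may start at 0 or 1 in the file; they are
#' normalised to 0-based internally and the shift is recorded.  Rows with
#' missing or non-finite coordinates are dropped and counted.
#'
#' @param path CSV file path.
#' @param frame_interval seconds per frame, used to reconstruct times when
#'   `POSITION_T` is absent; required in that case (no silent default for
#'   a unit-bearing quantity).
#' @return tibble with columns `track`, `frame` (0-based), `t`, `x`, `y`
#'   and `area` (NA when absent); attributes `n_dropped` and
#'   `frame_offset`.
#' @export
read_tracks <- function(path, frame_interval = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  # drop exporter sub-header rows (non-numeric FRAME)
  fr_num <- suppressWarnings(as.numeric(raw$FRAME))
  raw <- raw[!is.na(fr_num), , drop = FALSE]
  num <- function(v) suppressWarnings(as.numeric(v))
  d <- tibble::tibble(track = as.integer(num(raw$TRACK_ID)),
                      frame = as.integer(num(raw$FRAME)),
                      x = num(raw$POSITION_X), y = num(raw$POSITION_Y),
                      t = if ("POSITION_T" %in% names(raw))
                        num(raw$POSITION_T) else NA_real_,
                      area = if ("AREA" %in% names(raw))
                        num(raw$AREA) else NA_real_)
  ok <- is.finite(d$x) & is.finite(d$y) & !is.na(d$track) & !is.na(d$frame)
  n_dropped <- sum(!ok)
  d <- d[ok, ]
  offset <- if (nrow(d) > 0) min(d$frame) else 0L
  d$frame <- d$frame - offset
  if (all(is.na(d$t))) {
    if (is.null(frame_interval))
      stop("POSITION_T absent: frame_interval must be supplied explicitly")
    d$t <- d$frame * frame_interval
  }
  d <- d[order(d$track, d$frame), ]
  attr(d, "n_dropped") <- n_dropped
  attr(d, "frame_offset") <- offset
  d
}

#' Write a track table in the TrackMate-style dialect
#'
#' Inverse of [read_tracks()]: numeric fields are written with full
#' precision so a round-trip is lossless to double precision.
#'
#' @param tracks tibble with columns `track`, `frame`, `t`, `x`, `y`, and
#'   optionally `area`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  d <- data.frame(TRACK_ID = tracks$track, FRAME = tracks$frame,
                  POSITION_X = fmt17(tracks$x),
                  POSITION_Y = fmt17(tracks$y),
                  POSITION_T = fmt17(tracks$t))
  if (!is.null(tracks$area) && !all(is.na(tracks$area)))
    d$AREA <- fmt17(tracks$area)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Split a track table into per-track pieces
#'
#' @param tracks tibble from [read_tracks()] or [make_tracks()].
#' @param min_points drop tracks with fewer points.
#' @return named list of per-track tibbles, ordered by track id.
#' @export
split_tracks <- function(tracks, min_points = 2) {
  out <- split(tracks, tracks$track)
  out[vapply(out, nrow, 0L) >= min_points]
}
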