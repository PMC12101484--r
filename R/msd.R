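#' Windowed local MSD exponents of a track
#'
#' Within every sliding window of `window` consecutive points the mean
#' squared displacement is computed for lags `1..max_lag` (time pairs fully
#' inside the window) and the local anomalous-diffusion exponent
#' \eqn{\alpha} is the slope of the least-squares fit of
#' \eqn{\log \mathrm{MSD}} against \eqn{\log \tau}.  \eqn{\alpha = 1}
#' marks Brownian motion, \eqn{\alpha = 2} ballistic motion; windows with
#' zero MSD (a stationary spot) yield `NA` rather than an error.
#'
#' @param track a tibble/data.frame with columns `t`, `x`, `y` (one track,
#'   frames in order) such as one group of [read_tracks()] output.
#' @param window window size in frames.
#' @param max_lag largest lag (frames) entering the fit; default
#'   `floor(window/3)` (at least 3 lags, the short-lag regime).
#' @return object of class `local_motion_profile`: tibble with one row per
#'   window (`t_center`, `alpha`) plus attributes `window`, `max_lag`, and
#'   the per-step `speeds`/`angles` tibble from [speeds_and_angles()].
#' @export
local_msd_exponents <- function(track, window = 12, max_lag = NULL) {
  track <- as.data.frame(track)
  n <- nrow(track)
  if (n < window)
    stop(sprintf("track too short for local MSD: %d points, window needs >= %d",
                 n, window))
  if (is.null(max_lag)) max_lag <- max(3L, floor(window / 3))
  max_lag <- min(max_lag, window - 1)
  xy <- cbind(track$x, track$y)
  tt <- track$t
  nw <- n - window + 1
  alpha <- rep(NA_real_, nw)
  t_center <- numeric(nw)
  lags <- seq_len(max_lag)
  dt_frame <- stats::median(diff(tt))
  for (w in seq_len(nw)) {
    idx <- w:(w + window - 1)
    msd <- vapply(lags, function(lag) {
      i <- idx[seq_len(window - lag)]
      mean(rowSums((xy[i + lag, , drop = FALSE] - xy[i, , drop = FALSE])^2))
    }, numeric(1))
    t_center[w] <- mean(tt[idx])
    if (all(msd > 0))
      alpha[w] <- stats::coef(stats::lm(log(msd) ~ log(lags * dt_frame)))[2]
  }
  prof <- tibble::tibble(t_center = t_center, alpha = alpha)
  attr(prof, "window") <- window
  attr(prof, "max_lag") <- max_lag
  attr(prof, "steps") <- speeds_and_angles(track)
  class(prof) <- c("local_motion_profile", class(prof))
  prof
}

#' Classify windows and tracks as active or passive
#'
#' A window is active when its exponent exceeds `threshold`
#' (\eqn{\alpha > 1} indicates active, superdiffusive motion).  The primary
#' statistic is the window-level active fraction; a per-track label (active
#' iff the track's median defined \eqn{\alpha} exceeds the threshold) is
#' also returned as a convenience.
#'
#' @param profiles a single `local_motion_profile` or a list of them (one
#'   per track).
#' @param threshold exponent threshold \eqn{\alpha^*}.
#' @return list with `window_fraction`, `track_fraction`, `track_labels`
#'   (logical per track), and counts `n_windows`, `n_undefined`.
#' @export
classify_active <- function(profiles, threshold = 1) {
  if (inherits(profiles, "local_motion_profile")) profiles <- list(profiles)
  alphas <- lapply(profiles, function(p) p$alpha)
  all_a <- unlist(alphas)
  defined <- all_a[!is.na(all_a)]
  if (length(defined) == 0)
    stop("all window exponents are undefined: cannot classify")
  labels <- vapply(alphas, function(a) {
    a <- a[!is.na(a)]
    if (length(a) == 0) NA else stats::median(a) > threshold
  }, logical(1))
  list(window_fraction = mean(defined > threshold),
       track_fraction = mean(labels, na.rm = TRUE),
       track_labels = labels,
       n_windows = length(defined),
       n_undefined = sum(is.na(all_a)))
}

#' Per-step speeds and turning angles of a track
#'
#' Speed is the displacement magnitude between consecutive spots divided by
#' the elapsed time; the turning angle is the angle in degrees between
#' consecutive displacement vectors, in \eqn{[0\degree, 180\degree]}
#' (0 = straight ahead).  Zero-length displacements give an undefined
#' (`NA`) angle, flagged, not thrown.
#'
#' @param track tibble/data.frame with columns `t`, `x`, `y` for one track.
#' @return tibble with `t`, `speed` (um/s; `NA` in the last row) and
#'   `angle` (degrees; `NA` where undefined).
#' @export
speeds_and_angles <- function(track) {
  track <- as.data.frame(track)
  n <- nrow(track)
  if (n < 2) stop("need at least 2 points for speeds")
  dx <- diff(track$x)
  dy <- diff(track$y)
  dt <- diff(track$t)
  sp <- sqrt(dx^2 + dy^2) / dt
  ang <- rep(NA_real_, n - 1)
  if (n >= 3) {
    for (i in seq_len(n - 2)) {
      a <- c(dx[i], dy[i])
      b <- c(dx[i + 1], dy[i + 1])
      na <- sqrt(sum(a^2))
      nb <- sqrt(sum(b^2))
      if (na > 0 && nb > 0) {
        cosv <- min(1, max(-1, sum(a * b) / (na * nb)))
        ang[i] <- acos(cosv) * 180 / pi
      }
    }
  }
  tibble::tibble(t = track$t[-n], speed = sp, angle = ang)
}
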