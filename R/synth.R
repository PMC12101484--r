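#' Generate a synthetic condensate track cohort with ground truth
#'
#' Active tracks move at a constant speed along a persistent random
#' heading (optionally with slow angular diffusion) on top of 2D Brownian
#' motion; passive tracks are purely Brownian.  Independent Gaussian
#' localization noise is added to every observed position.  Per-spot areas
#' follow either a constant model or grow linearly with the true
#' instantaneous speed.  The generator is a pure function of its arguments
#' and the seed.
#'
#' @param n_tracks number of tracks.
#' @param n_frames points per track.
#' @param frame_interval seconds between frames (0.15 matches the windowed
#'   MSD analysis; 1/2.3 matches the imaging frame rate).
#' @param active_fraction fraction of tracks that are active; the first
#'   `round(active_fraction * n_tracks)` tracks are active.
#' @param speed ballistic speed of active tracks in um/s.
#' @param diffusion diffusion coefficient in um^2/s (applies to both
#'   classes).
#' @param noise_sd localization noise standard deviation in um.  The
#'   default 0.1 um is a typical spot-localization uncertainty for dim,
#'   moving condensates; it also reproduces the short-lag MSD flattening
#'   that makes purely thermal tracks read as subdiffusive, as passive
#'   condensates do in real recordings.
#' @param heading_sd per-frame angular diffusion of the active heading in
#'   radians (0 = perfectly persistent).
#' @param area_model `"constant"` or `"speed"` (area increases linearly
#'   with instantaneous speed).
#' @param area_base baseline area in um^2.
#' @param area_slope um^2 per (um/s) under the `"speed"` model.
#' @param area_noise_sd lognormal-ish multiplicative jitter (sd of a
#'   Gaussian factor, truncated at 0).
#' @param seed integer seed.
#' @return tibble with columns `track`, `frame` (0-based), `t`, `x`, `y`,
#'   `area`, plus attribute `labels` (logical: active per track).
#' @export
make_tracks <- function(n_tracks = 100, n_frames = 60,
                        frame_interval = 1 / 2.3, active_fraction = 0.3,
                        speed = 2, diffusion = 0.05, noise_sd = 0.1,
                        heading_sd = 0, area_model = c("constant", "speed"),
                        area_base = 0.5, area_slope = 0.2,
                        area_noise_sd = 0, seed = 1) {
  area_model <- match.arg(area_model)
  n_active <- round(active_fraction * n_tracks)
  labels <- seq_len(n_tracks) <= n_active
  with_seed(seed, {
    rows <- vector("list", n_tracks)
    for (k in seq_len(n_tracks)) {
      th <- stats::runif(1, 0, 2 * pi)
      x <- y <- numeric(n_frames)
      x[1] <- stats::runif(1, 0, 50)
      y[1] <- stats::runif(1, 0, 50)
      sp_true <- numeric(n_frames)
      for (i in 2:n_frames) {
        drift <- c(0, 0)
        if (labels[k]) {
          if (heading_sd > 0) th <- th + stats::rnorm(1, 0, heading_sd)
          drift <- speed * frame_interval * c(cos(th), sin(th))
        }
        dstep <- sqrt(2 * diffusion * frame_interval) * stats::rnorm(2)
        x[i] <- x[i - 1] + drift[1] + dstep[1]
        y[i] <- y[i - 1] + drift[2] + dstep[2]
        sp_true[i - 1] <- sqrt(sum((drift + dstep)^2)) / frame_interval
      }
      sp_true[n_frames] <- sp_true[n_frames - 1]
      xo <- x + stats::rnorm(n_frames, 0, noise_sd)
      yo <- y + stats::rnorm(n_frames, 0, noise_sd)
      area <- if (area_model == "constant") rep(area_base, n_frames)
        else area_base + area_slope * sp_true
      if (area_noise_sd > 0)
        area <- area * pmax(stats::rnorm(n_frames, 1, area_noise_sd), 0.05)
      rows[[k]] <- tibble::tibble(track = k, frame = seq_len(n_frames) - 1L,
                                  t = (seq_len(n_frames) - 1) * frame_interval,
                                  x = xo, y = yo, area = area)
    }
    out <- do.call(rbind, rows)
    attr(out, "labels") <- labels
    out
  })
}

#' Render synthetic fluorescence frames with elliptical Gaussian spots
#'
#' Each spot is an anisotropic Gaussian whose standard deviations are
#' chosen so that its 33%-of-peak contour has the stated major/minor axes
#' (i.e. \eqn{\sigma = \mathrm{axis} / (2\sqrt{2\ln(1/0.33)})}), which pins
#' the rendered ground truth to the moment-based ellipse convention of the
#' sizing pipeline.  Gaussian read noise is added on a constant
#' background.  Overlapping spots are allowed but flagged.
#'
#' @param spots tibble with columns `row`, `col`, `major`, `minor`,
#'   `orientation` (degrees), `peak`, and optionally `track`, `frame`.
#' @param frame_size integer pair (rows, cols).
#' @param background constant background level.
#' @param noise_sd Gaussian noise standard deviation.
#' @param pixel_size um/px (recorded in the ground truth).
#' @param seed integer seed.
#' @return list with `frames` (list of matrices, one per unique frame id),
#'   `truth` (`area_record`-style tibble with the analytic
#'   \eqn{\pi(major/2)(minor/2)} areas) and `overlaps` (logical per spot).
#' @export
make_images <- function(spots, frame_size = c(64, 64), background = 10,
                        noise_sd = 0, pixel_size = 0.1, seed = 1) {
  stopifnot(all(c("row", "col", "major", "minor", "peak") %in% names(spots)))
  if (!"orientation" %in% names(spots)) spots$orientation <- 0
  if (!"frame" %in% names(spots)) spots$frame <- 1L
  if (!"track" %in% names(spots)) spots$track <- seq_len(nrow(spots))
  if (any(spots$row < 1 | spots$row > frame_size[1] |
          spots$col < 1 | spots$col > frame_size[2]))
    stop("all spots must lie inside the frame")
  if (any(spots$peak <= background))
    stop("spot peak intensities must exceed the background")
  kk <- 2 * sqrt(2 * log(1 / 0.33)) # axis length per Gaussian sd at 33% cut
  frames_id <- sort(unique(spots$frame))
  rr <- matrix(rep(seq_len(frame_size[1]), frame_size[2]), frame_size[1])
  cc <- matrix(rep(seq_len(frame_size[2]), each = frame_size[1]),
               frame_size[1])
  with_seed(seed, {
    frames <- vector("list", length(frames_id))
    names(frames) <- as.character(frames_id)
    overlap <- rep(FALSE, nrow(spots))
    for (fi in seq_along(frames_id)) {
      img <- matrix(background, frame_size[1], frame_size[2])
      sel <- which(spots$frame == frames_id[fi])
      mask_any <- matrix(FALSE, frame_size[1], frame_size[2])
      for (s in sel) {
        sr <- spots$major[s] / kk
        sc <- spots$minor[s] / kk
        th <- spots$orientation[s] * pi / 180
        dr <- rr - spots$row[s]
        dc <- cc - spots$col[s]
        u <- dr * cos(th) + dc * sin(th)
        v <- -dr * sin(th) + dc * cos(th)
        g <- (spots$peak[s] - background) *
          exp(-0.5 * ((u / sr)^2 + (v / sc)^2))
        hit <- g > 0.1 * (spots$peak[s] - background)
        overlap[s] <- overlap[s] || any(mask_any & hit)
        mask_any <- mask_any | hit
        img <- img + g
      }
      if (noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                            nrow(img))
      frames[[fi]] <- img
    }
    truth <- tibble::tibble(track = spots$track, frame = spots$frame,
                            row = spots$row, col = spots$col,
                            major = spots$major, minor = spots$minor,
                            area_px2 = pi * (spots$major / 2) *
                              (spots$minor / 2),
                            area_um2 = pi * (spots$major / 2) *
                              (spots$minor / 2) * pixel_size^2)
    list(frames = frames, truth = truth, overlaps = overlap)
  })
}

#' Build a two-phase bead configuration of known densities
#'
#' Places beads uniformly at density `rho_den` inside a sphere or
#' ellipsoid at the box centre and at `rho_sat` outside it, assigning
#' chain ids in contiguous blocks (the "chains" are bookkeeping blocks for
#' the density analytics, not bonded polymers).
#'
#' @param rho_den,rho_sat dense/dilute number densities in beads/sigma^3
#'   (`rho_den > rho_sat >= 0`).
#' @param radius sphere radius, or length-3 semi-axes of an ellipsoid, in
#'   sigma.
#' @param box length-3 box edge lengths.
#' @param beads_per_chain block size for chain-id assignment.
#' @param seed integer seed.
#' @return a `system_state` (velocities zero, all chains passive); the
#'   generating densities are attached as attribute `truth`.
#' @export
make_slab_configuration <- function(rho_den = 0.6, rho_sat = 0.01,
                                    radius = 10, box = c(32, 32, 50),
                                    beads_per_chain = 25, seed = 1) {
  stopifnot(rho_den > rho_sat, rho_sat >= 0)
  if (rho_den > 1.2)
    stop("rho_den exceeds close packing for unit beads")
  ax <- if (length(radius) == 1) rep(radius, 3) else radius
  stopifnot(length(ax) == 3, all(2 * ax < box))
  v_ell <- 4 / 3 * pi * prod(ax)
  v_box <- prod(box)
  n_in <- round(rho_den * v_ell)
  n_out <- round(rho_sat * (v_box - v_ell))
  with_seed(seed, {
    # uniform in the ellipsoid: scale uniform-in-ball samples
    ball <- matrix(stats::rnorm(3 * n_in), ncol = 3)
    ball <- ball / sqrt(rowSums(ball^2)) * stats::runif(n_in)^(1 / 3)
    inside <- sweep(ball, 2, ax, "*")
    out <- matrix(NA_real_, 0, 3)
    while (nrow(out) < n_out) {
      cand <- cbind(stats::runif(2 * n_out + 10, -box[1] / 2, box[1] / 2),
                    stats::runif(2 * n_out + 10, -box[2] / 2, box[2] / 2),
                    stats::runif(2 * n_out + 10, -box[3] / 2, box[3] / 2))
      keep <- rowSums(sweep(cand, 2, ax, "/")^2) > 1
      out <- rbind(out, cand[keep, , drop = FALSE])
    }
    out <- out[seq_len(n_out), , drop = FALSE]
    pos <- rbind(inside, out)
    n <- nrow(pos)
    n_chains <- ceiling(n / beads_per_chain)
    pad <- n_chains * beads_per_chain - n
    if (pad > 0) { # pad the last block by duplicating dilute positions
      extra <- out[seq_len(min(pad, nrow(out))), , drop = FALSE]
      while (nrow(extra) < pad) extra <- rbind(extra, inside[1, , drop = FALSE])
      pos <- rbind(pos, extra)
      n <- nrow(pos)
    }
    p <- sim_params(n_chains = n_chains, beads_per_chain = beads_per_chain,
                    box = box, total_steps = 0, bias_steps = 0,
                    dump_every = 1, scale = "small")
    st <- system_state(pos, matrix(0, n, 3), p, step = 0)
    attr(st, "truth") <- list(rho_den = rho_den, rho_sat = rho_sat,
                              axes = ax, box = box)
    attr(st, "params") <- p
    st
  })
}
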