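#' Radial density profile about a centre
#'
#' Counts beads in spherical shells around `center` using minimum-image
#' distances and divides by shell volumes.  Shells inside the inscribed
#' sphere of the periodic box use the analytic volume
#' \eqn{\tfrac{4}{3}\pi(r_2^3 - r_1^3)}; shells reaching beyond it are
#' clipped to the box by a deterministic Monte-Carlo volume estimate.
#'
#' @param state a `system_state` or an N x 3 position matrix.
#' @param center length-3 centre (e.g. the largest-cluster centre of mass).
#' @param bin_width shell thickness in \eqn{\sigma}.
#' @param box length-3 box lengths (required for a bare matrix).
#' @param r_max outermost radius; default the half-diagonal reach
#'   `min(box)/2`.
#' @return object of class `density_profile`: tibble-like list with
#'   direction tag `"isotropic"`, bin centers `r`, densities `rho` in
#'   beads/\eqn{\sigma^3}, per-bin `counts`, `volumes`, and `bin_width`.
#' @export
radial_density_profile <- function(state, center, bin_width = 0.5,
                                   box = NULL, r_max = NULL) {
  pos <- if (inherits(state, "system_state")) state$positions else state
  if (is.null(box)) box <- infer_box(pos)
  stopifnot(bin_width > 0)
  if (bin_width > min(box) / 2)
    stop("bin_width exceeds the smallest box half-length")
  if (is.null(r_max)) r_max <- min(box) / 2
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  d <- min_image(sweep(pos, 2, center), box)
  r <- sqrt(rowSums(d^2))
  counts <- graphics::hist(r[r < r_max], breaks = breaks, plot = FALSE)$counts
  vols <- shell_volumes(breaks, box)
  new_density_profile("isotropic", breaks, counts, vols, bin_width)
}

new_density_profile <- function(direction, breaks, counts, volumes, bin_width) {
  p <- list(direction = direction,
            r = (breaks[-1] + breaks[-length(breaks)]) / 2,
            rho = counts / volumes,
            counts = counts, volumes = volumes,
            breaks = breaks, bin_width = bin_width)
  class(p) <- "density_profile"
  p
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("density_profile (%s): %d bins, r in [%g, %g], rho in [%.4g, %.4g]\n",
              x$direction, length(x$r), min(x$breaks), max(x$breaks),
              min(x$rho), max(x$rho)))
  invisible(x)
}

# volumes of spherical shells clipped to the periodic box; analytic inside
# the inscribed sphere, seeded Monte-Carlo beyond it (deterministic)
shell_volumes <- function(breaks, box, n_mc = 3e5, mc_seed = 20240101) {
  nb <- length(breaks) - 1
  vol <- 4 / 3 * pi * diff(breaks^3)
  rin <- min(box) / 2
  clipped <- which(breaks[-1] > rin + 1e-12)
  if (length(clipped) > 0) {
    frac <- with_seed(mc_seed, {
      u <- cbind(stats::runif(n_mc, -box[1] / 2, box[1] / 2),
                 stats::runif(n_mc, -box[2] / 2, box[2] / 2),
                 stats::runif(n_mc, -box[3] / 2, box[3] / 2))
      r <- sqrt(rowSums(u^2))
      graphics::hist(r[r < max(breaks)], breaks = breaks,
                     plot = FALSE)$counts / n_mc
    })
    vbox <- prod(box)
    vol[clipped] <- pmax(frac[clipped] * vbox, 1e-12)
  }
  vol
}

#' Directional density profiles parallel and perpendicular to the force
#'
#' The active force acts along +z.  The perpendicular profile selects the
#' slab `|z - z_c| <= slab_half_thickness` and bins beads by their in-plane
#' (x, y) radial distance from the centre.  The parallel profile does the
#' same in the two slabs `|x - x_c| <= s` and `|y - y_c| <= s` (planes that
#' contain the force axis), binning by in-plane radial distance in the
#' (y, z) and (x, z) planes respectively, and averages the two.  Densities
#' are counts over annulus volumes \eqn{2\pi r\,dr \cdot 2s}.
#'
#' @param state a `system_state` or N x 3 position matrix.
#' @param center length-3 profile centre.
#' @param slab_half_thickness slab half-thickness \eqn{s} in \eqn{\sigma}.
#' @param bin_width radial bin width.
#' @param box length-3 box lengths (required for a bare matrix).
#' @return list with elements `perpendicular` and `parallel`, both
#'   `density_profile` objects.
#' @export
directional_profiles <- function(state, center, slab_half_thickness = 1,
                                 bin_width = 0.5, box = NULL) {
  pos <- if (inherits(state, "system_state")) state$positions else state
  if (is.null(box)) box <- infer_box(pos)
  stopifnot(slab_half_thickness > 0)
  d <- min_image(sweep(pos, 2, center), box)
  s <- slab_half_thickness

  planar <- function(normal_axis, plane_axes, r_lim) {
    breaks <- seq(0, r_lim, by = bin_width)
    sel <- abs(d[, normal_axis]) <= s
    if (!any(sel)) {
      warning("empty slab selection: all-zero profile returned")
      counts <- rep(0L, length(breaks) - 1)
    } else {
      r <- sqrt(rowSums(d[sel, plane_axes, drop = FALSE]^2))
      counts <- graphics::hist(r[r < r_lim], breaks = breaks,
                               plot = FALSE)$counts
    }
    vols <- pi * diff(breaks^2) * 2 * s
    list(counts = counts, vols = vols, breaks = breaks)
  }

  r_perp <- min(box[1], box[2]) / 2
  pp <- planar(3, c(1, 2), r_perp)
  perp <- new_density_profile("perpendicular", pp$breaks, pp$counts,
                              pp$vols, bin_width)

  r_par <- min(box) / 2
  px <- planar(1, c(2, 3), r_par)
  py <- planar(2, c(1, 3), r_par)
  par <- new_density_profile("parallel", px$breaks,
                             (px$counts + py$counts) / 2,
                             px$vols, bin_width)
  list(perpendicular = perp, parallel = par)
}

#' Time-averaged radial profile of a trajectory
#'
#' For each snapshot in the analysis window the largest cluster and its
#' centre of mass are recomputed, shell counts accumulated, and the summed
#' counts divided by the summed shell volumes.
#'
#' @param dump a `trajectory_dump`.
#' @param bin_width shell thickness.
#' @param cluster_cutoff linkage distance for [largest_cluster()].
#' @param directional logical; also accumulate directional profiles.
#' @param slab_half_thickness passed to [directional_profiles()].
#' @param r_max outermost isotropic-profile radius; default reaches the box
#'   corners (shells clipped by Monte-Carlo volumes).
#' @return a `density_profile`, or when `directional` a list
#'   `(isotropic, perpendicular, parallel)`.
#' @export
profile_from_dump <- function(dump, bin_width = 0.5, cluster_cutoff = 1.5,
                              directional = FALSE, slab_half_thickness = 1,
                              r_max = NULL) {
  snaps <- analysis_snapshots(dump)
  box <- dump$params$box
  # reach into the box corners by default: the outer shells (clipped to the
  # box by Monte-Carlo volumes) sample pure gas even when the force
  # elongates the cluster along z
  if (is.null(r_max)) r_max <- sqrt(sum((box / 2)^2)) - bin_width
  acc <- NULL
  for (st in snaps) {
    cl <- largest_cluster(st, cluster_cutoff = cluster_cutoff, box = box)
    iso <- radial_density_profile(st, cl$com, bin_width = bin_width,
                                  box = box, r_max = r_max)
    if (is.null(acc)) {
      acc <- list(iso = iso, n = 1)
      if (directional) {
        dp <- directional_profiles(st, cl$com, slab_half_thickness,
                                   bin_width, box = box)
        acc$perp <- dp$perpendicular
        acc$par <- dp$parallel
      }
    } else {
      acc$iso$counts <- acc$iso$counts + iso$counts
      acc$n <- acc$n + 1
      if (directional) {
        dp <- directional_profiles(st, cl$com, slab_half_thickness,
                                   bin_width, box = box)
        acc$perp$counts <- acc$perp$counts + dp$perpendicular$counts
        acc$par$counts <- acc$par$counts + dp$parallel$counts
      }
    }
  }
  finish <- function(p, n) {
    p$rho <- p$counts / (p$volumes * n)
    p
  }
  iso <- finish(acc$iso, acc$n)
  if (!directional) return(iso)
  list(isotropic = iso,
       perpendicular = finish(acc$perp, acc$n),
       parallel = finish(acc$par, acc$n))
}
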