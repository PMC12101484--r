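# moving-average smoother; width 1 returns the input unchanged
smooth_ma <- function(y, width = 3) {
  if (width <= 1) return(y)
  n <- length(y)
  out <- numeric(n)
  h <- floor(width / 2)
  for (i in seq_len(n)) {
    lo <- max(1, i - h)
    hi <- min(n, i + h)
    out[i] <- mean(y[lo:hi])
  }
  out
}

# central-difference derivative on a (possibly non-uniform) grid
central_deriv <- function(r, rho) {
  n <- length(r)
  d <- numeric(n)
  if (n < 3) return(d)
  d[2:(n - 1)] <- (rho[3:n] - rho[1:(n - 2)]) / (r[3:n] - r[1:(n - 2)])
  d[1] <- (rho[2] - rho[1]) / (r[2] - r[1])
  d[n] <- (rho[n] - rho[n - 1]) / (r[n] - r[n - 1])
  d
}

# contiguous run of TRUE containing index i (or integer(0))
run_containing <- function(mask, i) {
  if (!mask[i]) return(integer(0))
  lo <- i
  while (lo > 1 && mask[lo - 1]) lo <- lo - 1
  hi <- i
  while (hi < length(mask) && mask[hi + 1]) hi <- hi + 1
  lo:hi
}

#' Coexisting-phase densities from a sigmoidal radial profile
#'
#' The profile is smoothed with a moving average, differentiated by central
#' differences, and bins where the derivative magnitude falls below
#' `deriv_frac` of its maximum are declared plateau bins.  The dense-phase
#' density \eqn{\rho_{den}} is the mean raw density over the inner plateau
#' (the low-\eqn{r} run), the saturation density \eqn{\rho_{sat}} the mean
#' over the outer plateau (the large-\eqn{r} run).  A profile whose
#' plateaus are indistinguishable (ratio below `min_ratio`) is reported as
#' single-phase rather than an error.
#'
#' @param profile a `density_profile` with at least 10 bins.
#' @param smooth moving-average width in bins.
#' @param deriv_frac plateau threshold as a fraction of the maximum
#'   derivative magnitude.
#' @param min_ratio minimum \eqn{\rho_{den}/\rho_{sat}} for the two-phase
#'   flag.
#' @return list with `rho_den`, `rho_sat`, `two_phase` flag, and the
#'   plateau bin indices `inner_bins`, `outer_bins`.
#' @export
coexistence_densities <- function(profile, smooth = 3, deriv_frac = 0.1,
                                  min_ratio = 2) {
  stopifnot(inherits(profile, "density_profile"))
  n <- length(profile$r)
  if (n < 10) stop("profile must have at least 10 bins")
  # volume-weighted smoothing: pool counts over pooled shell volumes, so
  # sparsely sampled (tiny-volume) central shells cannot spike the profile;
  # on unit-weight analytic profiles this reduces to the plain average
  rho_s <- smooth_ma(profile$rho * profile$volumes, smooth) /
    smooth_ma(profile$volumes, smooth)
  d <- central_deriv(profile$r, rho_s)
  dmax <- max(abs(d))
  plateau <- abs(d) <= deriv_frac * dmax
  # inner plateau: the run holding the density maximum (robust against
  # sparsely sampled central shells); outer: the run holding the last bin.
  # A drifting or diffuse cluster can leave the dense arm gently sloping
  # everywhere (no run contains the maximum): fall back to the dense core,
  # the contiguous bins around the maximum with at least 80% of it.
  # anchor only on bins large enough to estimate a density: the innermost
  # shells of a radial profile hold a handful of beads and their Poisson
  # noise must not pick the maximum (analytic fixtures with symbolic unit
  # volumes keep all bins)
  eligible <- profile$volumes >= 15
  if (!any(eligible)) eligible <- rep(TRUE, n)
  imax <- which(eligible)[which.max(rho_s[eligible])]
  inner <- run_containing(plateau, imax)
  if (length(inner) == 0)
    inner <- run_containing(rho_s >= 0.8 * rho_s[imax], imax)
  outer <- run_containing(plateau, n)
  if (length(outer) == 0) {
    last <- rev(which(plateau))[1]
    outer <- if (is.na(last)) n else run_containing(plateau, last)
  }
  w <- profile$volumes
  rho_den <- stats::weighted.mean(profile$rho[inner], w[inner])
  rho_sat <- stats::weighted.mean(profile$rho[outer], w[outer])
  distinct <- !identical(inner, outer)
  two_phase <- distinct && is.finite(rho_den) && is.finite(rho_sat) &&
    rho_den > min_ratio * max(rho_sat, 0) && dmax > 0
  if (!two_phase && !distinct) {
    m <- mean(profile$rho[plateau])
    rho_den <- m
    rho_sat <- m
  }
  list(rho_den = rho_den, rho_sat = rho_sat, two_phase = two_phase,
       inner_bins = inner, outer_bins = outer)
}

#' Interfacial width from the profile derivative
#'
#' The interface is the contiguous region around the steepest-descent bin
#' where the derivative magnitude exceeds `deriv_frac` of its maximum; the
#' width is the spanned distance \eqn{r_{max} - r_{min}}.  The derivative
#' in the dense and dilute plateaus is (near) zero, so the region bounds
#' mark where the density transition begins and ends.
#'
#' @param profile a two-phase `density_profile`.
#' @param smooth moving-average width (default 1: time-averaged profiles
#'   are already smooth, and central differences regularise bin noise).
#' @param deriv_frac threshold fraction of the maximum derivative
#'   magnitude.
#' @return width in \eqn{\sigma}.
#' @export
interfacial_width <- function(profile, smooth = 1, deriv_frac = 0.1) {
  stopifnot(inherits(profile, "density_profile"))
  width_from_points(profile$r, profile$rho, smooth, deriv_frac)
}

width_from_points <- function(r, rho, smooth = 1, deriv_frac = 0.1) {
  d <- central_deriv(r, smooth_ma(rho, smooth))
  i0 <- which.min(d) # steepest descent (dense -> dilute)
  if (!is.finite(d[i0]) || d[i0] >= 0 || max(abs(d)) == 0)
    stop("undefined width: profile has no descending interface")
  above <- abs(d) > deriv_frac * max(abs(d))
  reg <- run_containing(above, i0)
  if (length(reg) == 0) stop("undefined width: no interface region")
  w <- r[reg[length(reg)]] - r[reg[1]]
  # resolution floor: an interface sharper than one bin reports one bin
  max(w, stats::median(diff(r)))
}

#' Leave-one-out bootstrap of the interfacial width
#'
#' Each trial removes one uniformly chosen profile point and recomputes
#' [interfacial_width()] on the remaining points (the derivative handles
#' the non-uniform grid).  Trials in which the deletion destroys the
#' interface are skipped but counted.
#'
#' @param profile a two-phase `density_profile`.
#' @param n_trials number of bootstrap trials.
#' @param seed integer seed; results are reproducible given the seed.
#' @param smooth,deriv_frac passed to the width estimator.
#' @return list with `mean`, `sd`, `widths` (per successful trial),
#'   `n_trials`, `n_failed`.
#' @export
bootstrap_width <- function(profile, n_trials = 1000, seed = 1,
                            smooth = 1, deriv_frac = 0.1) {
  stopifnot(inherits(profile, "density_profile"))
  n <- length(profile$r)
  drop_idx <- with_seed(seed, sample.int(n, n_trials, replace = TRUE))
  widths <- rep(NA_real_, n_trials)
  for (t in seq_len(n_trials)) {
    keep <- setdiff(seq_len(n), drop_idx[t])
    widths[t] <- tryCatch(
      width_from_points(profile$r[keep], profile$rho[keep],
                        smooth, deriv_frac),
      error = function(e) NA_real_)
  }
  ok <- widths[!is.na(widths)]
  if (length(ok) == 0) stop("undefined width in every bootstrap trial")
  list(mean = mean(ok), sd = stats::sd(ok), widths = ok,
       n_trials = n_trials, n_failed = sum(is.na(widths)))
}
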