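#' Joint probability density of speeds and angles
#'
#' A normalised 2D histogram: the mass over all cells sums to 1.
#'
#' @param speeds,angles paired numeric vectors; pairs with an `NA` member
#'   are dropped.
#' @param speed_bins,angle_bins either a bin count or an explicit vector
#'   of bin edges.
#' @return list with matrix `density` (speed bins x angle bins),
#'   `speed_edges`, `angle_edges`, and `n` (pairs used).
#' @export
joint_density <- function(speeds, angles, speed_bins = 20, angle_bins = 18) {
  keep <- !is.na(speeds) & !is.na(angles)
  s <- speeds[keep]
  a <- angles[keep]
  if (length(s) == 0) stop("no defined (speed, angle) pairs")
  se <- make_edges(s, speed_bins)
  ae <- make_edges(a, angle_bins)
  si <- bin_index(s, se)
  ai <- bin_index(a, ae)
  m <- matrix(0, length(se) - 1, length(ae) - 1)
  for (k in seq_along(si)) m[si[k], ai[k]] <- m[si[k], ai[k]] + 1
  list(density = m / sum(m), speed_edges = se, angle_edges = ae,
       n = length(s))
}

make_edges <- function(x, bins) {
  if (length(bins) > 1) return(sort(bins))
  rng <- range(x)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  seq(rng[1], rng[2], length.out = bins + 1)
}

bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(i, 1L), length(edges) - 1L)
}

#' Speed-conditioned condensate area distributions
#'
#' Each spot is assigned to a speed interval by its instantaneous speed;
#' a normalised area histogram on a shared set of bin edges is returned
#' per interval.  Empty intervals are flagged (and should be excluded from
#' divergence comparisons).
#'
#' @param tracks tibble with columns `track`, `t`, `x`, `y`, `area` (one
#'   row per spot).
#' @param speed_intervals matrix/data.frame with columns `lo`, `hi`
#'   (non-overlapping), or `NULL` for quartiles of the pooled speed
#'   distribution.
#' @param area_bins bin count or explicit shared edges for the area
#'   histograms.
#' @return list with `intervals` (tibble lo/hi/n/empty), `edges`, and
#'   `histograms` (list of normalised vectors, `NULL` where empty).
#' @export
area_distributions_by_speed <- function(tracks, speed_intervals = NULL,
                                        area_bins = 20) {
  stopifnot("area" %in% names(tracks))
  per <- lapply(split(tracks, tracks$track), function(tr) {
    tr <- tr[order(tr$t), ]
    if (nrow(tr) < 2) return(NULL)
    sa <- speeds_and_angles(tr)
    tibble::tibble(speed = sa$speed, area = tr$area[-nrow(tr)])
  })
  spots <- do.call(rbind, per[!vapply(per, is.null, TRUE)])
  spots <- spots[!is.na(spots$speed) & !is.na(spots$area), ]
  if (is.null(speed_intervals)) {
    q <- stats::quantile(spots$speed, c(0, 0.25, 0.5, 0.75, 1))
    speed_intervals <- data.frame(lo = q[-5], hi = q[-1])
  }
  speed_intervals <- as.data.frame(speed_intervals)
  edges <- make_edges(spots$area, area_bins)
  hists <- vector("list", nrow(speed_intervals))
  n_in <- integer(nrow(speed_intervals))
  for (i in seq_len(nrow(speed_intervals))) {
    hi_closed <- i == nrow(speed_intervals)
    sel <- spots$speed >= speed_intervals$lo[i] &
      (if (hi_closed) spots$speed <= speed_intervals$hi[i]
       else spots$speed < speed_intervals$hi[i])
    n_in[i] <- sum(sel)
    if (n_in[i] > 0) {
      counts <- tabulate(bin_index(spots$area[sel], edges),
                         nbins = length(edges) - 1)
      hists[[i]] <- counts / sum(counts)
    }
  }
  list(intervals = tibble::tibble(lo = speed_intervals$lo,
                                  hi = speed_intervals$hi,
                                  n = n_in, empty = n_in == 0),
       edges = edges, histograms = hists)
}

#' Kullback-Leibler divergence between two histograms
#'
#' \deqn{D(P\|Q) = \sum_i P_i \ln(P_i/Q_i)} after adding `pseudocount` to
#' every bin of both histograms and renormalising.  With `pseudocount = 0`
#' and \eqn{Q_i = 0} where \eqn{P_i > 0} the divergence is infinite and
#' flagged.  `D >= 0`, with equality iff the regularised distributions are
#' identical.
#'
#' @param P,Q numeric histograms on identical bin edges (normalised or
#'   raw counts).
#' @param pseudocount non-negative regulariser added per bin.
#' @param edges_P,edges_Q optional bin edges; when both are supplied they
#'   must match exactly.
#' @param base `"nats"` (natural log, default) or `"bits"`.
#' @return divergence (named numeric with attribute `infinite_support`
#'   when the unregularised prior has empty support under P).
#' @export
kl_divergence <- function(P, Q, pseudocount = 1e-6,
                          edges_P = NULL, edges_Q = NULL,
                          base = c("nats", "bits")) {
  base <- match.arg(base)
  if (!is.null(edges_P) && !is.null(edges_Q) &&
      !isTRUE(all.equal(edges_P, edges_Q)))
    stop("P and Q are defined on different bin edges")
  if (length(P) != length(Q)) stop("P and Q must have the same number of bins")
  stopifnot(pseudocount >= 0)
  p <- P + pseudocount
  q <- Q + pseudocount
  p <- p / sum(p)
  q <- q / sum(q)
  sup <- p > 0
  flag <- any(sup & q == 0)
  d <- if (flag) Inf else sum(p[sup] * log(p[sup] / q[sup]))
  if (base == "bits") d <- d / log(2)
  structure(d, infinite_support = flag)
}
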