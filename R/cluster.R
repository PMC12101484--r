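#' Largest cluster of a system state
#'
#' Beads are linked when their minimum-image distance is at most
#' `cluster_cutoff` (default 1.5 \eqn{\sigma}, the first Lennard-Jones
#' coordination shell); connected components are found by union-find and
#' the component with the most beads is returned.  Chains are assigned to
#' the cluster when the majority of their beads belong to it.  The centre
#' of mass is computed with a periodic (circular-mean) unwrapping so it is
#' well defined even when the cluster straddles a box boundary.
#'
#' @param state a `system_state`, or an N x 3 position matrix (then `box`
#'   must be given).
#' @param cluster_cutoff linkage distance in \eqn{\sigma}.
#' @param box numeric length-3 box lengths; taken from `params` of the
#'   calling context when `state` is a `system_state` built by this package.
#' @return list with `chains` (integer chain ids), `beads` (bead indices of
#'   the largest component), `com` (length-3 centre of mass), `labels`
#'   (per-bead component labels) and `n_components`.
#' @export
largest_cluster <- function(state, cluster_cutoff = 1.5, box = NULL) {
  if (inherits(state, "system_state")) {
    pos <- state$positions
    chain <- state$chain_id
  } else {
    pos <- state
    chain <- NULL
  }
  if (is.null(box)) box <- infer_box(pos)
  if (is.null(dim(pos)) || nrow(pos) == 0) stop("empty state: no beads to cluster")
  stopifnot(cluster_cutoff > 0)
  labels <- cpp_cluster_labels(pos, box, cluster_cutoff)
  counts <- tabulate(labels)
  big <- which.max(counts)
  beads <- which(labels == big)
  chains <- integer(0)
  if (!is.null(chain)) {
    # chain belongs to the cluster when the majority of its beads do
    in_big <- tapply(labels == big, chain, mean)
    chains <- as.integer(names(in_big))[in_big > 0.5]
  }
  com <- periodic_com(pos[beads, , drop = FALSE], box)
  list(chains = chains, beads = beads, com = com,
       labels = labels, n_components = length(counts))
}

# box lengths for a bare position matrix: smallest centred box that
# contains the data (positions are assumed wrapped already)
infer_box <- function(pos) {
  2 * apply(abs(pos), 2, max) + 1e-9
}

#' Periodic centre of mass
#'
#' Circular-mean unwrapping: each coordinate is mapped to an angle on a
#' circle of circumference equal to the box length; the centre of mass is
#' the angle of the mean resultant vector mapped back to a coordinate.
#'
#' @param pos n x 3 matrix of wrapped positions.
#' @param box numeric length-3 box lengths.
#' @return length-3 centre of mass inside the box.
#' @export
periodic_com <- function(pos, box) {
  vapply(1:3, function(d) {
    theta <- 2 * pi * pos[, d] / box[d]
    atan2(mean(sin(theta)), mean(cos(theta))) * box[d] / (2 * pi)
  }, numeric(1))
}

# minimum-image displacement between two position sets
min_image <- function(d, box) {
  for (k in seq_along(box)) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# per-chain centre of mass, unwrapping each chain by walking its bonds
chain_coms <- function(state, box) {
  pos <- state$positions
  nch <- length(state$active)
  bpc <- nrow(pos) / nch
  out <- matrix(0, nch, 3)
  for (c in seq_len(nch)) {
    idx <- ((c - 1) * bpc + 1):(c * bpc)
    p <- pos[idx, , drop = FALSE]
    if (bpc > 1) {
      steps <- min_image(diff(p), box)
      cum <- apply(steps, 2, cumsum)
      if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
      p <- sweep(rbind(rep(0, 3), cum), 2, p[1, ], "+")
    }
    com <- colMeans(p)
    out[c, ] <- com - box * round(com / box)
  }
  out
}
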