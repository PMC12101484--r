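#' Per-phase mean chain speeds
#'
#' For every pair of consecutive snapshots, each chain's centre-of-mass
#' displacement (minimum image) is divided by the elapsed time, giving a
#' speed.  Chains in the largest cluster of the earlier snapshot are
#' labelled dense, the rest dilute; speeds are averaged within each phase
#' and then over snapshot pairs.  Speeds are reported in
#' \eqn{\sigma/\tau'} with \eqn{\tau' = 200\tau} (the production snapshot
#' spacing of the full protocol).
#'
#' @param dump a `trajectory_dump` with at least 2 snapshots.
#' @param cluster_cutoff linkage distance for [largest_cluster()].
#' @param tau_prime duration of the velocity unit in \eqn{\tau}.
#' @param analysis_start first step analysed (default from the dump).
#' @return list with `dense`, `dilute` (mean speeds in \eqn{\sigma/\tau'})
#'   and the per-pair tibble `pairs`.
#' @export
phase_velocities <- function(dump, cluster_cutoff = 1.5, tau_prime = 200,
                             analysis_start = dump$params$analysis_start) {
  snaps <- analysis_snapshots(dump, analysis_start)
  if (length(snaps) < 2) stop("need at least 2 snapshots to measure velocities")
  box <- dump$params$box
  dt <- dump$params$dt
  dense_m <- dilute_m <- numeric(0)
  rows <- list()
  com_prev <- chain_coms(snaps[[1]], box)
  for (k in 2:length(snaps)) {
    com_now <- chain_coms(snaps[[k]], box)
    elapsed <- (snaps[[k]]$step - snaps[[k - 1]]$step) * dt / tau_prime
    disp <- min_image(com_now - com_prev, box)
    speed <- sqrt(rowSums(disp^2)) / elapsed
    cl <- largest_cluster(snaps[[k - 1]], cluster_cutoff = cluster_cutoff,
                          box = box)
    dense <- seq_len(nrow(com_now)) %in% cl$chains
    dense_m <- c(dense_m, if (any(dense)) mean(speed[dense]) else NA_real_)
    dilute_m <- c(dilute_m, if (any(!dense)) mean(speed[!dense]) else NA_real_)
    rows[[k - 1]] <- tibble::tibble(pair = k - 1,
                                    dense = dense_m[length(dense_m)],
                                    dilute = dilute_m[length(dilute_m)])
    com_prev <- com_now
  }
  list(dense = mean(dense_m, na.rm = TRUE),
       dilute = if (all(is.na(dilute_m))) NA_real_ else
         mean(dilute_m, na.rm = TRUE),
       pairs = do.call(rbind, rows))
}

#' Active/passive partitioning between the phases
#'
#' Two normalisations are reported for each label class: per total chains
#' in the system and per chains of that class, since both conventions are
#' in common use for mixed active/passive systems.
#'
#' @param state a `system_state`.
#' @param cluster result of [largest_cluster()] on `state` (computed when
#'   omitted).
#' @param cluster_cutoff linkage distance if the cluster must be computed.
#' @return list: `active_in_dense_per_total`, `active_in_dense_per_class`,
#'   `passive_in_dense_per_total`, `passive_in_dense_per_class` (the two
#'   passive entries are `NA` when the system has no passive chains).
#' @export
partition_fractions <- function(state, cluster = NULL, cluster_cutoff = 1.5) {
  stopifnot(inherits(state, "system_state"))
  if (is.null(cluster))
    cluster <- largest_cluster(state, cluster_cutoff = cluster_cutoff,
                               box = infer_box(state$positions))
  act <- state$active
  n_tot <- length(act)
  in_dense <- seq_len(n_tot) %in% cluster$chains
  n_act <- sum(act)
  n_pas <- n_tot - n_act
  list(active_in_dense_per_total = sum(in_dense & act) / n_tot,
       active_in_dense_per_class =
         if (n_act > 0) sum(in_dense & act) / n_act else NA_real_,
       passive_in_dense_per_total =
         if (n_pas > 0) sum(in_dense & !act) / n_tot else NA_real_,
       passive_in_dense_per_class =
         if (n_pas > 0) sum(in_dense & !act) / n_pas else NA_real_)
}

#' Cluster-based gas (saturation) density of one snapshot
#'
#' The dilute-phase density measured directly from the cluster criterion:
#' beads of chains outside the largest cluster, divided by the gas volume
#' (box volume minus the cluster volume `n_cluster_beads / rho_den`).
#' Immune to the dense phase's shape: the profile-based outer-plateau
#' estimate reads high when a strong directional force elongates the
#' cluster into the far field, whereas the cluster criterion does not.
#'
#' @param state a `system_state`.
#' @param cluster result of [largest_cluster()] (computed when omitted).
#' @param rho_den dense-phase density used to deduct the cluster volume
#'   (a few percent correction; `NULL` uses 0.6).
#' @param cluster_cutoff linkage distance if the cluster must be computed.
#' @param box box lengths (taken from positions when omitted).
#' @return gas number density in beads/\eqn{\sigma^3}.
#' @export
gas_density <- function(state, cluster = NULL, rho_den = NULL,
                        cluster_cutoff = 1.5, box = NULL) {
  stopifnot(inherits(state, "system_state"))
  if (is.null(box)) box <- infer_box(state$positions)
  if (is.null(cluster))
    cluster <- largest_cluster(state, cluster_cutoff = cluster_cutoff,
                               box = box)
  # a failed profile estimate would make the deducted cluster volume
  # nonsensical; outside the physically plausible melt range fall back to
  # the nominal dense-phase density
  if (is.null(rho_den) || !is.finite(rho_den) || rho_den < 0.2 ||
      rho_den > 1.5)
    rho_den <- 0.6
  n_gas_beads <- sum(!(state$chain_id %in% cluster$chains))
  v_gas <- prod(box) - length(cluster$beads) / rho_den
  n_gas_beads / max(v_gas, 1e-9)
}

#' Full coexistence analysis of one trajectory
#'
#' Time-averaged isotropic and directional profiles, coexisting densities,
#' interfacial widths with their leave-one-out bootstrap, per-phase
#' velocities, and partition fractions (averaged over the analysis
#' snapshots).
#'
#' @param dump a `trajectory_dump`.
#' @param bin_width,cluster_cutoff,slab_half_thickness profile settings.
#' @param n_bootstrap bootstrap trials for the width errors (0 disables).
#' @param seed bootstrap seed.
#' @return object of class `coexistence_result`; `rho_sat` is the
#'   cluster-based gas density (see [gas_density()]) and
#'   `rho_sat_profile` the radial-profile outer-plateau estimate.
#' @export
analyze_coexistence <- function(dump, bin_width = 0.5, cluster_cutoff = 1.5,
                                slab_half_thickness = 1, n_bootstrap = 1000,
                                seed = 1) {
  snaps <- analysis_snapshots(dump)
  box <- dump$params$box
  dt <- dump$params$dt
  r_max <- sqrt(sum((box / 2)^2)) - bin_width
  # one cluster pass shared by profiles, gas density, partitioning, velocities
  clusters <- lapply(snaps, function(st)
    largest_cluster(st, cluster_cutoff = cluster_cutoff, box = box))

  acc <- NULL
  for (k in seq_along(snaps)) {
    st <- snaps[[k]]
    com <- clusters[[k]]$com
    iso <- radial_density_profile(st, com, bin_width = bin_width,
                                  box = box, r_max = r_max)
    dp <- directional_profiles(st, com, slab_half_thickness, bin_width,
                               box = box)
    if (is.null(acc)) {
      acc <- list(iso = iso, perp = dp$perpendicular, par = dp$parallel,
                  n = 1)
    } else {
      acc$iso$counts <- acc$iso$counts + iso$counts
      acc$perp$counts <- acc$perp$counts + dp$perpendicular$counts
      acc$par$counts <- acc$par$counts + dp$parallel$counts
      acc$n <- acc$n + 1
    }
  }
  finish <- function(p) {
    p$rho <- p$counts / (p$volumes * acc$n)
    p
  }
  prof <- list(isotropic = finish(acc$iso), perpendicular = finish(acc$perp),
               parallel = finish(acc$par))
  cd <- coexistence_densities(prof$isotropic)

  # primary rho_sat: cluster-based gas density, averaged over snapshots
  # (the profile outer plateau is kept as rho_sat_profile; it reads high
  # when the force elongates the cluster into the far field)
  gas <- vapply(seq_along(snaps), function(k)
    gas_density(snaps[[k]], cluster = clusters[[k]], rho_den = cd$rho_den,
                box = box), numeric(1))

  safe_width <- function(p) tryCatch(interfacial_width(p),
                                     error = function(e) NA_real_)
  w_perp <- safe_width(prof$perpendicular)
  w_par <- safe_width(prof$parallel)
  boot <- function(p) {
    if (n_bootstrap <= 0) return(list(mean = NA_real_, sd = NA_real_))
    tryCatch(bootstrap_width(p, n_trials = n_bootstrap, seed = seed),
             error = function(e) list(mean = NA_real_, sd = NA_real_))
  }
  b_perp <- boot(prof$perpendicular)
  b_par <- boot(prof$parallel)

  # per-phase speeds from chain-COM displacements between snapshot pairs
  tau_prime <- 200
  dense_m <- dilute_m <- numeric(0)
  if (length(snaps) >= 2) {
    com_prev <- chain_coms(snaps[[1]], box)
    for (k in 2:length(snaps)) {
      com_now <- chain_coms(snaps[[k]], box)
      elapsed <- (snaps[[k]]$step - snaps[[k - 1]]$step) * dt / tau_prime
      disp <- min_image(com_now - com_prev, box)
      speed <- sqrt(rowSums(disp^2)) / elapsed
      dense <- seq_len(nrow(com_now)) %in% clusters[[k - 1]]$chains
      dense_m <- c(dense_m, if (any(dense)) mean(speed[dense]) else NA_real_)
      dilute_m <- c(dilute_m,
                    if (any(!dense)) mean(speed[!dense]) else NA_real_)
      com_prev <- com_now
    }
  }
  parts <- lapply(seq_along(snaps), function(k)
    partition_fractions(snaps[[k]], clusters[[k]]))
  pmean <- function(field) {
    v <- vapply(parts, `[[`, 0, field)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  mean_or_na <- function(v) if (length(v) == 0 || all(is.na(v))) NA_real_
    else mean(v, na.rm = TRUE)
  res <- list(f_act = dump$params$f_act,
              f_passive = dump$params$f_passive,
              rho_den = cd$rho_den, rho_sat = mean(gas),
              rho_sat_profile = cd$rho_sat,
              two_phase = cd$two_phase,
              width_parallel = w_par, width_perpendicular = w_perp,
              width_parallel_boot = c(mean = b_par$mean, sd = b_par$sd),
              width_perpendicular_boot = c(mean = b_perp$mean, sd = b_perp$sd),
              speed_dense = mean_or_na(dense_m),
              speed_dilute = mean_or_na(dilute_m),
              active_in_dense_per_total = pmean("active_in_dense_per_total"),
              active_in_dense_per_class = pmean("active_in_dense_per_class"),
              passive_in_dense_per_total = pmean("passive_in_dense_per_total"),
              passive_in_dense_per_class = pmean("passive_in_dense_per_class"),
              profiles = prof)
  class(res) <- "coexistence_result"
  res
}

#' @export
print.coexistence_result <- function(x, ...) {
  cat(sprintf("coexistence_result (F_act = %g, f_passive = %g)\n",
              x$f_act, x$f_passive))
  cat(sprintf("  rho_den = %.4g, rho_sat = %.4g (two-phase: %s)\n",
              x$rho_den, x$rho_sat, x$two_phase))
  cat(sprintf("  widths: parallel %.3g, perpendicular %.3g sigma\n",
              x$width_parallel, x$width_perpendicular))
  cat(sprintf("  speeds (sigma/tau'): dense %.3g, dilute %.3g\n",
              x$speed_dense, x$speed_dilute))
  invisible(x)
}
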