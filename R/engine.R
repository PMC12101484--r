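#' Construct a system state
#'
#' @param positions N x 3 matrix of bead coordinates in \eqn{\sigma},
#'   wrapped into the periodic box centred on the origin.
#' @param velocities N x 3 matrix in \eqn{\sigma/\tau}.
#' @param params a [sim_params()] object.
#' @param step integer step counter attached to the state.
#' @return object of class `system_state`: positions, velocities, per-bead
#'   `chain_id`, per-bead `head` flag (first bead of each chain), per-chain
#'   `active` flag and the step counter.
#' @export
system_state <- function(positions, velocities, params, step = 0) {
  n <- params$n_chains * params$beads_per_chain
  stopifnot(nrow(positions) == n, nrow(velocities) == n)
  st <- list(positions = positions, velocities = velocities,
             chain_id = rep(seq_len(params$n_chains),
                            each = params$beads_per_chain),
             head = rep(c(TRUE, rep(FALSE, params$beads_per_chain - 1)),
                        params$n_chains),
             active = active_flags(params),
             step = step)
  class(st) <- "system_state"
  st
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("system_state: %d beads in %d chains (%d active), step %g\n",
              nrow(x$positions), length(x$active), sum(x$active), x$step))
  invisible(x)
}

# run `code` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# random-walk chain placement: starting points uniform in the central half
# of the box, successive beads at distance 0.97 sigma in random directions
rw_chains <- function(params) {
  n <- params$n_chains * params$beads_per_chain
  pos <- matrix(0, n, 3)
  half <- params$box / 4
  for (c in seq_len(params$n_chains)) {
    base <- (c - 1) * params$beads_per_chain
    p <- stats::runif(3, -half, half)
    pos[base + 1, ] <- p
    if (params$beads_per_chain > 1) {
      for (k in 2:params$beads_per_chain) {
        u <- stats::rnorm(3)
        p <- p + 0.97 * u / sqrt(sum(u^2))
        pos[base + k, ] <- p
      }
    }
  }
  # wrap into the box
  for (d in 1:3) pos[, d] <- pos[, d] - params$box[d] * round(pos[, d] / params$box[d])
  pos
}

# advance a state with the compiled BAOAB integrator
run_engine <- function(state, params, nsteps, dump_every = 0, f_act = 0,
                       bias_k = 0, seed = 1, want_dumps = FALSE,
                       thermo_every = 0, force_clamp = -1) {
  par <- engine_par(params, force_clamp = force_clamp)
  cpp_simulate(state$positions, state$velocities, state$chain_id,
               state$active, par, nsteps, dump_every, f_act, bias_k,
               seed, want_dumps, thermo_every, state$step)
}

#' Advance a system state by Langevin dynamics
#'
#' One call to the compiled BAOAB splitting of underdamped Langevin
#' dynamics (half kick, half drift, exact Ornstein-Uhlenbeck velocity
#' update with friction \eqn{\gamma = m/\mathrm{damping}} at \eqn{k_BT = 1},
#' half drift, half kick).  With `damping = Inf` the thermostat is off and
#' the scheme is plain velocity-Verlet.
#'
#' @param state a `system_state`.
#' @param params a [sim_params()] object (`f_act` is taken from it).
#' @param nsteps number of time steps.
#' @param seed integer seed for the thermostat noise.
#' @param thermo_every if > 0, record kinetic/potential energy every this
#'   many steps (returned as attribute `thermo`).
#' @return the advanced `system_state`; attribute `thermo` holds the energy
#'   trace when requested.
#' @export
langevin_step <- function(state, params, nsteps = 1, seed = params$seed,
                          thermo_every = 0) {
  res <- run_engine(state, params, nsteps, f_act = params$f_act,
                    seed = seed, thermo_every = thermo_every)
  out <- state
  out$positions <- res$positions
  out$velocities <- res$velocities
  out$step <- state$step + nsteps
  attr(out, "thermo") <- res$thermo
  out
}

#' Initialize a condensed starting configuration
#'
#' Chains are laid down as random walks with bond length just under
#' \eqn{\sigma}, overlaps are removed by a short force-capped push-off, and
#' a weak harmonic bias toward the box centre is applied to every bead for
#' `bias_steps` so the system assembles into a single dense phase.  The
#' bias is then removed.  Fails if the largest cluster holds fewer than 90%
#' of the chains afterwards.
#'
#' @param params a [sim_params()] object.
#' @param cluster_cutoff bead-bead linkage distance used for the final
#'   single-cluster check, in \eqn{\sigma}.
#' @return a condensed `system_state` at step 0.
#' @export
initialize_condensed <- function(params, cluster_cutoff = 1.5) {
  validate_sim_params(params)
  pos <- with_seed(params$seed, rw_chains(params))
  st <- system_state(pos, matrix(0, nrow(pos), 3), params, step = 0)

  # force-capped push-off removes random-walk overlaps without blowing up:
  # small time step, strong damping, and a rising cap on the pair force
  # (the FENE restoring force is never capped, so bonds stay below R0)
  soft <- params
  soft$damping <- 0.1
  soft$dt <- 0.002
  for (k in seq_along(clamps <- c(5, 20, 100))) {
    res <- run_engine(st, soft, 2000, seed = params$seed * 1000 + k,
                      force_clamp = clamps[k])
    st$positions <- res$positions
    st$velocities <- res$velocities
  }

  if (params$bias_steps > 0) {
    res <- run_engine(st, params, params$bias_steps, f_act = 0,
                      bias_k = params$bias_k,
                      seed = params$seed * 1000 + 3)
    st$positions <- res$positions
    st$velocities <- res$velocities
  }
  st$step <- 0

  cl <- largest_cluster(st, cluster_cutoff = cluster_cutoff)
  frac <- length(cl$chains) / params$n_chains
  if (params$n_chains > 1 && frac <= 0.9)
    stop(sprintf(paste0("initialization failure: largest cluster holds only ",
                        "%.0f%% of chains after %g bias steps"),
                 100 * frac, params$bias_steps))
  st
}

#' Run the full simulation protocol
#'
#' [initialize_condensed()], then `total_steps` of Langevin dynamics with
#' the active force on, recording a snapshot every `dump_every` steps
#' (including step 0).  Deterministic given `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @param init optional pre-built initial `system_state` (skips
#'   initialization; used to share one condensed state across force values).
#' @return object of class `trajectory_dump`: `params`, vector `steps`, and
#'   list `snapshots` of `system_state`s.
#' @export
run_simulation <- function(params, init = NULL) {
  validate_sim_params(params)
  st <- if (is.null(init)) initialize_condensed(params) else init
  if (params$total_steps == 0) {
    dump <- list(params = params, steps = st$step, snapshots = list(st))
    class(dump) <- "trajectory_dump"
    return(dump)
  }
  res <- run_engine(st, params, params$total_steps,
                    dump_every = params$dump_every, f_act = params$f_act,
                    seed = params$seed * 1000 + 4, want_dumps = TRUE)
  snaps <- lapply(res$dumps, function(d) {
    s <- system_state(d$positions, d$velocities, params, step = d$step)
    s
  })
  dump <- list(params = params, steps = vapply(res$dumps, `[[`, 0, "step"),
               snapshots = snaps)
  class(dump) <- "trajectory_dump"
  dump
}

#' @export
print.trajectory_dump <- function(x, ...) {
  cat(sprintf("trajectory_dump: %d snapshots, steps %g..%g (every %g)\n",
              length(x$snapshots), min(x$steps), max(x$steps),
              x$params$dump_every))
  print(x$params)
  invisible(x)
}

#' Snapshots belonging to the analysis window
#'
#' @param dump a `trajectory_dump`.
#' @param analysis_start first step included (default from the dump's
#'   parameters: the last half of the production run).
#' @return list of `system_state` snapshots with `step >= analysis_start`.
#' @export
analysis_snapshots <- function(dump, analysis_start = dump$params$analysis_start) {
  keep <- dump$steps >= analysis_start
  if (!any(keep)) keep[length(keep)] <- TRUE
  dump$snapshots[keep]
}
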