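#' Simulation parameters for the active-polymer model
#'
#' Builds the full parameter set of the coarse-grained Langevin model in
#' reduced units (bead diameter \eqn{\sigma}, thermal energy \eqn{k_BT} and
#' bead mass all equal to 1, so the time unit is
#' \eqn{\tau = \sigma\sqrt{m/k_BT} = 1}).  Chains are flexible bead-spring
#' polymers: consecutive beads are bonded by a FENE spring, all bead pairs
#' interact through a truncated 12-6 Lennard-Jones potential, and the first
#' ("head") bead of every active chain feels a constant force `f_act` along
#' +z.  Passive chains (a fraction `f_passive` of the system) receive no
#' active force.
#'
#' The `"full"` scale is the full production protocol (650 chains of 25
#' beads in a 64 x 64 x 100 box, 5e7 steps with snapshots every 2e4 steps,
#' the last half analysed).  The `"small"` scale is a 100-chain twin in a
#' 32 x 32 x 50 box with a proportionally shortened schedule, sized so that
#' a force scan completes in minutes on one CPU while still maintaining
#' two coexisting phases.
#'
#' @param n_chains number of polymer chains.
#' @param beads_per_chain beads per chain.
#' @param box numeric length-3 box edge lengths in \eqn{\sigma}; coordinates
#'   span `[-box/2, box/2]` with periodic boundaries in all directions.
#' @param epsilon Lennard-Jones well depth in \eqn{k_BT}.
#' @param fene_K FENE spring constant in \eqn{\epsilon/\sigma^2}
#'   (so `fene_K = 100` with `epsilon = 0.40` gives \eqn{40\,k_BT/\sigma^2}).
#' @param fene_R0 FENE maximum bond extension in \eqn{\sigma}.
#' @param lj_cutoff Lennard-Jones truncation radius in \eqn{\sigma}.
#' @param shift_lj logical; shift the pair potential to zero at the cutoff
#'   (forces are unchanged). Default unshifted truncation.
#' @param bonded_lj logical; apply the Lennard-Jones pair interaction to
#'   directly bonded beads as well (the standard Kremer-Grest convention,
#'   which keeps FENE bonds at a finite rest length). Default `TRUE`.
#' @param dt integration time step in \eqn{\tau}.
#' @param damping Langevin damping time in \eqn{\tau}; the friction is
#'   \eqn{\gamma = m/\mathrm{damping}}. `Inf` disables the thermostat.
#' @param f_act magnitude of the constant head-bead force in
#'   \eqn{k_BT/\sigma}, applied along +z.
#' @param f_passive fraction of chains that are passive (no head force).
#' @param bias_steps steps of the initial centering bias used to assemble a
#'   single dense phase before production.
#' @param bias_k stiffness of the per-bead harmonic bias toward the box
#'   centre, in \eqn{\epsilon/\sigma^2}.
#' @param total_steps production steps after the bias is released.
#' @param dump_every snapshot interval in steps.
#' @param analysis_start first production step whose snapshots enter
#'   time-averaged analyses (default `total_steps/2`).
#' @param seed integer seed; every stochastic element of a run derives from it.
#' @param skin Verlet-list skin in \eqn{\sigma}.
#' @param scale `"full"` or `"small"`; presets applied before explicit
#'   arguments override them.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @export
sim_params <- function(n_chains = NULL, beads_per_chain = 25,
                       box = NULL, epsilon = 0.40,
                       fene_K = 100, fene_R0 = 1.5,
                       lj_cutoff = 2.5, shift_lj = FALSE, bonded_lj = TRUE,
                       dt = 0.01, damping = 0.50,
                       f_act = 0, f_passive = 0,
                       bias_steps = NULL, bias_k = 0.05,
                       total_steps = NULL, dump_every = NULL,
                       analysis_start = NULL, seed = 1L,
                       skin = 0.3, scale = c("full", "small")) {
  scale <- match.arg(scale)
  preset <- if (scale == "full") {
    list(n_chains = 650, box = c(64, 64, 100), bias_steps = 2e5,
         total_steps = 5e7, dump_every = 2e4)
  } else {
    list(n_chains = 100, box = c(32, 32, 50), bias_steps = 2e4,
         total_steps = 6e4, dump_every = 1e3)
  }
  if (is.null(n_chains)) n_chains <- preset$n_chains
  if (is.null(box)) box <- preset$box
  if (is.null(bias_steps)) bias_steps <- preset$bias_steps
  if (is.null(total_steps)) total_steps <- preset$total_steps
  if (is.null(dump_every)) dump_every <- preset$dump_every
  if (is.null(analysis_start)) analysis_start <- total_steps / 2

  p <- list(n_chains = as.integer(n_chains),
            beads_per_chain = as.integer(beads_per_chain),
            box = as.numeric(box), epsilon = epsilon, sigma = 1,
            fene_K = fene_K * epsilon,  # stored in kBT/sigma^2
            fene_K_eps = fene_K, fene_R0 = fene_R0,
            lj_cutoff = lj_cutoff, shift_lj = isTRUE(shift_lj),
            bonded_lj = isTRUE(bonded_lj),
            dt = dt, damping = damping,
            f_act = f_act, f_passive = f_passive,
            bias_steps = bias_steps, bias_k = bias_k * epsilon,
            bias_k_eps = bias_k,
            total_steps = total_steps, dump_every = dump_every,
            analysis_start = analysis_start, seed = as.integer(seed),
            skin = skin, scale = scale,
            force_clamp = -1, all_pairs = FALSE)
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

#' Validate simulation parameters
#'
#' @param p a `sim_params` object.
#' @return `p` invisibly; stops with a descriptive error on violation.
#' @export
validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(p$n_chains >= 1, "n_chains must be >= 1")
  chk(p$beads_per_chain >= 1, "beads_per_chain must be >= 1")
  chk(length(p$box) == 3 && all(p$box > 0), "box must be three positive lengths")
  chk(p$epsilon > 0, "epsilon must be > 0")
  chk(p$fene_K > 0, "fene_K must be > 0")
  chk(p$fene_R0 > p$sigma, "fene_R0 must exceed sigma")
  chk(p$lj_cutoff > 0, "lj_cutoff must be > 0")
  chk(p$dt > 0, "dt must be > 0")
  chk(!is.finite(p$damping) || p$dt < p$damping, "dt must be smaller than damping")
  chk(p$f_act >= 0, "f_act must be >= 0")
  chk(p$f_passive >= 0 && p$f_passive <= 1, "f_passive must lie in [0, 1]")
  chk(p$bias_steps >= 0, "bias_steps must be >= 0")
  chk(p$total_steps >= 0, "total_steps must be >= 0")
  chk(p$dump_every >= 1, "dump_every must be >= 1")
  chk(p$analysis_start <= p$total_steps, "analysis_start must not exceed total_steps")
  chk(p$skin > 0, "skin must be > 0")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("Active-polymer simulation parameters (%s scale)\n", x$scale))
  cat(sprintf("  %d chains x %d beads, box %g x %g x %g sigma\n",
              x$n_chains, x$beads_per_chain, x$box[1], x$box[2], x$box[3]))
  cat(sprintf("  epsilon = %g kBT, FENE K = %g eps/sigma^2 (R0 = %g), LJ cutoff %g%s\n",
              x$epsilon, x$fene_K_eps, x$fene_R0, x$lj_cutoff,
              if (x$shift_lj) " (shifted)" else ""))
  cat(sprintf("  dt = %g tau, damping = %g tau, F_act = %g kBT/sigma, f_passive = %g\n",
              x$dt, x$damping, x$f_act, x$f_passive))
  cat(sprintf("  %g bias + %g production steps, dumps every %g, analysis from %g, seed %d\n",
              x$bias_steps, x$total_steps, x$dump_every, x$analysis_start, x$seed))
  invisible(x)
}

# number of active chains under the fixed labeling convention: the first
# floor((1 - f_passive) * n_chains) chain ids are active, independent of seed
n_active_chains <- function(p) {
  as.integer(floor((1 - p$f_passive) * p$n_chains))
}

#' Per-chain active flags
#'
#' The first `floor((1 - f_passive) * n_chains)` chains (by id) are active;
#' the labeling is fixed for a whole run and independent of the seed.
#'
#' @param p a `sim_params` object.
#' @return logical vector of length `n_chains`.
#' @export
active_flags <- function(p) {
  seq_len(p$n_chains) <= n_active_chains(p)
}
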