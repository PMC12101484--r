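#' FENE bond energy
#'
#' Finitely extensible nonlinear elastic bond potential
#' \deqn{U(r) = -\tfrac{1}{2} K R_0^2 \ln\!\left(1 - (r/R_0)^2\right),}
#' which diverges as the bond length approaches its maximum extension
#' \eqn{R_0}.  `K` is taken from `params` in \eqn{k_BT/\sigma^2}.
#'
#' @param r bond length(s) in \eqn{\sigma}; must satisfy `0 <= r < R0`.
#' @param params a [sim_params()] object.
#' @return energy in \eqn{k_BT}.
#' @export
fene_energy <- function(r, params = sim_params()) {
  if (any(r < 0)) stop("bond length must be non-negative")
  if (any(r >= params$fene_R0))
    stop(sprintf("FENE bond overstretched: r = %g >= R0 = %g",
                 max(r), params$fene_R0))
  -0.5 * params$fene_K * params$fene_R0^2 * log1p(-(r / params$fene_R0)^2)
}

#' FENE bond force magnitude
#'
#' Analytic negative gradient of [fene_energy()],
#' \eqn{F(r) = -K r / (1 - (r/R_0)^2)} (negative = attractive, pulling the
#' bonded beads together).
#'
#' @inheritParams fene_energy
#' @return signed radial force in \eqn{k_BT/\sigma}.
#' @export
fene_force <- function(r, params = sim_params()) {
  if (any(r >= params$fene_R0))
    stop(sprintf("FENE bond overstretched: r = %g >= R0 = %g",
                 max(r), params$fene_R0))
  -params$fene_K * r / (1 - (r / params$fene_R0)^2)
}

#' Lennard-Jones pair energy
#'
#' Truncated 12-6 potential
#' \deqn{U(r) = 4\epsilon\left[(\sigma/r)^{12} - (\sigma/r)^6\right]}
#' for \eqn{r \le r_c}, zero beyond.  By default the truncation is plain
#' (unshifted); with `params$shift_lj` the potential is shifted to zero at
#' the cutoff.
#'
#' @param r separation(s) in \eqn{\sigma}; must be positive.
#' @param params a [sim_params()] object.
#' @return energy in \eqn{k_BT}.
#' @export
lj_energy <- function(r, params = sim_params()) {
  if (any(r <= 0)) stop("singular overlap: separation must be positive")
  sr6 <- (params$sigma / r)^6
  u <- 4 * params$epsilon * (sr6^2 - sr6)
  if (params$shift_lj) {
    src6 <- (params$sigma / params$lj_cutoff)^6
    u <- u - 4 * params$epsilon * (src6^2 - src6)
  }
  ifelse(r > params$lj_cutoff, 0, u)
}

#' Lennard-Jones pair force magnitude
#'
#' \eqn{F(r) = 24\epsilon\,(2 (\sigma/r)^{12} - (\sigma/r)^6)/r}; positive =
#' repulsive.  Zero beyond the cutoff.
#'
#' @inheritParams lj_energy
#' @return signed radial force in \eqn{k_BT/\sigma}.
#' @export
lj_force <- function(r, params = sim_params()) {
  if (any(r <= 0)) stop("singular overlap: separation must be positive")
  sr6 <- (params$sigma / r)^6
  f <- 24 * params$epsilon * (2 * sr6^2 - sr6) / r
  ifelse(r > params$lj_cutoff, 0, f)
}

#' Total per-bead forces of a system state
#'
#' Sums FENE forces over bonded pairs, Lennard-Jones forces over all pairs
#' within the cutoff under the minimum-image convention, the constant
#' active force `(0, 0, f_act)` on the head bead of every active chain, and
#' nothing else.  Uses the same compiled kernel as the integrator.
#'
#' @param state a `system_state` (see [initialize_condensed()]).
#' @param params a [sim_params()] object.
#' @param all_pairs logical; bypass the cell/Verlet list and enumerate all
#'   pairs (reference path used in tests).
#' @return list with `forces` (N x 3 matrix in \eqn{k_BT/\sigma}),
#'   `potential` and `kinetic` energies in \eqn{k_BT}.
#' @export
total_forces <- function(state, params, all_pairs = FALSE) {
  stopifnot(inherits(state, "system_state"))
  par <- engine_par(params, all_pairs = all_pairs)
  cpp_forces(state$positions, state$velocities, state$chain_id,
             state$active, par, params$f_act, 0)
}

# flat list handed to the compiled engine
engine_par <- function(params, force_clamp = -1, all_pairs = FALSE) {
  list(box = params$box, epsilon = params$epsilon, fene_K = params$fene_K,
       fene_R0 = params$fene_R0, lj_cutoff = params$lj_cutoff,
       shift_lj = params$shift_lj, bonded_lj = params$bonded_lj,
       dt = params$dt, damping = params$damping, skin = params$skin,
       force_clamp = force_clamp, all_pairs = all_pairs || params$all_pairs)
}
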