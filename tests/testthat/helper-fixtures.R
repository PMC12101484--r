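# shared fixtures and lazily cached scaled simulation runs

# analytic tanh coexistence profile on a 0.25-sigma grid
tanh_profile <- function(rho_den = 0.6, rho_sat = 0.01, r0 = 10, w = 2,
                         r_max = 16, bin = 0.25) {
  breaks <- seq(0, r_max, by = bin)
  r <- (breaks[-1] + breaks[-length(breaks)]) / 2
  rho <- rho_sat + (rho_den - rho_sat) * (1 - tanh((r - r0) / w)) / 2
  p <- list(direction = "isotropic", r = r, rho = rho,
            counts = rep(1, length(r)), volumes = rep(1, length(r)),
            breaks = breaks, bin_width = bin)
  class(p) <- "density_profile"
  p
}

# piecewise-linear ramp profile: rho_hi for r < r1, rho_lo for r > r2
ramp_profile <- function(rho_hi = 0.6, rho_lo = 0.01, r1 = 4, r2 = 6,
                         r_max = 12, bin = 0.25) {
  breaks <- seq(0, r_max, by = bin)
  r <- (breaks[-1] + breaks[-length(breaks)]) / 2
  rho <- ifelse(r <= r1, rho_hi,
                ifelse(r >= r2, rho_lo,
                       rho_hi + (rho_lo - rho_hi) * (r - r1) / (r2 - r1)))
  p <- list(direction = "isotropic", r = r, rho = rho,
            counts = rep(1, length(r)), volumes = rep(1, length(r)),
            breaks = breaks, bin_width = bin)
  class(p) <- "density_profile"
  p
}

# scaled production runs shared by the simulation-facing acceptance checks;
# computed once per session and cached
.run_cache <- new.env(parent = emptyenv())

scaled_run_summary <- function(f_act, seed, f_passive = 0) {
  key <- sprintf("f%g_s%d_p%g", f_act, seed, f_passive)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  init_key <- sprintf("init_s%d", seed)
  if (is.null(.run_cache[[init_key]])) {
    p0 <- sim_params(scale = "small", seed = seed)
    .run_cache[[init_key]] <- initialize_condensed(p0)
  }
  p <- sim_params(scale = "small", f_act = f_act, f_passive = f_passive,
                  seed = seed)
  dump <- run_simulation(p, init = .run_cache[[init_key]])
  res <- analyze_coexistence(dump, n_bootstrap = 0)
  .run_cache[[key]] <- res
  res
}
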