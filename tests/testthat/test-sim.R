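test_that("FENE and LJ potentials match direct evaluation", {
  p <- sim_params()
  # -0.5 * 40 * 2.25 * log(1 - (1/1.5)^2) evaluated by hand
  expect_equal(fene_energy(1.0, p), 26.4504, tolerance = 1e-5)
  expect_equal(fene_energy(0, p), 0)
  expect_error(fene_energy(1.5, p), "overstretched")
  expect_gt(fene_energy(1.4999, p), 200) # log divergence near R0

  expect_equal(lj_energy(1, p), 0)
  expect_equal(lj_energy(2^(1 / 6), p), -0.40) # potential minimum = -eps
  expect_equal(lj_energy(2.5, p), 1.6 * (2.5^-12 - 2.5^-6), tolerance = 1e-12)
  expect_equal(lj_energy(2.5, p), -6.527e-3, tolerance = 1e-4)
  expect_error(lj_energy(0, p), "overlap")
  # shifted variant vanishes at the cutoff
  psh <- sim_params(shift_lj = TRUE)
  expect_equal(lj_energy(2.5, psh), 0, tolerance = 1e-15)
})

test_that("parameter invariants are enforced", {
  expect_error(sim_params(epsilon = -1), "epsilon")
  expect_error(sim_params(f_passive = 1.5), "f_passive")
  expect_error(sim_params(dt = 0.6), "damping")
  expect_error(sim_params(fene_R0 = 0.9), "fene_R0")
  expect_error(sim_params(total_steps = 10, analysis_start = 20),
               "analysis_start")
  p <- sim_params(scale = "small", f_passive = 0.2)
  expect_equal(sum(active_flags(p)), 80)
  expect_equal(active_flags(p)[1:80], rep(TRUE, 80))
})

# capped-force quench used before dynamics on freshly built random walks
relax_state <- function(st, params) {
  soft <- params
  soft$damping <- 0.1
  soft$dt <- 0.002
  for (cl in c(5, 20, 100)) {
    r <- actophase:::run_engine(st, soft, 1500, seed = 77, force_clamp = cl)
    st$positions <- r$positions
    st$velocities <- r$velocities
  }
  st
}

two_bead_state <- function(r, params) {
  system_state(matrix(c(0, 0, 0, r, 0, 0), 2, 3, byrow = TRUE),
               matrix(0, 2, 3), params)
}

test_that("total forces: pair repulsion, active force, Newton's third law", {
  p <- sim_params(n_chains = 2, beads_per_chain = 1, box = c(20, 20, 20),
                  scale = "small", total_steps = 0)
  f <- total_forces(two_bead_state(1, p), p)$forces
  # d/dr LJ at r = sigma gives repulsion 24 eps = 9.6 kBT/sigma along x
  expect_equal(f[1, ], c(-9.6, 0, 0))
  expect_equal(f[2, ], c(9.6, 0, 0))

  # isolated head bead of an active chain feels exactly (0, 0, F_act)
  pa <- sim_params(n_chains = 1, beads_per_chain = 1, box = c(20, 20, 20),
                   f_act = 2.5, scale = "small", total_steps = 0)
  st <- system_state(matrix(0, 1, 3), matrix(0, 1, 3), pa)
  expect_equal(total_forces(st, pa)$forces[1, ], c(0, 0, 2.5))

  # a passive chain's head bead feels nothing
  pp <- sim_params(n_chains = 1, beads_per_chain = 1, box = c(20, 20, 20),
                   f_act = 2.5, f_passive = 1, scale = "small",
                   total_steps = 0)
  stp <- system_state(matrix(0, 1, 3), matrix(0, 1, 3), pp)
  expect_equal(total_forces(stp, pp)$forces[1, ], c(0, 0, 0))

  # conservative forces sum to zero on a random passive configuration
  pr <- sim_params(n_chains = 4, beads_per_chain = 5, box = c(12, 12, 12),
                   scale = "small", total_steps = 0)
  pos <- local({ set.seed(42); actophase:::rw_chains(pr) })
  str <- system_state(pos, matrix(0, 20, 3), pr)
  f <- total_forces(str, pr)$forces
  # machine tolerance relative to the largest force in play
  expect_lt(max(abs(colSums(f))) / max(abs(f)), 1e-12)
})

test_that("neighbour-list forces match the all-pairs reference", {
  p <- sim_params(n_chains = 8, beads_per_chain = 10, box = c(10, 10, 14),
                  scale = "small", total_steps = 0)
  pos <- local({ set.seed(7); actophase:::rw_chains(p) })
  st <- system_state(pos, matrix(0, 80, 3), p)
  f_list <- total_forces(st, p)$forces
  f_ref <- total_forces(st, p, all_pairs = TRUE)$forces
  expect_lt(max(abs(f_list - f_ref)), 1e-10)
})

test_that("free streaming: no forces, no noise, displacement = v * dt", {
  p <- sim_params(n_chains = 1, beads_per_chain = 1, box = c(20, 20, 20),
                  damping = Inf, scale = "small", total_steps = 0)
  st <- system_state(matrix(0, 1, 3), matrix(c(1, -2, 0.5), 1, 3), p)
  out <- langevin_step(st, p, nsteps = 1)
  expect_equal(out$positions[1, ], c(1, -2, 0.5) * p$dt, tolerance = 1e-14)
})

test_that("equipartition: free-bead ensemble thermalises to kBT = 1", {
  # 125 ideal (non-interacting) beads: kinetic temperature within 2%
  p <- sim_params(n_chains = 125, beads_per_chain = 1, box = c(50, 50, 50),
                  epsilon = 1e-12, scale = "small", total_steps = 0)
  pos <- as.matrix(expand.grid(x = 1:5, y = 1:5, z = 1:5)) * 3 - 9
  st <- system_state(pos, matrix(0, 125, 3), p)
  res <- actophase:::run_engine(st, p, 1e5, seed = 11, thermo_every = 100)
  th <- res$thermo
  keep <- th$step > 2e4 # discard thermalisation from cold start
  temp <- mean(th$kinetic[keep]) / (1.5 * 125)
  expect_gt(temp, 0.98)
  expect_lt(temp, 1.02)
})

test_that("thermostat off: velocity-Verlet conserves energy", {
  # single 8-bead globule with the cutoff beyond any pair distance, so the
  # potential surface is smooth and the symplectic error stays bounded.
  # The thermal Lennard-Jones collisions are stiff (dt*omega ~ 0.3 at
  # dt = 0.01), so the tight secular-drift bound is checked at dt = 0.002
  # and only boundedness at the production step.
  p <- sim_params(n_chains = 1, beads_per_chain = 8, box = c(30, 30, 30),
                  lj_cutoff = 8, damping = Inf, shift_lj = TRUE,
                  scale = "small", total_steps = 0, dt = 0.002)
  pos <- local({ set.seed(3); actophase:::rw_chains(p) })
  st <- relax_state(system_state(pos, matrix(0, 8, 3), p), p)
  warm <- p
  warm$damping <- 0.5
  r0 <- actophase:::run_engine(st, warm, 2000, seed = 5)
  st$positions <- r0$positions
  st$velocities <- r0$velocities
  res <- actophase:::run_engine(st, p, 5e4, seed = 6, thermo_every = 500)
  etot <- res$thermo$kinetic + res$thermo$potential
  # symplectic check: the total energy oscillates but must not trend;
  # secular drift = fitted slope over 1e4 steps, per bead
  slope <- unname(stats::coef(stats::lm(etot ~ res$thermo$step))[2])
  expect_lt(abs(slope) * 1e4 / 8, 1e-4)
  # at the production step the energy stays bounded (no blow-up)
  p2 <- p
  p2$dt <- 0.01
  res2 <- actophase:::run_engine(st, p2, 1e4, seed = 6, thermo_every = 100)
  etot2 <- res2$thermo$kinetic + res2$thermo$potential
  expect_lt(stats::sd(etot2) / 8, 0.05)
  expect_lt(abs(etot2[length(etot2)] - etot2[1]) / 8, 0.05)
})

test_that("active chain in vacuum drifts at F_act / (n_beads * gamma)", {
  f_act <- 5
  p <- sim_params(n_chains = 1, beads_per_chain = 25,
                  box = c(200, 200, 200), f_act = f_act, scale = "small",
                  total_steps = 0)
  pos <- local({ set.seed(9); actophase:::rw_chains(p) })
  st <- relax_state(system_state(pos, matrix(0, 25, 3), p), p)
  # settle into the steady drifting state, then measure COM displacement
  r0 <- actophase:::run_engine(st, p, 5000, f_act = f_act, seed = 21)
  st$positions <- r0$positions
  st$velocities <- r0$velocities
  # the COM drifts many box lengths over the run: accumulate the
  # minimum-image COM displacement over segments shorter than half a box
  seg <- 5e4
  nseg <- 16
  com_prev <- actophase:::chain_coms(st, p$box)
  total <- c(0, 0, 0)
  for (k in seq_len(nseg)) {
    r1 <- actophase:::run_engine(st, p, seg, f_act = f_act, seed = 22 + k)
    st$positions <- r1$positions
    st$velocities <- r1$velocities
    com_now <- actophase:::chain_coms(st, p$box)
    total <- total + actophase:::min_image(com_now - com_prev, p$box)[1, ]
    com_prev <- com_now
  }
  nsteps <- seg * nseg
  disp <- total
  v_meas <- disp[3] / (nsteps * p$dt)
  gamma <- 1 / p$damping
  v_theory <- f_act / (25 * gamma)
  expect_equal(v_meas, v_theory, tolerance = 0.05)
  # transverse drift is pure noise, far below the driven component
  expect_lt(max(abs(disp[1:2])) / (nsteps * p$dt), 0.2 * v_theory)
})

test_that("initialization produces a bonded, condensed single cluster", {
  p1 <- sim_params(n_chains = 1, box = c(20, 20, 20), bias_steps = 2000,
                   scale = "small", total_steps = 0)
  st <- initialize_condensed(p1)
  expect_s3_class(st, "system_state")
  d <- sqrt(rowSums(actophase:::min_image(diff(st$positions), p1$box)^2))
  expect_true(all(d < p1$fene_R0)) # every bond below R0
  expect_lt(sqrt(sum(largest_cluster(st, box = p1$box)$com^2)), 6)

  p <- sim_params(n_chains = 30, box = c(22, 22, 30), bias_steps = 8000,
                  scale = "small", total_steps = 0, seed = 2)
  st <- initialize_condensed(p)
  cl <- largest_cluster(st, box = p$box)
  expect_gt(length(cl$chains) / p$n_chains, 0.9)
  bonds <- unlist(lapply(seq_len(p$n_chains), function(c) {
    idx <- ((c - 1) * 25 + 1):(c * 25)
    sqrt(rowSums(actophase:::min_image(diff(st$positions[idx, ]), p$box)^2))
  }))
  expect_true(all(bonds < p$fene_R0))
})

test_that("run_simulation: snapshot schedule and determinism", {
  p <- sim_params(n_chains = 6, box = c(14, 14, 18), bias_steps = 3000,
                  total_steps = 1e4, dump_every = 2000, scale = "small",
                  seed = 5)
  d1 <- run_simulation(p)
  expect_equal(d1$steps, seq(0, 1e4, by = 2000)) # 6 snapshots incl. step 0
  d2 <- run_simulation(p)
  expect_identical(d1$snapshots[[6]]$positions, d2$snapshots[[6]]$positions)
  expect_identical(d1$snapshots[[6]]$velocities, d2$snapshots[[6]]$velocities)

  p0 <- sim_params(n_chains = 6, box = c(14, 14, 18), bias_steps = 3000,
                   total_steps = 0, scale = "small", seed = 5)
  d0 <- run_simulation(p0)
  expect_length(d0$snapshots, 1)
  expect_equal(d0$steps, 0)
})
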