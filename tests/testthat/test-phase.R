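# brute-force single-linkage clustering oracle (all pairs, union-find in R)
brute_clusters <- function(pos, box, cutoff) {
  n <- nrow(pos)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- pos[i, ] - pos[j, ]
    d <- d - box * round(d / box)
    if (sqrt(sum(d^2)) <= cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, integer(1))
}

test_that("largest cluster matches a brute-force union-find oracle", {
  box <- c(32, 32, 50)
  set.seed(11)
  # two blobs of 10 and 5 'chains' (5 beads each), 10 sigma apart
  blob <- function(center, n_chains) {
    do.call(rbind, lapply(seq_len(n_chains), function(i) {
      start <- center + stats::runif(3, -1, 1)
      sweep(matrix(stats::rnorm(15, sd = 0.3), 5, 3), 2, start, "+")
    }))
  }
  pos <- rbind(blob(c(-8, 0, 0), 10), blob(c(2, 0, 0), 5))
  labels_oracle <- brute_clusters(pos, box, 1.5)
  big_oracle <- which(labels_oracle == names(sort(table(labels_oracle),
                                                  decreasing = TRUE))[1])
  p <- sim_params(n_chains = 15, beads_per_chain = 5, box = box,
                  scale = "small", total_steps = 0)
  st <- system_state(pos, matrix(0, 75, 3), p)
  cl <- largest_cluster(st, cluster_cutoff = 1.5, box = box)
  expect_setequal(cl$beads, big_oracle)
  expect_setequal(cl$chains, 1:10)
  # isolated chain: cluster is that chain, COM = bead centroid
  one <- sim_params(n_chains = 1, beads_per_chain = 5, box = box,
                    scale = "small", total_steps = 0)
  po <- matrix(stats::rnorm(15, sd = 0.3), 5, 3)
  sto <- system_state(po, matrix(0, 5, 3), one)
  clo <- largest_cluster(sto, box = box)
  expect_equal(clo$chains, 1L)
  expect_equal(clo$com, colMeans(po), tolerance = 1e-3)
  expect_error(largest_cluster(matrix(0, 0, 3), box = box), "empty")
})

test_that("periodic COM is exact for a cluster straddling the boundary", {
  box <- c(10, 10, 10)
  pos <- rbind(c(4.8, 0, 0), c(-4.8, 0, 0)) # wrap-adjacent pair
  com <- periodic_com(pos, box)
  expect_equal(abs(com[1]), 5, tolerance = 1e-9)
  expect_equal(com[2:3], c(0, 0), tolerance = 1e-9)
})

test_that("radial profile: flat for an ideal gas, exact for a known shell", {
  box <- c(20, 20, 20)
  set.seed(4)
  n <- round(0.05 * prod(box))
  pos <- cbind(runif(n, -10, 10), runif(n, -10, 10), runif(n, -10, 10))
  prof <- radial_density_profile(pos, c(0, 0, 0), bin_width = 1, box = box)
  # each bin within 3 standard errors of 0.05 (Poisson counts)
  se <- sqrt(pmax(prof$counts, 1)) / prof$volumes
  expect_true(all(abs(prof$rho - 0.05) <= 3 * se))
  expect_equal(sum(prof$counts), sum(sqrt(rowSums(pos^2)) < 10))

  # 100 beads uniform in the shell r in [2, 3]
  set.seed(5)
  u <- matrix(rnorm(300), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * (2^3 + runif(100) * (3^3 - 2^3))^(1 / 3)
  prof2 <- radial_density_profile(u, c(0, 0, 0), bin_width = 1, box = box)
  expect_equal(prof2$rho[3], 100 / (4 / 3 * pi * (27 - 8)), tolerance = 1e-9)
  expect_equal(prof2$rho[1], 0)
  expect_error(radial_density_profile(u, c(0, 0, 0), bin_width = 11,
                                      box = box), "bin_width")
})

test_that("clipped shell volumes integrate to the box volume", {
  box <- c(12, 12, 20)
  breaks <- seq(0, sqrt(sum((box / 2)^2)) + 0.5, by = 0.5)
  v <- actophase:::shell_volumes(breaks, box)
  expect_equal(sum(v), prod(box), tolerance = 0.01)
})

test_that("directional profiles resolve anisotropy of a prolate cluster", {
  box <- c(32, 32, 50)
  st <- make_slab_configuration(rho_den = 0.6, rho_sat = 0.005,
                                radius = c(6, 6, 14), box = box, seed = 8)
  dp <- directional_profiles(st$positions, c(0, 0, 0), box = box)
  # the long axis lies along z: beyond the short radius the planes that
  # contain z still hold dense material, the z = 0 slab only gas
  band <- function(p) mean(p$rho[p$r >= 8 & p$r <= 12])
  expect_gt(band(dp$parallel), 10 * band(dp$perpendicular))

  # isotropic sphere: parallel and perpendicular agree within sampling error
  sts <- make_slab_configuration(rho_den = 0.6, rho_sat = 0.005,
                                 radius = 9, box = box, seed = 9)
  dps <- directional_profiles(sts$positions, c(0, 0, 0), box = box)
  core_mean <- function(p) mean(p$rho[p$r >= 2 & p$r <= 7])
  expect_equal(core_mean(dps$parallel), core_mean(dps$perpendicular),
               tolerance = 0.1)

  # beads entirely above the slab leave the perpendicular profile empty
  hi <- matrix(c(0, 0, 10, 1, 1, 12), 2, 3, byrow = TRUE)
  expect_warning(dph <- directional_profiles(hi, c(0, 0, 0), box = box),
                 "empty slab")
  expect_true(all(dph$perpendicular$rho == 0))
})

test_that("coexistence densities: step, tanh and uniform profiles", {
  stepp <- ramp_profile(rho_hi = 0.6, rho_lo = 0.01, r1 = 5, r2 = 8)
  cd <- coexistence_densities(stepp)
  expect_true(cd$two_phase)
  expect_equal(cd$rho_den, 0.6)
  expect_equal(cd$rho_sat, 0.01)

  tp <- tanh_profile(rho_den = 0.6, rho_sat = 0.01, r0 = 10, w = 2)
  cdt <- coexistence_densities(tp)
  expect_true(cdt$two_phase)
  # recovered within 2% of the density contrast
  expect_lt(abs(cdt$rho_den - 0.6) / 0.59, 0.02)
  expect_lt(abs(cdt$rho_sat - 0.01) / 0.59, 0.02)

  flat <- ramp_profile(rho_hi = 0.05, rho_lo = 0.05, r1 = 5, r2 = 8)
  cdf <- coexistence_densities(flat)
  expect_false(cdf$two_phase)
  expect_equal(cdf$rho_den, cdf$rho_sat)
})

test_that("interfacial width: ramp construction, ratio, resolution floor", {
  # linear ramp 0.6 -> 0.01 over 2 sigma, endpoints on bin centers:
  # width recovered exactly
  rp <- ramp_profile(r1 = 4.125, r2 = 6.125, bin = 0.25)
  expect_equal(interfacial_width(rp), 2, tolerance = 1e-9)

  # two tanh interfaces of widths w and 2w: estimates preserve the ratio
  w1 <- interfacial_width(tanh_profile(w = 1, r0 = 8))
  w2 <- interfacial_width(tanh_profile(w = 2, r0 = 8))
  expect_gt(w2, w1)
  expect_equal(w2 / w1, 2, tolerance = 0.15)

  # a step sharper than one bin cannot exceed ~2 bin widths
  sharp <- ramp_profile(r1 = 5, r2 = 5.25, bin = 0.25)
  expect_lte(interfacial_width(sharp), 3 * 0.25)

  flat <- ramp_profile(rho_hi = 0.05, rho_lo = 0.05)
  expect_error(interfacial_width(flat), "undefined width")
})

test_that("leave-one-out bootstrap is deterministic and tight", {
  tp <- tanh_profile(w = 2, r0 = 10)
  b1 <- bootstrap_width(tp, n_trials = 1000, seed = 42)
  b2 <- bootstrap_width(tp, n_trials = 1000, seed = 42)
  expect_identical(b1$mean, b2$mean)
  expect_identical(b1$sd, b2$sd)
  expect_equal(length(b1$widths) + b1$n_failed, 1000)
  # deleting one point of a smooth noise-free profile barely moves the width
  expect_lt(b1$sd / b1$mean, 0.05)
  b3 <- bootstrap_width(tp, n_trials = 1000, seed = 43)
  expect_false(identical(b1$widths, b3$widths))
})

test_that("phase velocities: static, uniform drift", {
  p <- sim_params(n_chains = 4, beads_per_chain = 5, box = c(20, 20, 40),
                  total_steps = 0, dump_every = 2e4, scale = "small")
  set.seed(3)
  pos <- do.call(rbind, lapply(1:4, function(c)
    sweep(matrix(rnorm(15, sd = 0.3), 5, 3), 2,
          c(runif(1, -2, 2), runif(1, -2, 2), runif(1, -2, 2)), "+")))
  st0 <- system_state(pos, matrix(0, 20, 3), p, step = 0)
  st1 <- system_state(pos, matrix(0, 20, 3), p, step = 2e4)
  dump <- structure(list(params = p, steps = c(0, 2e4),
                         snapshots = list(st0, st1)),
                    class = "trajectory_dump")
  dump$params$analysis_start <- 0
  v <- phase_velocities(dump)
  expect_equal(v$dense, 0)

  # uniform drift of 5 sigma along z per tau' snapshot
  pos2 <- sweep(pos, 2, c(0, 0, 5), "+")
  st1b <- system_state(pos2, matrix(0, 20, 3), p, step = 2e4)
  dump$snapshots[[2]] <- st1b
  v2 <- phase_velocities(dump)
  expect_equal(v2$dense, 5, tolerance = 1e-9)
  expect_error(phase_velocities(structure(list(params = p, steps = 0,
                                               snapshots = list(st0)),
                                          class = "trajectory_dump")),
               "at least 2")
})

test_that("partition fractions count label classes correctly", {
  # 10 active + 5 passive chains; 3 active and 1 passive in the cluster
  box <- c(32, 32, 50)
  p <- sim_params(n_chains = 15, beads_per_chain = 5, box = box,
                  f_passive = 1 / 3, total_steps = 0, scale = "small")
  set.seed(21)
  mk <- function(center) sweep(matrix(rnorm(15, sd = 0.25), 5, 3), 2,
                               center, "+")
  centers <- rbind(
    matrix(rep(c(0, 0, 0), 3), 3, byrow = TRUE) + cbind(seq(0, 2, 1), 0, 0),
    cbind(seq(8, 20, length.out = 7), -10, 5),   # far-apart active chains
    c(1, 1, 0),                                   # passive chain in cluster
    cbind(seq(-8, -20, length.out = 4), 10, -5))  # far-apart passive chains
  pos <- do.call(rbind, lapply(seq_len(15), function(i) mk(centers[i, ])))
  st <- system_state(pos, matrix(0, 75, 3), p)
  cl <- largest_cluster(st, cluster_cutoff = 1.5, box = box)
  pf <- partition_fractions(st, cl)
  expect_equal(sort(cl$chains), c(1, 2, 3, 11))
  expect_equal(pf$active_in_dense_per_total, 3 / 15)
  expect_equal(pf$passive_in_dense_per_class, 1 / 5)
  expect_equal(pf$active_in_dense_per_class, 3 / 10)

  # no passive chains: passive fractions are not applicable
  p0 <- sim_params(n_chains = 15, beads_per_chain = 5, box = box,
                   total_steps = 0, scale = "small")
  st0 <- system_state(pos, matrix(0, 75, 3), p0)
  pf0 <- partition_fractions(st0, cl)
  expect_true(is.na(pf0$passive_in_dense_per_class))
})

test_that("slab fixture densities are recovered by the profile pipeline", {
  st <- make_slab_configuration(rho_den = 0.6, rho_sat = 0.01, radius = 10,
                                box = c(32, 32, 50), seed = 1)
  prof <- radial_density_profile(st$positions, c(0, 0, 0), bin_width = 0.5,
                                 box = c(32, 32, 50))
  cd <- coexistence_densities(prof)
  expect_true(cd$two_phase)
  expect_lt(abs(cd$rho_den - 0.6) / 0.6, 0.05)
  expect_lt(abs(cd$rho_sat - 0.01) / 0.01, 0.35) # few beads per outer shell
  # mass conservation: profile counts cover every bead inside r_max
  r <- sqrt(rowSums(st$positions^2))
  expect_equal(sum(prof$counts), sum(r < max(prof$breaks)))
})
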