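ballistic_track <- function(n = 30, v = 2, dt = 0.15, theta = 0.3) {
  tibble::tibble(track = 1L, frame = seq_len(n) - 1L, t = (seq_len(n) - 1) * dt,
                 x = v * cos(theta) * (seq_len(n) - 1) * dt,
                 y = v * sin(theta) * (seq_len(n) - 1) * dt)
}

test_that("local MSD exponents: ballistic tracks give alpha = 2 exactly", {
  pr <- local_msd_exponents(ballistic_track(), window = 12)
  expect_true(all(is.finite(pr$alpha)))
  expect_equal(pr$alpha, rep(2, nrow(pr)), tolerance = 1e-10)

  # stationary track: zero MSD -> undefined alpha, flagged not thrown
  still <- tibble::tibble(t = (0:19) * 0.15, x = rep(1, 20), y = rep(2, 20))
  prs <- local_msd_exponents(still, window = 12)
  expect_true(all(is.na(prs$alpha)))

  expect_error(local_msd_exponents(ballistic_track(n = 8), window = 12),
               "window")
})

test_that("Brownian cohort recovers alpha near 1 and its MSD slope near 4D", {
  D <- 0.05
  dt <- 0.15
  tr <- make_tracks(n_tracks = 500, n_frames = 30, frame_interval = dt,
                    active_fraction = 0, diffusion = D, noise_sd = 0,
                    seed = 101)
  pieces <- split_tracks(tr)
  profs <- lapply(pieces, local_msd_exponents, window = 12)
  mean_alpha <- mean(unlist(lapply(profs, function(p) p$alpha)), na.rm = TRUE)
  expect_gt(mean_alpha, 0.85)
  expect_lt(mean_alpha, 1.15)

  # ensemble MSD slope vs lag time = 4D within 10%
  lags <- 1:5
  msd <- vapply(lags, function(L) {
    mean(unlist(lapply(pieces, function(p) {
      n <- nrow(p)
      i <- seq_len(n - L)
      (p$x[i + L] - p$x[i])^2 + (p$y[i + L] - p$y[i])^2
    })))
  }, numeric(1))
  slope <- stats::coef(stats::lm(msd ~ I(lags * dt)))[2]
  expect_equal(unname(slope), 4 * D, tolerance = 0.1)
})

test_that("active-fraction classification recovers a 30/70 mixture", {
  expect_equal(classify_active(list(tibble::tibble(alpha = rep(2, 5))))$
                 window_fraction, 1)
  expect_equal(classify_active(list(tibble::tibble(alpha = rep(0.5, 5))))$
                 window_fraction, 0)
  expect_error(classify_active(list(tibble::tibble(alpha = NA_real_))),
               "undefined")

  tr <- make_tracks(n_tracks = 200, n_frames = 40, frame_interval = 0.15,
                    active_fraction = 0.3, speed = 2, diffusion = 0.05,
                    seed = 7)
  res <- analyze_tracks(tr, window = 12)
  expect_gt(res$summary$track_active_fraction, 0.25)
  expect_lt(res$summary$track_active_fraction, 0.35)
  # classification matches the generator's ground-truth labels
  cls <- classify_active(lapply(split_tracks(tr), local_msd_exponents,
                                window = 12))
  truth <- attr(tr, "labels")
  expect_gt(mean(cls$track_labels == truth), 0.9)
})

test_that("speeds and angles: collinear, orthogonal, reversal", {
  dt <- 1 / 2.3
  tr <- tibble::tibble(t = c(0, dt, 2 * dt), x = c(0, 2, 4), y = c(0, 0, 0))
  sa <- speeds_and_angles(tr)
  expect_equal(sa$speed, c(4.6, 4.6))
  expect_equal(sa$angle[1], 0)

  tr90 <- tibble::tibble(t = 0:2, x = c(0, 1, 1), y = c(0, 0, 1))
  expect_equal(speeds_and_angles(tr90)$angle[1], 90)
  tr180 <- tibble::tibble(t = 0:2, x = c(0, 1, 0), y = c(0, 0, 0))
  expect_equal(speeds_and_angles(tr180)$angle[1], 180)
  # zero-length displacement: undefined angle, flagged
  trz <- tibble::tibble(t = 0:2, x = c(0, 0, 1), y = c(0, 0, 0))
  expect_true(is.na(speeds_and_angles(trz)$angle[1]))
  expect_error(speeds_and_angles(tibble::tibble(t = 0, x = 0, y = 0)),
               "at least 2")
})

test_that("reflecting a track across the x-axis preserves speeds and angles", {
  tr <- make_tracks(n_tracks = 1, n_frames = 25, active_fraction = 1,
                    speed = 1.5, diffusion = 0.02, noise_sd = 0.01,
                    seed = 3)
  sa <- speeds_and_angles(tr)
  trr <- tr
  trr$y <- -trr$y
  sar <- speeds_and_angles(trr)
  expect_equal(sa$speed, sar$speed)
  expect_equal(sa$angle, sar$angle)
})

test_that("joint density normalises to one and flattens for uniform input", {
  jd1 <- joint_density(1.5, 30, speed_bins = 5, angle_bins = 5)
  expect_equal(sum(jd1$density), 1)
  expect_equal(max(jd1$density), 1) # single pair occupies a single cell

  set.seed(12)
  n <- 5e4
  jd <- joint_density(runif(n, 0, 10), runif(n, 0, 180),
                      speed_bins = 5, angle_bins = 5)
  expect_equal(sum(jd$density), 1, tolerance = 1e-12)
  expect_lt(max(jd$density) - min(jd$density), 0.01)
  expect_error(joint_density(numeric(0), numeric(0)), "no defined")
})

test_that("speed-conditioned area histograms share edges and order by mean", {
  # deterministic area = base + slope * speed: faster interval, larger areas
  tr <- make_tracks(n_tracks = 80, n_frames = 30, active_fraction = 0.5,
                    speed = 3, diffusion = 0.05, noise_sd = 0,
                    area_model = "speed", area_base = 0.2, area_slope = 0.3,
                    seed = 19)
  ad <- area_distributions_by_speed(tr)
  expect_false(any(ad$intervals$empty))
  means <- vapply(seq_along(ad$histograms), function(i) {
    mid <- (ad$edges[-1] + ad$edges[-length(ad$edges)]) / 2
    sum(ad$histograms[[i]] * mid)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  for (h in ad$histograms) expect_equal(sum(h), 1)

  # all spots forced into one interval: the others are flagged empty
  ad1 <- area_distributions_by_speed(tr, speed_intervals = data.frame(
    lo = c(0, 1e5), hi = c(1e5, 2e5)))
  expect_false(ad1$intervals$empty[1])
  expect_true(ad1$intervals$empty[2])
})

test_that("KL divergence: identity, two-bin value, asymmetry, properties", {
  expect_equal(as.numeric(kl_divergence(c(0.3, 0.7), c(0.3, 0.7), 0)), 0)
  d <- kl_divergence(c(1, 0), c(0.5, 0.5), pseudocount = 0)
  expect_equal(as.numeric(d), log(2), tolerance = 1e-12)
  rev <- kl_divergence(c(0.5, 0.5), c(1, 0), pseudocount = 0)
  expect_true(is.infinite(as.numeric(rev)))
  expect_true(attr(rev, "infinite_support"))
  expect_equal(as.numeric(kl_divergence(c(1, 0), c(0.5, 0.5), 0,
                                        base = "bits")), 1,
               tolerance = 1e-12)
  expect_error(kl_divergence(c(1, 0), c(0.5, 0.5), 0, edges_P = 0:2,
                             edges_Q = c(0, 1, 3)), "different bin edges")

  # non-negativity over random histogram pairs; zero iff identical
  set.seed(8)
  for (k in 1:2000) {
    P <- stats::rgamma(6, 1); P <- P / sum(P)
    Q <- stats::rgamma(6, 1); Q <- Q / sum(Q)
    expect_gte(as.numeric(kl_divergence(P, Q, 1e-6)), 0)
  }
  P <- c(0.2, 0.8)
  expect_equal(as.numeric(kl_divergence(P, P, 1e-6)), 0)
})

test_that("mock vs Brownian-prior cohorts reproduce the speed-KL trend", {
  # 'treated' prior: Brownian, small constant areas
  prior <- make_tracks(n_tracks = 120, n_frames = 30, active_fraction = 0,
                       diffusion = 0.03, noise_sd = 0.01,
                       area_model = "constant", area_base = 0.3,
                       area_noise_sd = 0.2, seed = 31)
  # 'untreated' cohort: mixed motion, area increasing with speed
  mock <- make_tracks(n_tracks = 120, n_frames = 30, active_fraction = 0.4,
                      speed = 2.5, diffusion = 0.03, noise_sd = 0.01,
                      area_model = "speed", area_base = 0.3,
                      area_slope = 0.25, area_noise_sd = 0.2, seed = 32)
  res <- analyze_tracks(mock, window = 12, prior_tracks = prior)
  kl <- res$summary$kl_vs_prior
  expect_true(all(is.finite(kl)))
  # divergence from the passive prior grows with the conditioning speed
  expect_gt(kl[length(kl)], kl[1])
})
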