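test_that("a clean exponential rise is recovered to 0.1%", {
  p <- bead_sim_params(max_extension = 500 * (24 + 200) / 200,
                       concentration = 200, half_saturation = 24,
                       extension_timescale = 50, position_noise = 1e-6,
                       duration = 400, injection_time = 20, seed = 2)
  traj <- simulate_bead_trajectory(p)
  fit <- fit_extension(traj, injection_time = 20)
  expect_lt(abs(fit$amplitude - 500) / 500, 1e-3)
  expect_lt(abs(fit$timescale - 50) / 50, 1e-3)
  expect_equal(fit$rate, fit$amplitude / fit$timescale)
})

test_that("a flat trajectory yields a null-extension result", {
  traj <- simulate_bead_trajectory(bead_sim_params(
    concentration = 0, duration = 100, position_noise = 20, seed = 3))
  fit <- fit_extension(traj, injection_time = 20)
  expect_true(fit$null_extension)
  expect_equal(fit$amplitude, 0)
  expect_equal(fit$rate, 0)
})

test_that("extension amplitude is invariant to a constant offset", {
  p <- bead_sim_params(concentration = 200, duration = 300, seed = 5)
  t1 <- simulate_bead_trajectory(p)
  t2 <- t1; t2$parallel <- t2$parallel + 1234
  f1 <- fit_extension(t1, 20); f2 <- fit_extension(t2, 20)
  expect_equal(f2$amplitude, f1$amplitude, tolerance = 1e-8)
  expect_equal(f2$baseline, f1$baseline + 1234, tolerance = 1e-8)
})

test_that("saturation fit recovers an exact hyperbola and its identities", {
  conc <- c(10, 20, 40, 100, 200)
  amp <- 1000 * conc / (24 + conc)
  fit <- fit_saturation(conc, amp)
  expect_equal(fit$A_max, 1000, tolerance = 1e-6)
  expect_equal(fit$S05, 24, tolerance = 1e-6)
  # midpoint identity: amplitude at c = S_0.5 is A_max / 2
  expect_equal(1000 * 24 / (24 + 24), 500)
  # near-linear regime below S_0.5 / 10: the initial slope A_max/S_0.5
  # reproduces the curve to within 5% of A_max
  c_small <- c(0.5, 1.2, 2.4)
  a_small <- 1000 * c_small / (24 + c_small)
  expect_true(all(abs(a_small - (1000 / 24) * c_small) / 1000 < 0.05))
  expect_error(fit_saturation(c(10, 10, 10), c(1, 2, 3)), "degenerate")
})

test_that("equipartition force calibration matches the plug-in formula", {
  # construct a transverse series with sample variance exactly 1636 nm^2
  y <- rnorm(5000)
  y <- (y - mean(y)) / sqrt(mean((y - mean(y))^2)) * sqrt(1636)
  traj <- structure(list(bead_id = "b", time = seq_along(y) / 50,
                         parallel = numeric(5000), transverse = y,
                         sampling_rate = 50, condition = list(), truth = NULL),
                    class = "bead_trajectory")
  f <- calibrate_force(traj, tether_length = 1000, temperature = 296)
  expect_equal(f$msd_transverse, 1636, tolerance = 1e-9)
  expect_equal(f$force, 1.380649e-2 * 296 * 1000 / 1636, tolerance = 1e-9)
  expect_lt(abs(f$force - 2.50), 0.01)

  # doubling the variance halves the force; linear in T and l
  traj2 <- traj; traj2$transverse <- y * sqrt(2)
  expect_equal(calibrate_force(traj2, 1000, 296)$force, f$force / 2,
               tolerance = 1e-9)
  for (sc in c(0.5, 2, 3)) {
    expect_equal(calibrate_force(traj, 1000 * sc, 296)$force, f$force * sc,
                 tolerance = 1e-9)
    expect_equal(calibrate_force(traj, 1000, 296 * sc)$force, f$force * sc,
                 tolerance = 1e-9)
  }
})

test_that("force calibration round-trips through the bead simulator", {
  traj <- simulate_bead_trajectory(bead_sim_params(
    force = 2.5, tether_length = 1000, temperature = 296,
    duration = 200, sampling_rate = 50, seed = 9))
  f <- calibrate_force(traj, tether_length = 1000, temperature = 296)
  expect_gte(f$n, 1e4)
  expect_lt(abs(f$force - 2.5), 3 * f$sem_force)
})

test_that("net force is the Euclidean norm of orthogonal components", {
  expect_equal(net_force(3, 4), 5)
  expect_equal(net_force(0, 1.7), 1.7)
  expect_equal(net_force(1.1, 2.2), sqrt(1.1^2 + 2.2^2))
  expect_equal(signif(net_force(1.1, 2.2), 2), 2.5)
  expect_error(net_force(-1, 2), ">= 0")
})

test_that("washout decay is recovered, and flat tails flagged as no decay", {
  p <- bead_sim_params(concentration = 200, extension_timescale = 30,
                       duration = 700, injection_time = 20,
                       washout_time = 300, dissociation_timescale = 100,
                       position_noise = 1e-6, seed = 10)
  traj <- simulate_bead_trajectory(p)
  fit <- fit_dissociation(traj, washout_time = 300)
  expect_true(fit$decayed)
  expect_lt(abs(fit$timescale - 100) / 100, 1e-3)

  # noisy two-segment trajectory: rise and decay independently recovered
  p$position_noise <- 20
  p$seed <- 11
  noisy <- simulate_bead_trajectory(p)
  # restrict the rise fit to the pre-washout window
  pre <- noisy; keep <- noisy$time < 300
  pre$time <- noisy$time[keep]; pre$parallel <- noisy$parallel[keep]
  pre$transverse <- noisy$transverse[keep]
  rise <- fit_extension(pre, injection_time = 20)
  amp_true <- 1000 * 200 / 224
  expect_lt(abs(rise$amplitude - amp_true), 2 * rise$sem_amplitude + 4)
  decay <- fit_dissociation(noisy, washout_time = 300)
  expect_true(decay$decayed)
  expect_lt(abs(decay$timescale - 100), 2 * decay$sem_timescale + 4)

  # flat post-washout segment: non-finite timescale with flag
  flat <- simulate_bead_trajectory(bead_sim_params(
    concentration = 0, duration = 200, seed = 12))
  fd <- fit_dissociation(flat, washout_time = 100, baseline = 0)
  expect_false(fd$decayed)
  expect_false(is.finite(fd$timescale))
})
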