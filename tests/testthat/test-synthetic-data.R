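test_that("parameter validation rejects unphysical settings", {
  expect_error(binding_sim_params(k_on_true = -1), "rates")
  expect_error(binding_sim_params(frame_interval = 0), "frame_interval")
  expect_error(binding_sim_params(trace_duration = -5), "trace_duration")
  expect_error(binding_sim_params(fret_means = c(0.5, 1.2)), "fret_means")
  expect_error(binding_sim_params(crosstalk = 1), "crosstalk")
  expect_error(bead_sim_params(force = 0), "force")
  expect_error(bead_sim_params(half_saturation = -2), "half_saturation")
  expect_error(simulate_titration(binding_sim_params(), numeric(0), 0.01),
               "non-empty")
  expect_error(simulate_titration(binding_sim_params(), c(10, -5), 0.01),
               "concentrations")
})

test_that("zero on-rate leaves the unbound state absorbing", {
  sim <- simulate_binding_trace(binding_sim_params(
    k_on_true = 0, trace_duration = 10, seed = 7))
  expect_true(all(sim$truth$true_state_paths[[1]] == 0L))
})

test_that("long-trace bound occupancy matches the two-state stationary law", {
  k_on <- 0.4; k_off <- 0.2
  sim <- simulate_binding_trace(binding_sim_params(
    k_on_true = k_on, k_off_true = k_off, trace_duration = 4000,
    n_traces = 1, seed = 101))
  frac <- mean(sim$truth$true_state_paths[[1]])
  p <- k_on / (k_on + k_off)
  n_cycles <- 4000 / (1 / k_on + 1 / k_off)  # effective independent visits
  se <- sqrt(p * (1 - p) / n_cycles)
  expect_lt(abs(frac - p), 3 * se)
})

test_that("complete bound dwells average 1/k_off", {
  sim <- simulate_binding_trace(binding_sim_params(
    k_off_true = 0.25, n_traces = 120, seed = 5))
  dw <- extract_dwells_all(truth_paths(sim))
  b <- dw[dw$state == "bound" & !dw$left_censored & !dw$right_censored, ]
  expect_gt(nrow(b), 500)
  se <- 4 / sqrt(nrow(b))
  expect_lt(abs(mean(b$duration_s) - 4), 3 * se)
})

test_that("truth-path dwell times are exponential (KS)", {
  sim <- simulate_binding_trace(binding_sim_params(
    k_on_true = 0.5, k_off_true = 0.5, frame_interval = 0.02,
    trace_duration = 400, n_traces = 110, seed = 31))
  dw <- extract_dwells_all(truth_paths(sim))
  d <- dw$duration_s[dw$state == "bound" & !dw$left_censored & !dw$right_censored]
  expect_gt(length(d), 1e4)
  ks <- suppressWarnings(stats::ks.test(d[seq_len(1e4)], "pexp", rate = 0.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("occupancy conservation holds on every trace", {
  sim <- simulate_binding_trace(binding_sim_params(n_traces = 20, seed = 3))
  for (s in sim$truth$true_state_paths)
    expect_identical(sum(s == 0L) + sum(s == 1L), length(s))
  n_frames <- round(60 / 0.05)
  expect_true(all(lengths(sim$truth$true_state_paths) == n_frames))
})

test_that("identical seed and params reproduce simulations bit-for-bit", {
  p <- binding_sim_params(n_traces = 3, seed = 99)
  expect_identical(simulate_binding_trace(p), simulate_binding_trace(p))
  bp <- bead_sim_params(duration = 10, seed = 99)
  expect_identical(simulate_bead_trajectory(bp), simulate_bead_trajectory(bp))
})

test_that("crosstalk/background correction inverts the generator exactly", {
  p <- binding_sim_params(n_traces = 2, trace_duration = 10, seed = 12)
  sim <- simulate_binding_trace(p)
  corr <- correction_params(p$background_donor, p$background_acceptor,
                            p$crosstalk)
  for (i in seq_along(sim$traces)) {
    f <- compute_fret(correct_intensities(sim$traces[[i]], corr))
    ideal <- p$fret_means[sim$truth$true_state_paths[[i]] + 1L]
    # corrected E differs from the ideal only by the emission noise
    expect_lt(mean(abs(f$efficiency - ideal)), p$fret_sigma)
    # and matches the pre-intensity (noise-carrying) FRET to round-off
    e_noisy <- 1 - (sim$traces[[i]]$donor - p$background_donor) / p$total_intensity
    expect_lt(max(abs(f$efficiency - e_noisy)), 1e-9)
  }
})

test_that("titration shares the generative law and scales event rates with c", {
  base <- binding_sim_params(n_traces = 1, seed = 40)
  # single concentration with k_a * c = base k_on reproduces the same traces
  one <- simulate_titration(base, 50, k_a = base$k_on_true / 50)[["50"]]
  direct <- simulate_binding_trace(base)
  expect_equal(one$truth$true_state_paths, direct$truth$true_state_paths)

  # doubling c doubles binding events per unit unbound time (Poisson oracle)
  base$n_traces <- 60
  sims <- simulate_titration(base, c(50, 100), k_a = 0.46 / 50)
  ev_rate <- vapply(sims, function(s) {
    paths <- truth_paths(s)
    events <- sum(vapply(paths, function(p)
      sum(diff(p$states) == 1L), 1L))
    events / unbound_time(paths)
  }, 1)
  ratio <- ev_rate[["100"]] / ev_rate[["50"]]
  expect_lt(abs(ratio - 2), 3 * ratio * sqrt(2 / (ev_rate[["50"]] * 60 * 30)))

  # k_a chosen as k_off/29 puts the true k_on = k_off intercept at 29 nM
  k_a <- base$k_off_true / 29
  sims29 <- simulate_titration(binding_sim_params(n_traces = 1, seed = 1,
                                                  trace_duration = 5),
                               c(10, 20, 50, 100, 300), k_a = k_a)
  kons <- vapply(sims29, function(s) s$truth$params$k_on_true, 1)
  expect_equal(unname(kons), k_a * c(10, 20, 50, 100, 300))
  expect_equal(base$k_off_true / k_a, 29)
})

test_that("bead trajectories obey the extension and equipartition laws", {
  # zero concentration: flat at baseline up to localization noise
  flat <- simulate_bead_trajectory(bead_sim_params(
    concentration = 0, duration = 60, baseline = 100, seed = 8))
  expect_lt(abs(mean(flat$parallel) - 100), 3 * 20 / sqrt(length(flat$parallel)))

  # c = S_0.5: asymptotic extension is A_max / 2
  mid <- simulate_bead_trajectory(bead_sim_params(
    concentration = 24, half_saturation = 24, max_extension = 1000,
    extension_timescale = 10, duration = 300, seed = 8))
  late <- mid$parallel[mid$time > 200]
  expect_lt(abs(mean(late) - 500), 5)

  # transverse variance matches k_B T l / F within 3 s.e. at 1e4 samples
  bp <- bead_sim_params(duration = 200, sampling_rate = 50, force = 2.5,
                        tether_length = 1000, temperature = 296, seed = 21)
  traj <- simulate_bead_trajectory(bp)
  v_true <- 1.380649e-2 * 296 * 1000 / 2.5
  n <- length(traj$transverse)
  expect_gte(n, 1e4)
  se <- v_true * sqrt(2 / n)
  expect_lt(abs(var(traj$transverse) - v_true), 3 * se)
})
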