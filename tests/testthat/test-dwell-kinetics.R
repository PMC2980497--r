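test_that("dwell extraction converts runs to durations with boundary censoring", {
  # U U B B B U at 50 ms
  dw <- extract_dwells(make_state_path(c(1, 1, 2, 2, 2, 1)))
  bound <- dw[dw$state == "bound", ]
  expect_equal(bound$duration_s, 0.15)
  expect_false(bound$left_censored || bound$right_censored)
  unb <- dw[dw$state == "unbound", ]
  expect_equal(unb$duration_s, c(0.10, 0.05))
  expect_true(unb$left_censored[1] && !unb$right_censored[1])
  expect_true(!unb$left_censored[2] && unb$right_censored[2])

  # all-unbound path: one fully censored dwell, zero bound dwells
  dw1 <- extract_dwells(make_state_path(rep(1, 10)))
  expect_identical(nrow(dw1), 1L)
  expect_identical(dw1$state, "unbound")
  expect_true(dw1$left_censored && dw1$right_censored)
  expect_identical(sum(dw1$state == "bound"), 0L)
})

test_that("gaps censor the adjacent dwells", {
  dw <- extract_dwells(make_state_path(c(1, 1, NA, 2, 2, 1)))
  expect_identical(nrow(dw), 3L)
  expect_true(all(dw$left_censored[1:2]))   # trace start / after gap
  expect_true(dw$right_censored[1])         # before gap
  expect_false(dw$left_censored[3])
})

test_that("dwell counts match an independent run-length oracle on truth paths", {
  sim <- simulate_binding_trace(binding_sim_params(n_traces = 15, seed = 44))
  dw <- extract_dwells_all(truth_paths(sim))
  for (i in seq_along(sim$truth$true_state_paths)) {
    s <- sim$truth$true_state_paths[[i]]
    r <- rle(s)
    id <- sprintf("truth_%03d", i)
    d_i <- dw[dw$trace_id == id, ]
    expect_identical(nrow(d_i), length(r$lengths))
    # complete bound runs: interior runs of state 1
    interior <- seq_along(r$values)[-c(1, length(r$values))]
    expect_identical(sum(d_i$state == "bound" & !d_i$left_censored &
                           !d_i$right_censored),
                     sum(r$values[interior] == 1L))
    # time conservation: all dwells sum to the trace duration
    expect_equal(sum(d_i$duration_s), length(s) * 0.05, tolerance = 0.05)
  }
})

test_that("exponential MLE equals the closed form 1/mean with sem rate/sqrt(n)", {
  dw <- data.frame(trace_id = "a", state = "bound", state_index = 2,
                   duration_s = c(1, 2, 3), left_censored = FALSE,
                   right_censored = FALSE)
  r <- fit_rate(dw, min_dwells = 3)
  expect_equal(r$value, 0.5)
  expect_equal(r$sem, 0.5 / sqrt(3))
  expect_identical(r$n_dwells, 3L)

  expect_error(fit_rate(dw[1:2, ]), class = "insufficient_data_error")
  err <- tryCatch(fit_rate(dw[1:2, ]), error = identity)
  expect_identical(err$n, 2L)
})

test_that("MLE and histogram estimators agree with a sampling oracle", {
  set.seed(55)
  d <- rexp(1e4, 0.25)
  dw <- data.frame(trace_id = "a", state = "bound", state_index = 2,
                   duration_s = d, left_censored = FALSE,
                   right_censored = FALSE)
  mle <- fit_rate(dw, "mle")
  expect_lt(abs(mle$value - 0.25), 3 * mle$sem)
  hist_fit <- fit_rate(dw, "histogram")
  expect_lt(abs(hist_fit$value - 0.25) / 0.25, 0.05)
  # estimator agreement at n >= 1000
  expect_lt(abs(mle$value - hist_fit$value) / mle$value, 0.10)
})

test_that("the censored-dwell exclusion rule is enforced and motivated", {
  # short traces truncate boundary dwells well below their true length, so
  # folding censored durations into the MLE inflates the rate above truth
  sim <- simulate_binding_trace(binding_sim_params(
    n_traces = 400, trace_duration = 6, seed = 66))
  dw <- extract_dwells_all(truth_paths(sim))
  b <- dw[dw$state == "bound", ]
  all_rate <- 1 / mean(b$duration_s)
  expect_gt(all_rate, 0.25 * 1.2)

  # regression of the exclusion rule itself: censored entries never touch
  # the estimate
  complete <- b[!b$left_censored & !b$right_censored, ]
  garbage <- complete
  garbage$duration_s <- 0.05
  garbage$left_censored <- TRUE
  expect_equal(fit_rate(rbind(complete, garbage))$value,
               fit_rate(complete)$value, tolerance = 1e-12)
})

test_that("estimate_rates maps bound dwells to k_off and unbound to k_on", {
  set.seed(77)
  dw <- rbind(
    data.frame(trace_id = "a", state = "bound", state_index = 2,
               duration_s = rexp(4000, 0.25), left_censored = FALSE,
               right_censored = FALSE),
    data.frame(trace_id = "a", state = "unbound", state_index = 1,
               duration_s = rexp(4000, 0.46), left_censored = FALSE,
               right_censored = FALSE))
  kr <- estimate_rates(dw)
  expect_lt(abs(kr$k_off$value - 0.25), 3 * kr$k_off$sem)
  expect_lt(abs(kr$k_on$value - 0.46), 3 * kr$k_on$sem)
  expect_identical(kr$n_events, 4000L)

  # deterministic mean-dwell identities: tau_on = 4 s -> k_off = 0.25,
  # tau_off = 2.174 s -> k_on = 0.46
  dw2 <- rbind(
    data.frame(trace_id = "a", state = "bound", state_index = 2,
               duration_s = rep(4, 10), left_censored = FALSE,
               right_censored = FALSE),
    data.frame(trace_id = "a", state = "unbound", state_index = 1,
               duration_s = rep(2.174, 10), left_censored = FALSE,
               right_censored = FALSE))
  kr2 <- estimate_rates(dw2)
  expect_equal(kr2$k_off$value, 0.25)
  expect_equal(kr2$k_on$value, 0.46, tolerance = 1e-3)

  # absent state: partial result
  b_only <- dw[dw$state == "bound", ]
  kr3 <- suppressMessages(estimate_rates(b_only))
  expect_null(kr3$k_on)
  expect_false(is.null(kr3$k_off))
})

test_that("symmetric rates are recovered symmetrically", {
  sim <- simulate_binding_trace(binding_sim_params(
    k_on_true = 0.3, k_off_true = 0.3, n_traces = 60, seed = 88))
  kr <- estimate_rates(extract_dwells_all(truth_paths(sim)))
  joint_sem <- sqrt(kr$k_on$sem^2 + kr$k_off$sem^2)
  expect_lt(abs(kr$k_on$value - kr$k_off$value), 3 * joint_sem)
})

test_that("recovered k_on rises monotonically across a titration", {
  base <- binding_sim_params(n_traces = 25, seed = 111)
  sims <- simulate_titration(base, c(10, 20, 50, 100, 300), k_a = 0.25 / 29)
  kon <- vapply(sims, function(s)
    estimate_rates(extract_dwells_all(truth_paths(s)))$k_on$value, 1)
  expect_equal(cor(kon, c(10, 20, 50, 100, 300), method = "spearman"), 1,
               tolerance = 1e-9)
})
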