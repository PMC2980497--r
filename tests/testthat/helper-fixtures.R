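# Small constructors used across the suite.

make_state_path <- function(states, means = c(0.44, 0.26),
                            frame_interval = 0.05, trace_id = "t1") {
  structure(list(trace_id = trace_id, states = as.integer(states),
                 state_means = means, frame_interval = frame_interval,
                 condition = list()),
            class = "state_path")
}

make_fret_trace <- function(eff, frame_interval = 0.05, trace_id = "t1") {
  fret_trace(trace_id, eff, frame_interval)
}

make_model <- function(means, sigmas, A, pi0) {
  structure(list(n_states = length(means), means = means, sigmas = sigmas,
                 transition_matrix = A, initial_probs = pi0),
            class = "hmm_model")
}

# Hand-built kinetic_rates for titration-level tests.
make_rates <- function(concentration, k_on, k_off, k_on_sem = 0.01,
                       k_off_sem = 0.01, n_events = 100) {
  structure(list(condition = list(concentration = concentration),
                 k_on = structure(list(value = k_on, sem = k_on_sem,
                                       n_dwells = n_events, method = "mle"),
                                  class = "rate_estimate"),
                 k_off = structure(list(value = k_off, sem = k_off_sem,
                                        n_dwells = n_events, method = "mle"),
                                   class = "rate_estimate"),
                 n_events = n_events),
            class = "kinetic_rates")
}

# Truth state paths of a simulation, wrapped as state_path objects so the
# dwell/titration stages can be exercised without the HMM.
truth_paths <- function(sim) {
  p <- sim$truth$params
  lapply(seq_along(sim$truth$true_state_paths), function(i)
    make_state_path(sim$truth$true_state_paths[[i]] + 1L,
                    means = p$fret_means, frame_interval = p$frame_interval,
                    trace_id = sprintf("truth_%03d", i)))
}

# Exhaustive Viterbi oracle: maximize the joint log-probability over all
# K^T state sequences.
brute_force_viterbi <- function(x, means, sigmas, A, pi0) {
  K <- length(means); T_ <- length(x)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  lp <- apply(grid, 1, function(s) {
    v <- log(pi0[s[1]]) + dnorm(x[1], means[s[1]], sigmas[s[1]], log = TRUE)
    for (t in seq_len(T_ - 1))
      v <- v + log(A[s[t], s[t + 1]]) +
        dnorm(x[t + 1], means[s[t + 1]], sigmas[s[t + 1]], log = TRUE)
    v
  })
  list(path = grid[which.max(lp), ], logprob = max(lp))
}

# Full smFRET chain on simulated traces; returns rates plus stage objects.
run_chain <- function(sim, k_range = 1:4, corr = correction_params(
                        sim$truth$params$background_donor,
                        sim$truth$params$background_acceptor,
                        sim$truth$params$crosstalk)) {
  fret <- lapply(sim$traces, function(tr)
    compute_fret(correct_intensities(tr, corr)))
  model <- fit_hmm(fret, k_range = k_range)
  paths <- lapply(fret, viterbi_path, model = model)
  dwells <- extract_dwells_all(paths)
  list(fret = fret, model = model, paths = paths, dwells = dwells,
       rates = estimate_rates(dwells,
                              condition = sim$traces[[1]]$condition))
}
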