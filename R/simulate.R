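#' Simulate two-state smFRET binding traces
#'
#' Simulates the unbound/bound switching of a protein on a surface-tethered
#' ssDNA as a continuous-time Markov chain with exponential waiting times
#' (mean `1/k_on_true` unbound, `1/k_off_true` bound), sampled exactly
#' (Gillespie waiting times) and then discretized to camera frames by taking
#' the state at each frame midpoint. Events shorter than one frame are
#' silently merged, as a real camera would. Per-frame ideal FRET is the
#' state mean plus Gaussian noise; intensities are constructed as
#' `acceptor = E * total_intensity`, `donor = (1 - E) * total_intensity`,
#' after which crosstalk and channel backgrounds are *added*, so the
#' correction stage must invert them.
#'
#' Traces start in the unbound state (the tether is protein-free before
#' binding); with `k_on_true = 0` the unbound state is absorbing.
#'
#' @param params A [binding_sim_params()] object.
#' @return A list of class `binding_simulation` with elements
#'   `traces` (list of `intensity_trace` objects) and `truth` (list with
#'   `true_state_paths` — per-trace integer vectors, 0 = unbound, 1 = bound
#'   — plus `params` and `seed`).
#' @export
simulate_binding_trace <- function(params) {
  validate_binding_sim_params(params)
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)

  n_frames_full <- max(1L, as.integer(round(p$trace_duration / p$frame_interval)))
  traces <- vector("list", p$n_traces)
  paths <- vector("list", p$n_traces)

  for (i in seq_len(p$n_traces)) {
    n_frames <- n_frames_full
    if (is.finite(p$bleach_timescale)) {
      t_bleach <- rexp(1, 1 / p$bleach_timescale)
      n_frames <- max(2L, min(n_frames, as.integer(floor(t_bleach / p$frame_interval))))
    }
    duration_i <- n_frames * p$frame_interval
    switch_times <- ctmc_switch_times(p$k_on_true, p$k_off_true, duration_i)
    midpoints <- (seq_len(n_frames) - 0.5) * p$frame_interval
    # state parity: even number of switches before the midpoint -> unbound
    state <- findInterval(midpoints, switch_times) %% 2L

    e_ideal <- p$fret_means[state + 1L] + rnorm(n_frames, 0, p$fret_sigma)
    acceptor_ideal <- e_ideal * p$total_intensity
    donor_ideal <- (1 - e_ideal) * p$total_intensity
    donor <- donor_ideal + p$background_donor
    acceptor <- acceptor_ideal + p$crosstalk * donor_ideal + p$background_acceptor

    traces[[i]] <- intensity_trace(
      trace_id = sprintf("sim_%03d", i),
      time = (seq_len(n_frames) - 1L) * p$frame_interval,
      donor = donor, acceptor = acceptor,
      frame_interval = p$frame_interval,
      condition = list(concentration = p$concentration, salt = p$salt,
                       nucleotide = p$nucleotide, substrate = p$substrate))
    paths[[i]] <- state
  }

  structure(list(traces = traces,
                 truth = list(true_state_paths = paths, params = p,
                              seed = p$seed)),
            class = "binding_simulation")
}

# Exact CTMC switch times on [0, duration] for a two-state chain starting
# unbound. Returns the ordered switch times (possibly length 0).
ctmc_switch_times <- function(k_on, k_off, duration) {
  times <- numeric(0)
  t <- 0
  state <- 0L
  repeat {
    rate <- if (state == 0L) k_on else k_off
    if (rate <= 0) break   # absorbing state
    t <- t + rexp(1, rate)
    if (t >= duration) break
    times <- c(times, t)
    state <- 1L - state
  }
  times
}

#' Simulate a concentration titration of binding traces
#'
#' One trace set per concentration with a concentration-proportional
#' effective on-rate `k_on_true = k_a * c` and the shared `k_off_true` of
#' `base`. Per-concentration seeds are derived from `base$seed` so the
#' titration is reproducible as a whole.
#'
#' @param base A [binding_sim_params()] object giving the shared settings.
#' @param concentrations Numeric vector of protein concentrations (nM).
#' @param k_a Association rate constant (per nM per s).
#' @return Named list of `binding_simulation` objects, one per
#'   concentration, names = concentration in nM.
#' @export
simulate_titration <- function(base, concentrations, k_a) {
  if (length(concentrations) == 0) stop("concentrations must be non-empty", call. = FALSE)
  if (any(concentrations < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (k_a <= 0) stop("k_a must be > 0", call. = FALSE)
  sims <- vector("list", length(concentrations))
  for (i in seq_along(concentrations)) {
    p <- base
    p$concentration <- concentrations[i]
    p$k_on_true <- k_a * concentrations[i]
    if (!is.null(base$seed)) p$seed <- base$seed + i - 1L
    sims[[i]] <- simulate_binding_trace(p)
  }
  names(sims) <- as.character(concentrations)
  sims
}

#' Simulate a tethered-bead flow-extension trajectory
#'
#' The flow-parallel coordinate follows
#' `baseline + A(c) * (1 - exp(-(t - t_inj)/tau))` after protein injection,
#' with plateau `A(c) = max_extension * c / (half_saturation + c)`, plus
#' Gaussian localization noise. If a washout time is set, the extension
#' decays exponentially back toward baseline afterwards. The transverse
#' coordinate is zero-mean Gaussian with variance
#' `k_B T * tether_length / force` (inverted-pendulum equipartition),
#' independent per sample: the force calibration uses only this variance, so
#' no temporal correlation is modelled.
#'
#' @param params A [bead_sim_params()] object.
#' @return A `bead_trajectory` object: list with `bead_id`, `time` (s),
#'   `parallel` (nm), `transverse` (nm), `sampling_rate`, `condition`, and
#'   `truth` (the generating params).
#' @export
simulate_bead_trajectory <- function(params) {
  validate_bead_sim_params(params)
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)

  n <- as.integer(round(p$duration * p$sampling_rate))
  time <- (seq_len(n) - 1L) / p$sampling_rate
  amp <- p$max_extension * p$concentration / (p$half_saturation + p$concentration)

  ext <- numeric(n)
  after <- time >= p$injection_time
  ext[after] <- amp * (1 - exp(-(time[after] - p$injection_time) / p$extension_timescale))
  if (!is.null(p$washout_time)) {
    w <- time >= p$washout_time
    level <- amp * (1 - exp(-(p$washout_time - p$injection_time) / p$extension_timescale))
    ext[w] <- level * exp(-(time[w] - p$washout_time) / p$dissociation_timescale)
  }
  parallel <- p$baseline + ext + rnorm(n, 0, p$position_noise)
  transverse <- rnorm(n, 0, sqrt(K_BOLTZMANN_PN_NM * p$temperature *
                                   p$tether_length / p$force))

  structure(list(bead_id = "sim_bead", time = time, parallel = parallel,
                 transverse = transverse, sampling_rate = p$sampling_rate,
                 condition = list(concentration = p$concentration,
                                  salt = p$salt, force = p$force),
                 truth = p),
            class = "bead_trajectory")
}
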