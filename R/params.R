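#' Simulation parameters for two-state binding traces
#'
#' Bundles the generative settings for a two-state (unbound/bound)
#' continuous-time Markov binding process observed through donor/acceptor
#' fluorescence intensities. Defaults reproduce the study conditions of the
#' reference smFRET experiment: 50 ms frames, 60 s traces, FRET state means
#' 0.44 (unbound) and 0.26 (bound), and the 50 nM / 25 mM NaCl rate
#' estimates k_on = 0.46 s^-1, k_off = 0.25 s^-1.
#'
#' @param k_on_true Effective first-order on-rate (s^-1) at the simulated
#'   concentration (binding is pseudo-first-order: k_on = k_a * c).
#' @param k_off_true Dissociation rate (s^-1).
#' @param concentration Protein concentration (nM), metadata only.
#' @param frame_interval Camera frame interval (s).
#' @param trace_duration Trace length (s).
#' @param n_traces Number of traces to simulate.
#' @param fret_means Length-2 numeric, FRET means of the (unbound, bound)
#'   states.
#' @param fret_sigma Gaussian emission spread around the state mean. The
#'   default 0.10 keeps states separable; the marginal spread observed on
#'   real traces (~0.15) mixes state and shot noise.
#' @param total_intensity Summed donor + acceptor intensity per frame
#'   (arbitrary units), constant per trace.
#' @param crosstalk Fraction of donor signal leaking into the acceptor
#'   channel.
#' @param background_donor,background_acceptor Additive channel backgrounds
#'   (arbitrary units).
#' @param salt NaCl concentration (mM), metadata only.
#' @param nucleotide Nucleotide condition tag ("ATP"/"ADP"/"none"), metadata.
#' @param substrate Substrate tag, metadata only.
#' @param bleach_timescale Optional exponential photobleaching timescale (s);
#'   `Inf` (default) disables trace truncation.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @return An object of class `binding_sim_params`.
#' @export
binding_sim_params <- function(k_on_true = 0.46, k_off_true = 0.25,
                               concentration = 50, frame_interval = 0.05,
                               trace_duration = 60, n_traces = 1,
                               fret_means = c(0.44, 0.26), fret_sigma = 0.10,
                               total_intensity = 1000, crosstalk = 0.06,
                               background_donor = 50, background_acceptor = 40,
                               salt = 25, nucleotide = "ATP",
                               substrate = "dT33", bleach_timescale = Inf,
                               seed = NULL) {
  p <- list(k_on_true = k_on_true, k_off_true = k_off_true,
            concentration = concentration, frame_interval = frame_interval,
            trace_duration = trace_duration, n_traces = n_traces,
            fret_means = fret_means, fret_sigma = fret_sigma,
            total_intensity = total_intensity, crosstalk = crosstalk,
            background_donor = background_donor,
            background_acceptor = background_acceptor,
            salt = salt, nucleotide = nucleotide, substrate = substrate,
            bleach_timescale = bleach_timescale, seed = seed)
  class(p) <- "binding_sim_params"
  validate_binding_sim_params(p)
  p
}

validate_binding_sim_params <- function(p) {
  stopifnot(is.numeric(p$k_on_true), is.numeric(p$k_off_true))
  if (p$k_on_true < 0 || p$k_off_true < 0)
    stop("rates must be >= 0", call. = FALSE)
  if (!is.numeric(p$frame_interval) || p$frame_interval <= 0)
    stop("frame_interval must be > 0", call. = FALSE)
  if (!is.numeric(p$trace_duration) || p$trace_duration <= 0)
    stop("trace_duration must be > 0", call. = FALSE)
  if (length(p$fret_means) != 2 || any(p$fret_means < 0) || any(p$fret_means > 1))
    stop("fret_means must be two values in [0, 1]", call. = FALSE)
  if (p$fret_sigma < 0) stop("fret_sigma must be >= 0", call. = FALSE)
  if (p$crosstalk < 0 || p$crosstalk >= 1)
    stop("crosstalk must be in [0, 1)", call. = FALSE)
  if (p$n_traces < 1) stop("n_traces must be >= 1", call. = FALSE)
  invisible(p)
}

#' Simulation parameters for tethered-bead flow-extension trajectories
#'
#' Settings for a bead on a surface-tethered ssDNA under combined laminar
#' drag and magnetic lift. The flow-parallel coordinate rises exponentially
#' after protein injection with a concentration-dependent plateau
#' `A(c) = max_extension * c / (half_saturation + c)`; the transverse
#' coordinate fluctuates with variance `k_B T * tether_length / force`
#' (inverted-pendulum equipartition).
#'
#' @param max_extension Saturating extension amplitude A_max (nm).
#' @param half_saturation Concentration of half-maximal extension S_0.5 (nM).
#' @param concentration Protein concentration (nM).
#' @param extension_timescale Exponential rise timescale tau (s).
#' @param tether_length Tether (DNA) length l (nm).
#' @param force Net force on the bead (pN).
#' @param temperature Absolute temperature (K).
#' @param sampling_rate Position sampling rate (Hz).
#' @param duration Trajectory length (s).
#' @param position_noise Localization noise on the parallel coordinate (nm).
#' @param baseline Pre-injection parallel position (nm).
#' @param injection_time Time of protein injection (s).
#' @param washout_time Optional time free protein is washed out (s); `NULL`
#'   for no washout.
#' @param dissociation_timescale Decay timescale after washout (s).
#' @param salt NaCl concentration (mM), metadata only.
#' @param seed Integer RNG seed, or `NULL`.
#' @return An object of class `bead_sim_params`.
#' @export
bead_sim_params <- function(max_extension = 1000, half_saturation = 24,
                            concentration = 200, extension_timescale = 50,
                            tether_length = 1000, force = 2.5,
                            temperature = 296, sampling_rate = 50,
                            duration = 400, position_noise = 20,
                            baseline = 0, injection_time = 20,
                            washout_time = NULL,
                            dissociation_timescale = 100,
                            salt = 25, seed = NULL) {
  p <- list(max_extension = max_extension, half_saturation = half_saturation,
            concentration = concentration,
            extension_timescale = extension_timescale,
            tether_length = tether_length, force = force,
            temperature = temperature, sampling_rate = sampling_rate,
            duration = duration, position_noise = position_noise,
            baseline = baseline, injection_time = injection_time,
            washout_time = washout_time,
            dissociation_timescale = dissociation_timescale,
            salt = salt, seed = seed)
  class(p) <- "bead_sim_params"
  validate_bead_sim_params(p)
  p
}

validate_bead_sim_params <- function(p) {
  if (p$max_extension <= 0) stop("max_extension must be > 0", call. = FALSE)
  if (p$half_saturation <= 0) stop("half_saturation must be > 0", call. = FALSE)
  if (p$force <= 0) stop("force must be > 0", call. = FALSE)
  if (p$tether_length <= 0) stop("tether_length must be > 0", call. = FALSE)
  if (p$concentration < 0) stop("concentration must be >= 0", call. = FALSE)
  if (p$duration <= 0 || p$sampling_rate <= 0)
    stop("duration and sampling_rate must be > 0", call. = FALSE)
  if (p$extension_timescale <= 0)
    stop("extension_timescale must be > 0", call. = FALSE)
  invisible(p)
}

#' Intensity correction parameters
#'
#' Background and crosstalk corrections applied to raw donor/acceptor
#' intensities before FRET efficiencies are computed.
#'
#' @param background_donor,background_acceptor Additive channel backgrounds.
#' @param crosstalk Fraction of (background-subtracted) donor signal leaking
#'   into the acceptor channel; must lie in [0, 1).
#' @return An object of class `correction_params`.
#' @export
correction_params <- function(background_donor = 0, background_acceptor = 0,
                              crosstalk = 0) {
  if (crosstalk < 0 || crosstalk >= 1)
    stop("crosstalk must be in [0, 1)", call. = FALSE)
  structure(list(background_donor = background_donor,
                 background_acceptor = background_acceptor,
                 crosstalk = crosstalk),
            class = "correction_params")
}
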