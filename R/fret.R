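#' Construct an intensity trace
#'
#' Per-molecule donor/acceptor intensity time series with condition
#' metadata (protein concentration, salt, nucleotide, substrate).
#'
#' @param trace_id Identifier.
#' @param time Time stamps (s), strictly increasing with constant spacing.
#' @param donor,acceptor Channel intensities (arbitrary units).
#' @param frame_interval Frame interval (s).
#' @param condition Named list of condition metadata.
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(trace_id, time, donor, acceptor,
                            frame_interval = NULL, condition = list()) {
  if (length(donor) != length(acceptor) || length(time) != length(donor))
    stop("time, donor and acceptor must have equal length", call. = FALSE)
  if (length(time) > 1) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
    if (is.null(frame_interval)) frame_interval <- median(dt)
    if (any(abs(dt - frame_interval) > 1e-6 * frame_interval))
      stop("time spacing must be constant and equal to frame_interval",
           call. = FALSE)
  } else if (is.null(frame_interval)) {
    frame_interval <- NA_real_
  }
  structure(list(trace_id = trace_id, time = time, donor = donor,
                 acceptor = acceptor, frame_interval = frame_interval,
                 condition = condition),
            class = "intensity_trace")
}

#' Correct raw intensities for background and donor crosstalk
#'
#' Applies, in this fixed order: `donor' = donor - background_donor`, then
#' `acceptor' = acceptor - background_acceptor - crosstalk * donor'`.
#' Negative corrected values are permitted (they carry noise information)
#' and only reported via a message.
#'
#' @param trace An `intensity_trace`.
#' @param corr A [correction_params()] object.
#' @param verbose Message the number of negative corrected values? The
#'   count is always attached as attribute `"n_negative"`.
#' @return The corrected `intensity_trace`.
#' @export
correct_intensities <- function(trace, corr, verbose = FALSE) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (length(trace$donor) == 0) stop("empty trace", call. = FALSE)
  donor <- trace$donor - corr$background_donor
  acceptor <- trace$acceptor - corr$background_acceptor - corr$crosstalk * donor
  n_neg <- sum(donor < 0, na.rm = TRUE) + sum(acceptor < 0, na.rm = TRUE)
  if (verbose && n_neg > 0)
    message(sprintf("trace %s: %d negative corrected intensities retained",
                    trace$trace_id, n_neg))
  trace$donor <- donor
  trace$acceptor <- acceptor
  attr(trace, "n_negative") <- n_neg
  trace
}

#' Compute per-frame FRET efficiency
#'
#' `E_t = acceptor_t / (donor_t + acceptor_t)` on an (already corrected)
#' intensity trace. Values outside [0, 1] are retained as-is: clipping
#' would bias the Gaussian emission means fitted downstream. Frames with
#' zero summed intensity get a missing efficiency and are reported.
#'
#' @param trace A corrected `intensity_trace`.
#' @return An object of class `fret_trace`: list with `trace_id`, `time`,
#'   `efficiency`, `frame_interval`, `condition`.
#' @export
compute_fret <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  total <- trace$donor + trace$acceptor
  zero <- !is.na(total) & total == 0
  e <- trace$acceptor / total
  e[zero] <- NA_real_
  if (any(zero))
    message(sprintf("trace %s: %d zero-intensity frames set to missing",
                    trace$trace_id, sum(zero)))
  structure(list(trace_id = trace$trace_id, time = trace$time,
                 efficiency = e, frame_interval = trace$frame_interval,
                 condition = trace$condition),
            class = "fret_trace")
}

#' Construct a FRET trace directly from efficiencies
#'
#' @param trace_id Identifier.
#' @param efficiency FRET efficiency values.
#' @param frame_interval Frame interval (s).
#' @param time Optional time stamps; defaults to a regular grid.
#' @param condition Condition metadata list.
#' @return A `fret_trace` object.
#' @export
fret_trace <- function(trace_id, efficiency, frame_interval,
                       time = NULL, condition = list()) {
  if (is.null(time)) time <- (seq_along(efficiency) - 1L) * frame_interval
  structure(list(trace_id = trace_id, time = time, efficiency = efficiency,
                 frame_interval = frame_interval, condition = condition),
            class = "fret_trace")
}
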