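#' Fit an exponential-rise extension to a bead trajectory
#'
#' The baseline is the median flow-parallel position before the injection
#' time; the post-injection segment is fit to
#' `baseline + A * (1 - exp(-(t - t_inj)/tau))` by nonlinear least squares
#' (initial A = mean of the last decile minus baseline, initial tau = time
#' to half amplitude). The extension rate is reported as `A/tau`, the
#' initial slope of the rise. An amplitude indistinguishable from noise
#' (A < 3 x baseline RMS) yields a null-extension result.
#'
#' @param traj A `bead_trajectory`.
#' @param injection_time Injection time (s); samples must exist on both
#'   sides.
#' @return An object of class `extension_fit`: `baseline` (nm), `amplitude`
#'   (nm), `timescale` (s), `rate` (nm/s), `rms` (residual RMS, nm),
#'   `sem_amplitude`, `sem_timescale`, `null_extension` flag.
#' @export
fit_extension <- function(traj, injection_time = traj$truth$injection_time %||% 0) {
  stopifnot(inherits(traj, "bead_trajectory"))
  pre <- traj$time < injection_time
  post <- !pre
  if (!any(pre) || !any(post))
    stop("samples required both before and after injection_time", call. = FALSE)
  baseline <- median(traj$parallel[pre])
  base_rms <- sqrt(mean((traj$parallel[pre] - baseline)^2))

  t <- traj$time[post] - injection_time
  y <- traj$parallel[post]
  a0 <- mean(tail(y, max(1L, length(y) %/% 10))) - baseline
  if (a0 <= 3 * base_rms) {
    return(structure(list(baseline = baseline, amplitude = 0,
                          timescale = NA_real_, rate = 0, rms = base_rms,
                          sem_amplitude = NA_real_, sem_timescale = NA_real_,
                          null_extension = TRUE),
                     class = "extension_fit"))
  }
  half_idx <- which(y - baseline >= a0 / 2)
  tau0 <- if (length(half_idx)) max(t[half_idx[1]], diff(range(t)) / 100) else diff(range(t)) / 4
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ baseline + A * (1 - exp(-t / tau)),
                      start = list(A = a0, tau = tau0),
                      lower = c(0, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("extension fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- coef(fit)
  vc <- vcov(fit)
  structure(list(baseline = baseline, amplitude = cf[["A"]],
                 timescale = cf[["tau"]], rate = cf[["A"]] / cf[["tau"]],
                 rms = sqrt(mean(residuals(fit)^2)),
                 sem_amplitude = sqrt(vc["A", "A"]),
                 sem_timescale = sqrt(vc["tau", "tau"]),
                 null_extension = FALSE),
            class = "extension_fit")
}

#' @importFrom stats residuals
#' @export
print.extension_fit <- function(x, ...) {
  if (x$null_extension) {
    cat("extension fit: no extension above noise (null result)\n")
  } else {
    cat(sprintf("extension fit: A = %.1f +/- %.1f nm, tau = %.1f +/- %.1f s, rate = %.2f nm/s\n",
                x$amplitude, x$sem_amplitude, x$timescale, x$sem_timescale,
                x$rate))
  }
  invisible(x)
}

#' Fit the concentration saturation of extension amplitudes
#'
#' Least-squares fit of the rectangular hyperbola
#' `A(c) = A_max * c / (S_0.5 + c)` to (concentration, amplitude) pairs.
#' `S_0.5` is the concentration of half-maximal extension.
#'
#' @param concentration Concentrations (nM), at least 3 distinct values.
#' @param amplitude Extension amplitudes (nm).
#' @return An object of class `saturation_fit`: `A_max` (nm), `S05` (nM),
#'   `sem_A_max`, `sem_S05`.
#' @export
fit_saturation <- function(concentration, amplitude) {
  if (length(concentration) != length(amplitude))
    stop("concentration and amplitude must have equal length", call. = FALSE)
  if (length(unique(concentration)) < 3)
    stop("degenerate design: need >= 3 distinct concentrations", call. = FALSE)
  fit <- minpack.lm::nlsLM(amplitude ~ A_max * concentration / (S05 + concentration),
                           start = list(A_max = max(amplitude) * 1.2,
                                        S05 = median(concentration)),
                           lower = c(1e-9, 1e-9),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  vc <- vcov(fit)
  structure(list(A_max = cf[["A_max"]], S05 = cf[["S05"]],
                 sem_A_max = sqrt(vc["A_max", "A_max"]),
                 sem_S05 = sqrt(vc["S05", "S05"])),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("saturation fit: A_max = %.0f +/- %.0f nm, S_0.5 = %.1f +/- %.1f nM\n",
              x$A_max, x$sem_A_max, x$S05, x$sem_S05))
  invisible(x)
}

#' Equipartition force calibration from transverse bead fluctuations
#'
#' A bead on a tether of length `l` under tension `F` behaves as an
#' inverted pendulum: its transverse fluctuations satisfy
#' `F = k_B T l / <dy^2>`, with `<dy^2>` the sample variance of the
#' transverse coordinate about its global mean.
#'
#' @param traj A `bead_trajectory` with at least 100 transverse samples.
#' @param tether_length DNA tether length l (nm).
#' @param temperature Absolute temperature (K), default 296.
#' @return An object of class `force_estimate`: `force` (pN),
#'   `msd_transverse` (nm^2), `tether_length`, `temperature`, `sem_force`
#'   (from the chi-square spread of the variance), `n`.
#' @export
calibrate_force <- function(traj, tether_length, temperature = 296) {
  stopifnot(inherits(traj, "bead_trajectory"))
  y <- traj$transverse[is.finite(traj$transverse)]
  n <- length(y)
  if (n < 100) stop("at least 100 transverse samples required", call. = FALSE)
  msd <- var(y) * (n - 1) / n
  if (msd <= 0) stop("zero transverse variance", call. = FALSE)
  f <- K_BOLTZMANN_PN_NM * temperature * tether_length / msd
  # var of a Gaussian sample variance: 2 sigma^4 / n  ->  relative s.e. sqrt(2/n)
  structure(list(force = f, msd_transverse = msd,
                 tether_length = tether_length, temperature = temperature,
                 sem_force = f * sqrt(2 / n), n = n),
            class = "force_estimate")
}

#' @export
print.force_estimate <- function(x, ...) {
  cat(sprintf("force = %.3g +/- %.2g pN (<dy^2> = %.0f nm^2, l = %.0f nm, T = %.0f K, n = %d)\n",
              x$force, x$sem_force, x$msd_transverse, x$tether_length,
              x$temperature, x$n))
  invisible(x)
}

#' Net force from orthogonal magnetic and drag components
#'
#' The tether tension is the vector sum of the magnetic lift
#' (perpendicular to the surface) and the hydrodynamic drag (parallel to
#' the flow): `F_net = sqrt(magnetic^2 + drag^2)`.
#'
#' @param magnetic Magnetic force (pN), >= 0.
#' @param drag Hydrodynamic drag force (pN), >= 0.
#' @return Net force (pN).
#' @export
net_force <- function(magnetic, drag) {
  if (magnetic < 0 || drag < 0) stop("force components must be >= 0", call. = FALSE)
  sqrt(magnetic^2 + drag^2)
}

#' Fit the post-washout extension decay
#'
#' After free protein is washed out the extension relaxes back toward
#' baseline; the post-washout segment is fit to
#' `baseline + A * exp(-(t - t_wash)/tau)`. A segment with no resolvable
#' decay yields a non-finite timescale with `decayed = FALSE`.
#'
#' @param traj A `bead_trajectory`.
#' @param washout_time Washout time (s), within the trajectory.
#' @param baseline Baseline position (nm); defaults to the pre-injection
#'   median when the trajectory records an injection time, else the final
#'   decile median.
#' @return An object of class `dissociation_fit`: `timescale` (s),
#'   `sem_timescale`, `amplitude` (nm), `decayed` flag.
#' @export
fit_dissociation <- function(traj, washout_time = traj$truth$washout_time,
                             baseline = NULL) {
  stopifnot(inherits(traj, "bead_trajectory"))
  if (is.null(washout_time) || washout_time <= min(traj$time) ||
      washout_time >= max(traj$time))
    stop("washout_time must lie within the trajectory", call. = FALSE)
  if (is.null(baseline)) {
    inj <- traj$truth$injection_time %||% NA_real_
    baseline <- if (is.finite(inj) && any(traj$time < inj))
      median(traj$parallel[traj$time < inj])
    else median(tail(traj$parallel, max(1L, length(traj$parallel) %/% 10)))
  }
  post <- traj$time >= washout_time
  t <- traj$time[post] - washout_time
  y <- traj$parallel[post]
  a0 <- mean(head(y, max(1L, length(y) %/% 20))) - baseline
  noise <- sd(diff(y)) / sqrt(2)
  if (!is.finite(a0) || a0 <= 3 * noise / sqrt(max(1, length(y) %/% 20))) {
    return(structure(list(timescale = Inf, sem_timescale = NA_real_,
                          amplitude = 0, decayed = FALSE),
                     class = "dissociation_fit"))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ baseline + A * exp(-t / tau),
                      start = list(A = a0, tau = diff(range(t)) / 3),
                      lower = c(0, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(timescale = Inf, sem_timescale = NA_real_,
                          amplitude = a0, decayed = FALSE),
                     class = "dissociation_fit"))
  }
  cf <- coef(fit); vc <- vcov(fit)
  # a fitted timescale much longer than the observed window is not a decay
  decayed <- cf[["tau"]] < 10 * diff(range(t))
  structure(list(timescale = if (decayed) cf[["tau"]] else Inf,
                 sem_timescale = if (decayed) sqrt(vc["tau", "tau"]) else NA_real_,
                 amplitude = cf[["A"]], decayed = decayed),
            class = "dissociation_fit")
}
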