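#' Dissociation constant from a rate titration
#'
#' The effective on-rate of a pseudo-first-order binding reaction is
#' proportional to protein concentration, `k_on(c) = k_a * c`, while the
#' off-rate is concentration-independent. The dissociation constant is the
#' concentration where the two fitted curves intersect,
#' `K_D = k_off / k_a`. `k_a` comes from an inverse-variance-weighted least
#' squares fit of k_on vs concentration constrained through the origin (no
#' binding at zero protein); the pooled off-rate is the inverse-variance-
#' weighted mean of the per-concentration estimates. The s.e.m. of K_D
#' follows by first-order error propagation.
#'
#' @param rates List of `kinetic_rates`, one per concentration; each must
#'   carry `condition$concentration` and both rate estimates.
#' @return An object of class `titration_result`: `k_a` (per nM per s) with
#'   `sem_k_a`, `k_off_pooled` with `sem_k_off`, `K_D` (nM), `sem_K_D`,
#'   `per_concentration` (data.frame of the inputs).
#' @export
fit_titration <- function(rates) {
  rates <- Filter(function(r) !is.null(r$k_on) && !is.null(r$k_off), rates)
  if (length(rates) < 3)
    stop(errorCondition("at least 3 concentrations with both rates required",
                        class = c("insufficient_data_error", "error", "condition")))
  conc <- vapply(rates, function(r) r$condition$concentration, 1)
  kon <- vapply(rates, function(r) r$k_on$value, 1)
  kon_sem <- vapply(rates, function(r) r$k_on$sem, 1)
  koff <- vapply(rates, function(r) r$k_off$value, 1)
  koff_sem <- vapply(rates, function(r) r$k_off$sem, 1)

  w_on <- 1 / kon_sem^2
  k_a <- sum(w_on * conc * kon) / sum(w_on * conc^2)
  sem_k_a <- sqrt(1 / sum(w_on * conc^2))
  if (k_a <= 0)
    stop(errorCondition("degenerate fit: non-positive k_on slope",
                        class = c("degenerate_fit_error", "error", "condition")))

  w_off <- 1 / koff_sem^2
  k_off_pooled <- sum(w_off * koff) / sum(w_off)
  sem_k_off <- sqrt(1 / sum(w_off))

  K_D <- k_off_pooled / k_a
  sem_K_D <- K_D * sqrt((sem_k_off / k_off_pooled)^2 + (sem_k_a / k_a)^2)

  structure(list(k_a = k_a, sem_k_a = sem_k_a,
                 k_off_pooled = k_off_pooled, sem_k_off = sem_k_off,
                 K_D = K_D, sem_K_D = sem_K_D,
                 per_concentration = data.frame(
                   concentration = conc, k_on = kon, k_on_sem = kon_sem,
                   k_off = koff, k_off_sem = koff_sem,
                   n_events = vapply(rates, function(r) r$n_events, 1))),
            class = "titration_result")
}

#' @export
print.titration_result <- function(x, ...) {
  cat(sprintf("rate titration: k_a = %.4g +/- %.2g /nM/s, pooled k_off = %.4g +/- %.2g /s\n",
              x$k_a, x$sem_k_a, x$k_off_pooled, x$sem_k_off))
  cat(sprintf("  K_D (intercept where k_on = k_off) = %.3g +/- %.2g nM\n",
              x$K_D, x$sem_K_D))
  invisible(x)
}

#' Binding-event frequency of a set of state paths
#'
#' Number of transitions into the bound state divided by the supplied
#' observation time. Pass total trace time for events per second of
#' recording, or the time spent unbound (see [unbound_time()]) for events
#' per second of binding-competent observation — the latter is the
#' empirical on-rate and is the exposure on which conditions with different
#' bound-state occupancy are comparable.
#'
#' @param paths A `state_path` or list of them.
#' @param total_time Observation time (s), > 0.
#' @return Events per second.
#' @export
count_event_frequency <- function(paths, total_time) {
  if (inherits(paths, "state_path")) paths <- list(paths)
  if (!is.numeric(total_time) || total_time <= 0)
    stop("total_time must be > 0", call. = FALSE)
  n_events <- 0L
  for (p in paths) {
    if (length(p$state_means) < 2) next   # single-state model: no binding
    bound <- which.min(p$state_means)
    s <- p$states
    ok <- which(!is.na(s))
    if (length(ok) < 2) next
    consec <- ok[c(diff(ok) == 1, FALSE)]
    n_events <- n_events + sum(s[consec] != bound & s[consec + 1L] == bound)
  }
  n_events / total_time
}

#' Time spent in the unbound state across paths
#'
#' @param paths A `state_path` or list of them.
#' @return Total unbound observation time (s).
#' @export
unbound_time <- function(paths) {
  if (inherits(paths, "state_path")) paths <- list(paths)
  tot <- 0
  for (p in paths) {
    unbound <- if (length(p$state_means) < 2) 1L else which.max(p$state_means)
    tot <- tot + sum(p$states == unbound, na.rm = TRUE) * p$frame_interval
  }
  tot
}

#' Contrast binding-event frequencies between two conditions
#'
#' @param paths_a,paths_b State-path collections for conditions A and B.
#' @param time_a,time_b Observation times (s) for the two conditions (total
#'   or unbound time; use the same convention for both).
#' @param condition_a,condition_b Metadata lists.
#' @return An object of class `condition_contrast` with the two event
#'   frequencies (events/s) and their ratio A/B.
#' @export
contrast_event_frequency <- function(paths_a, paths_b, time_a, time_b,
                                     condition_a = list(), condition_b = list()) {
  fa <- count_event_frequency(paths_a, time_a)
  fb <- count_event_frequency(paths_b, time_b)
  structure(list(condition_a = condition_a, condition_b = condition_b,
                 event_frequency_a = fa, event_frequency_b = fb,
                 ratio = fa / fb),
            class = "condition_contrast")
}

#' Rate summary across an ordered series of conditions
#'
#' Tabulates k_on and k_off against a covariate (salt, ATP concentration,
#' substrate, ...) and reports the fold-change of each rate relative to the
#' first (reference) condition.
#'
#' @param rates Named or unnamed list of `kinetic_rates`.
#' @param covariate Numeric or character vector of covariate values, one
#'   per element of `rates`; defaults to the list names.
#' @return A data.frame with columns `covariate`, `k_on`, `k_on_sem`,
#'   `k_off`, `k_off_sem`, `n_events`, `k_on_fold`, `k_off_fold`.
#' @export
condition_series <- function(rates, covariate = names(rates)) {
  if (length(rates) < 2) stop("at least 2 conditions required", call. = FALSE)
  get <- function(r, which) if (is.null(r[[which]])) NA_real_ else r[[which]]$value
  gets <- function(r, which) if (is.null(r[[which]])) NA_real_ else r[[which]]$sem
  out <- data.frame(
    covariate = if (is.null(covariate)) seq_along(rates) else covariate,
    k_on = vapply(rates, get, 1, which = "k_on"),
    k_on_sem = vapply(rates, gets, 1, which = "k_on"),
    k_off = vapply(rates, get, 1, which = "k_off"),
    k_off_sem = vapply(rates, gets, 1, which = "k_off"),
    n_events = vapply(rates, function(r) r$n_events, 1),
    stringsAsFactors = FALSE)
  out$k_on_fold <- out$k_on / out$k_on[1]
  out$k_off_fold <- out$k_off / out$k_off[1]
  rownames(out) <- NULL
  out
}

#' Dissociation constant implied by a single rate pair
#'
#' `K_D = c * k_off / k_on`: with `k_on = k_a * c`, the concentration at
#' which the on- and off-rate lines would cross. Useful for bounding K_D
#' from a single measured condition (e.g. a lower bound on k_off yields a
#' lower bound on K_D).
#'
#' @param concentration Protein concentration (nM).
#' @param k_on Effective on-rate at that concentration (s^-1).
#' @param k_off Off-rate (s^-1).
#' @return K_D in nM.
#' @export
kd_from_rates <- function(concentration, k_on, k_off) {
  if (k_on <= 0) stop("k_on must be > 0", call. = FALSE)
  concentration * k_off / k_on
}
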