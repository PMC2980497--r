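# Contiguous finite segments of a FRET trace (missing frames split a trace;
# downstream dwells spanning a gap are censored).
finite_segments <- function(efficiency) {
  ok <- is.finite(efficiency)
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(i) starts[i]:ends[i])
}

SIGMA_FLOOR <- 1e-4

#' Fit a Gaussian-emission hidden Markov model to FRET traces
#'
#' Fits one shared model jointly across the traces of a condition (pooling
#' stabilizes the state means; fit per trace by passing a single trace).
#' For each candidate state count K, expectation-maximization (Baum-Welch)
#' runs to convergence from a K-means initialization seeded at the data
#' quantiles; the returned model is the K minimizing the Bayesian
#' information criterion. States are sorted by descending FRET mean, so in
#' a two-state binding model state 1 is the unbound (high-FRET) state and
#' state 2 the bound (low-FRET) state.
#'
#' @param traces A `fret_trace` or list of `fret_trace` objects, each with
#'   at least 10 frames.
#' @param k_range Integer vector of candidate state counts (default 1:4).
#' @param tol Absolute log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter Maximum EM iterations per K (default 500).
#' @return An object of class `hmm_model`: `n_states`, `means`, `sigmas`,
#'   `transition_matrix` (row-stochastic, per frame step), `initial_probs`,
#'   `log_likelihood`, `information_criterion` (BIC), `bic_by_k`,
#'   `loglik_trace` (per-iteration log-likelihoods of the selected fit),
#'   `n_obs`, `frame_interval`.
#' @export
fit_hmm <- function(traces, k_range = 1:4, tol = 1e-6, max_iter = 500) {
  if (inherits(traces, "fret_trace")) traces <- list(traces)
  if (length(traces) < 1) stop("at least one trace required", call. = FALSE)
  if (any(vapply(traces, function(tr) length(tr$efficiency), 1L) < 10))
    stop("each trace must have at least 10 frames", call. = FALSE)

  obs <- list()
  for (tr in traces)
    for (idx in finite_segments(tr$efficiency))
      if (length(idx) >= 2) obs <- c(obs, list(tr$efficiency[idx]))
  if (length(obs) == 0) stop("no usable (finite) observations", call. = FALSE)
  x <- unlist(obs, use.names = FALSE)
  lens <- vapply(obs, length, 1L)
  n <- length(x)
  if (max(k_range) > n)
    stop("number of states exceeds number of frames", call. = FALSE)

  fits <- list()
  for (K in k_range) {
    fits[[as.character(K)]] <- if (length(unique(x)) < K) {
      list(bic = Inf, feasible = FALSE)
    } else {
      em_gaussian_hmm(x, lens, K, tol, max_iter)
    }
  }
  bics <- vapply(fits, function(f) f$bic, 1)
  if (all(!is.finite(bics))) stop("EM failed for every candidate K", call. = FALSE)
  best <- fits[[which.min(bics)]]

  structure(list(n_states = best$K, means = best$means, sigmas = best$sigmas,
                 transition_matrix = best$A, initial_probs = best$pi0,
                 log_likelihood = best$loglik,
                 information_criterion = best$bic,
                 bic_by_k = setNames(bics, names(fits)),
                 loglik_trace = best$ll_trace,
                 n_obs = n,
                 frame_interval = traces[[1]]$frame_interval),
            class = "hmm_model")
}

# EM for one K. K-means initialization with centers at the data quantiles.
em_gaussian_hmm <- function(x, lens, K, tol, max_iter) {
  n <- length(x)
  if (K == 1) {
    mu <- mean(x)
    sg <- max(sd(x) * sqrt((n - 1) / n), SIGMA_FLOOR)
    ll <- sum(dnorm(x, mu, sg, log = TRUE))
    return(list(K = 1L, means = mu, sigmas = sg,
                A = matrix(1, 1, 1), pi0 = 1, loglik = ll,
                bic = -2 * ll + 2 * log(n), ll_trace = ll, feasible = TRUE))
  }
  centers <- unique(quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE))
  km <- if (length(centers) == K) {
    kmeans(x, centers = matrix(centers, ncol = 1))
  } else {
    kmeans(x, centers = K)
  }
  means <- as.numeric(km$centers)
  sigmas <- vapply(seq_len(K), function(k) {
    xs <- x[km$cluster == k]
    if (length(xs) > 1) max(sd(xs), SIGMA_FLOOR) else SIGMA_FLOOR
  }, 1)
  A <- matrix(0.1 / (K - 1), K, K); diag(A) <- 0.9
  pi0 <- rep(1 / K, K)

  ll_prev <- -Inf
  ll_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    es <- hmm_estep(x, lens, means, sigmas, A, pi0)
    ll <- es$loglik
    if (!is.finite(ll))
      stop("EM failure: non-finite log-likelihood (K = ", K, ")", call. = FALSE)
    ll_trace <- c(ll_trace, ll)
    # M-step
    pi0 <- es$gamma1 / sum(es$gamma1)
    rs <- rowSums(es$xi)
    A <- es$xi / ifelse(rs > 0, rs, 1)
    A[rs == 0, ] <- 1 / K
    means <- es$gx / es$gsum
    sigmas <- pmax(sqrt(pmax(es$gx2 / es$gsum - means^2, 0)), SIGMA_FLOOR)
    if (abs(ll - ll_prev) < tol) break
    ll_prev <- ll
  }
  # canonical order: descending mean
  o <- order(means, decreasing = TRUE)
  means <- means[o]; sigmas <- sigmas[o]; pi0 <- pi0[o]; A <- A[o, o, drop = FALSE]
  p <- (K - 1) + K * (K - 1) + 2 * K
  list(K = as.integer(K), means = means, sigmas = sigmas, A = A, pi0 = pi0,
       loglik = ll_trace[length(ll_trace)],
       bic = -2 * ll_trace[length(ll_trace)] + p * log(n),
       ll_trace = ll_trace, feasible = TRUE)
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("Gaussian-emission HMM: %d state(s), %d frames\n",
              x$n_states, x$n_obs))
  cat("  means: ", paste(sprintf("%.3f", x$means), collapse = ", "), "\n")
  cat("  sigmas:", paste(sprintf("%.3f", x$sigmas), collapse = ", "), "\n")
  cat(sprintf("  logLik %.2f, BIC %.2f\n", x$log_likelihood,
              x$information_criterion))
  invisible(x)
}

#' Most probable state sequence (Viterbi path) of a trace
#'
#' Decodes a FRET trace under a fitted model. Missing frames remain missing
#' in the path and split the trace into independently decoded segments.
#' Exact ties in the dynamic program resolve to the lower state index.
#'
#' @param model A fitted `hmm_model`.
#' @param trace A `fret_trace`.
#' @return An object of class `state_path`: `trace_id`, `states` (integer
#'   state index per frame, 1-based, NA at gaps), `state_means` (FRET mean
#'   per state index), `frame_interval`, `condition`.
#' @export
viterbi_path <- function(model, trace) {
  stopifnot(inherits(model, "hmm_model"), inherits(trace, "fret_trace"))
  if (length(trace$efficiency) == 0) stop("empty trace", call. = FALSE)
  states <- rep(NA_integer_, length(trace$efficiency))
  for (idx in finite_segments(trace$efficiency)) {
    v <- hmm_viterbi(trace$efficiency[idx], model$means, model$sigmas,
                     model$transition_matrix, model$initial_probs)
    states[idx] <- v$path + 1L
  }
  structure(list(trace_id = trace$trace_id, states = states,
                 state_means = model$means,
                 frame_interval = trace$frame_interval,
                 condition = trace$condition),
            class = "state_path")
}

#' Transition density histogram
#'
#' 2D histogram of (FRET before transition, FRET after transition) over all
#' detected state changes in a collection of state paths, the standard
#' visual summary of state connectivity in smFRET idealization. FRET values
#' are the fitted state means of the shared model.
#'
#' @param paths A `state_path` or list of `state_path` objects sharing a
#'   model.
#' @param n_bins Number of bins per axis on \[0, 1\] (default 50).
#' @return An object of class `transition_density`: `bin_edges`, `counts`
#'   (n_bins x n_bins, rows = FRET before), `n_transitions`, `n_traces`.
#' @export
transition_density <- function(paths, n_bins = 50) {
  if (inherits(paths, "state_path")) paths <- list(paths)
  edges <- seq(0, 1, length.out = n_bins + 1)
  counts <- matrix(0L, n_bins, n_bins)
  n_trans <- 0L
  for (p in paths) {
    s <- p$states
    ok <- which(!is.na(s))
    if (length(ok) < 2) next
    # transitions between consecutive observed frames only
    consec <- ok[c(diff(ok) == 1, FALSE)]
    from <- s[consec]; to <- s[consec + 1L]
    ch <- which(from != to)
    if (length(ch) == 0) next
    eb <- pmin(pmax(p$state_means[from[ch]], 0), 1 - 1e-12)
    ea <- pmin(pmax(p$state_means[to[ch]], 0), 1 - 1e-12)
    ib <- findInterval(eb, edges, rightmost.closed = TRUE)
    ia <- findInterval(ea, edges, rightmost.closed = TRUE)
    for (j in seq_along(ib)) counts[ib[j], ia[j]] <- counts[ib[j], ia[j]] + 1L
    n_trans <- n_trans + length(ch)
  }
  structure(list(bin_edges = edges, counts = counts,
                 n_transitions = n_trans, n_traces = length(paths)),
            class = "transition_density")
}
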