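#' Write intensity traces to CSV
#'
#' Long format with columns `trace_id, time_s, donor, acceptor`. An
#' optional JSON sidecar (same path with extension `.json`) records the
#' generating parameters and truth paths of a simulation.
#'
#' @param traces List of `intensity_trace` objects (or a
#'   `binding_simulation`, whose truth is then written to the sidecar).
#' @param path Output CSV path.
#' @param sidecar Write the JSON sidecar when truth is available?
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path, sidecar = TRUE) {
  truth <- NULL
  if (inherits(traces, "binding_simulation")) {
    truth <- traces$truth
    traces <- traces$traces
  }
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(trace_id = tr$trace_id, time_s = tr$time,
               donor = tr$donor, acceptor = tr$acceptor)))
  write.csv(df, path, row.names = FALSE)
  if (sidecar && !is.null(truth)) {
    side <- list(params = truth$params[setdiff(names(truth$params), "fret_means")],
                 fret_means = truth$params$fret_means,
                 seed = truth$seed,
                 true_state_paths = truth$true_state_paths)
    jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read intensity traces from CSV
#'
#' @param path CSV with columns `trace_id, time_s, donor, acceptor`.
#' @param condition Condition metadata attached to every trace.
#' @return List of `intensity_trace` objects.
#' @export
read_traces_csv <- function(path, condition = list()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trace_id", "time_s", "donor", "acceptor")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("trace file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  lapply(split(df, df$trace_id), function(d)
    intensity_trace(d$trace_id[1], d$time_s, d$donor, d$acceptor,
                    condition = condition))
}

#' Write a bead trajectory to CSV
#'
#' Columns `time_s, x_nm, y_nm` (x = flow-parallel, y = transverse).
#'
#' @param traj A `bead_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bead_csv <- function(traj, path) {
  write.csv(data.frame(time_s = traj$time, x_nm = traj$parallel,
                       y_nm = traj$transverse),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a bead trajectory from CSV
#'
#' @param path CSV with columns `time_s, x_nm, y_nm`.
#' @param bead_id Identifier for the trajectory.
#' @param condition Condition metadata list.
#' @return A `bead_trajectory`.
#' @export
read_bead_csv <- function(path, bead_id = basename(path), condition = list()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "x_nm", "y_nm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("bead file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dt <- diff(df$time_s)
  structure(list(bead_id = bead_id, time = df$time_s, parallel = df$x_nm,
                 transverse = df$y_nm,
                 sampling_rate = if (length(dt)) 1 / median(dt) else NA_real_,
                 condition = condition, truth = NULL),
            class = "bead_trajectory")
}

#' Write a dwell table to CSV
#' @param dwells A `dwell_set` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dwells_csv <- function(dwells, path) {
  write.csv(as.data.frame(dwells), path, row.names = FALSE)
  invisible(path)
}

#' Read a dwell table from CSV
#' @param path CSV written by [write_dwells_csv()].
#' @return A `dwell_set` data.frame.
#' @export
read_dwells_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("dwell_set", "data.frame")
  df
}

#' Read an analysis configuration from YAML
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_analysis_config <- function(path) yaml::read_yaml(path)

#' Write a run report to JSON
#' @param report A `run_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(strip_classes(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Run the full smFRET kinetics pipeline
#'
#' Orchestrates correct -> FRET -> HMM segmentation -> dwell extraction ->
#' rate estimation per condition, plus the rate-titration fit when at least
#' three concentrations are present and `config$titration` is not `FALSE`.
#' Deterministic given `config$seed`.
#'
#' The configuration is a list:
#' \describe{
#'   \item{seed}{integer; per-condition simulation seeds are derived from it}
#'   \item{correction}{args for [correction_params()]}
#'   \item{hmm}{`k_min`, `k_max`, `tol`, `max_iter` for [fit_hmm()]}
#'   \item{estimator}{"mle" (default) or "histogram"}
#'   \item{titration}{logical; fit [fit_titration()] across conditions}
#'   \item{conditions}{list; each element has `name`, and either `simulate`
#'     (args for [binding_sim_params()]) or `file` (trace CSV) plus
#'     `condition` metadata (concentration, salt, nucleotide, substrate)}
#' }
#'
#' @param config Configuration list (see Details) or path to a YAML file.
#' @return An object of class `run_report`: `version`, `seed`, `config`,
#'   `conditions` (per-condition list with `rates`, `n_traces`, `n_frames`,
#'   `n_transitions`, `total_time_s`, `unbound_time_s`, `model` summary),
#'   and `titration` when fitted. The segmentation objects themselves are
#'   attached as attribute `"stages"` for downstream plotting.
#' @export
run_smfret_pipeline <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  if (is.null(config$conditions) || length(config$conditions) == 0)
    stop("configuration error: empty condition manifest", call. = FALSE)
  seed <- config$seed %||% 1L
  corr <- do.call(correction_params, config$correction %||% list())
  hm <- config$hmm %||% list()
  k_range <- seq(hm$k_min %||% 1L, hm$k_max %||% 4L)
  estimator <- config$estimator %||% "mle"

  cond_out <- list()
  stages <- list()
  rates_list <- list()
  for (i in seq_along(config$conditions)) {
    cd <- config$conditions[[i]]
    name <- cd$name %||% as.character(i)
    traces <- if (!is.null(cd$simulate)) {
      sim_args <- cd$simulate
      sim_args$seed <- sim_args$seed %||% (seed + 1000L * i)
      sim <- simulate_binding_trace(do.call(binding_sim_params, sim_args))
      sim$traces
    } else if (!is.null(cd$file)) {
      read_traces_csv(cd$file, condition = cd$condition %||% list())
    } else {
      stop("condition '", name, "': neither a simulation block nor a file",
           call. = FALSE)
    }
    corrected <- lapply(traces, correct_intensities, corr = corr)
    n_neg <- sum(vapply(corrected, function(tr) attr(tr, "n_negative"), 1L))
    if (n_neg > 0)
      message(sprintf("[%s] %d negative corrected intensities retained", name, n_neg))
    fret <- lapply(corrected, compute_fret)
    model <- fit_hmm(fret, k_range = k_range, tol = hm$tol %||% 1e-6,
                     max_iter = hm$max_iter %||% 500)
    paths <- lapply(fret, viterbi_path, model = model)
    dwells <- extract_dwells_all(paths)
    condition <- traces[[1]]$condition
    rates <- estimate_rates(dwells, condition = condition, method = estimator)
    td <- transition_density(paths)
    total_time <- sum(vapply(traces, function(tr)
      length(tr$time) * tr$frame_interval, 1))
    ub_time <- unbound_time(paths)
    message(sprintf("[%s] %d traces, %d frames, %d transitions, %d complete binding events",
                    name, length(traces), model$n_obs, td$n_transitions,
                    rates$n_events))
    cond_out[[name]] <- list(
      condition = condition, rates = rates, n_traces = length(traces),
      n_frames = model$n_obs, n_transitions = td$n_transitions,
      total_time_s = total_time, unbound_time_s = ub_time,
      model = list(n_states = model$n_states, means = model$means,
                   sigmas = model$sigmas,
                   information_criterion = model$information_criterion))
    stages[[name]] <- list(fret = fret, model = model, paths = paths,
                           dwells = dwells, transition_density = td)
    rates_list[[name]] <- rates
  }

  report <- list(version = as.character(packageVersion("fretflow")),
                 seed = seed, config = config, conditions = cond_out)
  if (!isFALSE(config$titration) && length(rates_list) >= 3) {
    report$titration <- tryCatch(
      strip_sem_frame(fit_titration(rates_list)),
      error = function(e) {
        message("titration fit skipped: ", conditionMessage(e))
        NULL
      })
  }
  attr(report, "stages") <- stages
  class(report) <- "run_report"
  report
}

strip_sem_frame <- function(tr) {
  out <- unclass(tr)
  out$per_concentration <- as.list(tr$per_concentration)
  out
}

#' Run the flow-extension pipeline
#'
#' Per condition: load or simulate a bead trajectory, fit the exponential
#' extension rise, and (when requested) calibrate the force from the
#' transverse fluctuations. Across conditions with at least three distinct
#' concentrations, fit the saturation hyperbola to the amplitudes. Net
#' force components given in the config are echoed through [net_force()].
#'
#' Config fields: `seed`; `conditions` (list of `name` + `simulate` args
#' for [bead_sim_params()] or `file` + `condition`); `injection_time`;
#' `force_calibration` (`tether_length`, `temperature`);
#' `force_components` (`magnetic`, `drag`).
#'
#' @param config Configuration list or YAML path.
#' @return A `run_report` with per-condition `extension` fits, optional
#'   `saturation`, `force`, and `net_force` entries.
#' @export
run_extension_pipeline <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  if (is.null(config$conditions) || length(config$conditions) == 0)
    stop("configuration error: empty condition manifest", call. = FALSE)
  seed <- config$seed %||% 1L

  cond_out <- list()
  conc <- amp <- numeric(0)
  for (i in seq_along(config$conditions)) {
    cd <- config$conditions[[i]]
    name <- cd$name %||% as.character(i)
    traj <- if (!is.null(cd$simulate)) {
      sim_args <- cd$simulate
      sim_args$seed <- sim_args$seed %||% (seed + 1000L * i)
      simulate_bead_trajectory(do.call(bead_sim_params, sim_args))
    } else if (!is.null(cd$file)) {
      read_bead_csv(cd$file, condition = cd$condition %||% list())
    } else {
      stop("condition '", name, "': neither a simulation block nor a file",
           call. = FALSE)
    }
    inj <- cd$injection_time %||% config$injection_time %||%
      traj$truth$injection_time %||% 0
    ext <- fit_extension(traj, injection_time = inj)
    entry <- list(condition = traj$condition, extension = unclass(ext))
    if (!is.null(config$force_calibration)) {
      fc <- config$force_calibration
      entry$force <- unclass(calibrate_force(
        traj, tether_length = fc$tether_length,
        temperature = fc$temperature %||% 296))
    }
    message(sprintf("[%s] extension %.0f nm, tau %.1f s",
                    name, ext$amplitude, ext$timescale))
    cond_out[[name]] <- entry
    cc <- traj$condition$concentration
    if (!is.null(cc) && !ext$null_extension) {
      conc <- c(conc, cc)
      amp <- c(amp, ext$amplitude)
    }
  }

  report <- list(version = as.character(packageVersion("fretflow")),
                 seed = seed, config = config, conditions = cond_out)
  if (length(unique(conc)) >= 3)
    report$saturation <- unclass(fit_saturation(conc, amp))
  if (!is.null(config$force_components)) {
    fc <- config$force_components
    report$net_force <- net_force(fc$magnetic, fc$drag)
  }
  class(report) <- "run_report"
  report
}
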