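#!/usr/bin/env Rscript
# Segment the simulated 50 nM trace set: background/crosstalk correction,
# FRET efficiency, Gaussian-HMM fit with BIC model selection, Viterbi
# idealization, and the transition density plot. Writes the fitted model
# (JSON), per-frame state paths and the transition-density matrix (CSV),
# and a heatmap figure.

library(fretflow)

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
traces <- read_traces_csv("results/data/traces_50nM.csv",
                          condition = list(concentration = 50, salt = 25,
                                           nucleotide = "ATP"))
side <- jsonlite::read_json("results/data/traces_50nM.json",
                            simplifyVector = TRUE, simplifyMatrix = FALSE)
corr <- correction_params(side$params$background_donor,
                          side$params$background_acceptor,
                          side$params$crosstalk)

fret <- lapply(traces, function(tr) compute_fret(correct_intensities(tr, corr)))
model <- fit_hmm(fret, k_range = 1:4)
print(model)
message(sprintf("BIC selected K = %d; candidate BICs: %s", model$n_states,
                paste(sprintf("%.0f", model$bic_by_k), collapse = ", ")))

paths <- lapply(fret, viterbi_path, model = model)
td <- transition_density(paths)
message(sprintf("%d transitions from %d traces", td$n_transitions, td$n_traces))

jsonlite::write_json(
  list(n_states = model$n_states, means = model$means, sigmas = model$sigmas,
       transition_matrix = model$transition_matrix,
       initial_probs = model$initial_probs,
       log_likelihood = model$log_likelihood,
       information_criterion = model$information_criterion),
  "results/hmm_model_50nM.json", auto_unbox = TRUE, digits = NA)

path_df <- do.call(rbind, lapply(paths, function(p)
  data.frame(trace_id = p$trace_id, frame = seq_along(p$states) - 1L,
             state_index = p$states)))
write.csv(path_df, "results/state_paths_50nM.csv", row.names = FALSE)
write.csv(td$counts, "results/transition_density_50nM.csv", row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  mids <- td$bin_edges[-1] - diff(td$bin_edges) / 2
  df <- expand.grid(before = mids, after = mids)
  df$count <- as.vector(td$counts)
  gg <- ggplot(df[df$count > 0, ], aes(before, after, fill = count)) +
    geom_tile() +
    coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "FRET before transition", y = "FRET after transition",
         title = sprintf("Transition density: %d transitions, %d traces",
                         td$n_transitions, td$n_traces)) +
    theme_minimal()
  ggsave("results/figures/transition_density.png", gg, width = 5, height = 4,
         dpi = 150)
}
message("done: results/hmm_model_50nM.json, state_paths_50nM.csv")
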