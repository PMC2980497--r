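#!/usr/bin/env Rscript
# Generate the synthetic datasets the downstream analyses consume:
#   - one 50 nM / 25 mM NaCl smFRET trace set at the study conditions
#     (50 ms frames, 60 s traces, FRET means 0.44/0.26, sigma 0.1,
#     k_on 0.46 /s, k_off 0.25 /s)
#   - bead trajectories for the flow-extension arm, including one
#     injection + washout trajectory
# Trace CSVs plus JSON truth sidecars land under results/data/.

library(fretflow)

seed <- 20260925L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

message("simulating 60 smFRET traces at 50 nM ...")
p <- binding_sim_params(n_traces = 60, seed = seed)
sim <- simulate_binding_trace(p)
write_traces_csv(sim, "results/data/traces_50nM.csv")
n_frames <- sum(lengths(sim$truth$true_state_paths))
message(sprintf("  %d traces, %d frames (%.0f s observation)",
                length(sim$traces), n_frames, n_frames * p$frame_interval))

message("simulating the bead trajectory with washout ...")
traj <- simulate_bead_trajectory(bead_sim_params(
  concentration = 200, duration = 700, injection_time = 20,
  washout_time = 400, dissociation_timescale = 120, seed = seed + 1L))
write_bead_csv(traj, "results/data/bead_washout.csv")
message(sprintf("  %d samples at %g Hz", length(traj$time), traj$sampling_rate))

message("done: results/data/")
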