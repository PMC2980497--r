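# fretflow

Single-molecule analysis of transient protein–ssDNA binding, built around
the two assays used to characterize MutL (a DNA mismatch-repair protein)
on single-stranded DNA:

* an **smFRET kinetics chain** — donor/acceptor intensity correction, FRET
  efficiency `E = I_A/(I_D + I_A)`, Gaussian-emission hidden-Markov
  segmentation with BIC model selection, Viterbi idealization, censored
  dwell-time extraction, and exponential rate estimation
  (`k_off = 1/τ_on`, `k_on = 1/τ_off`), ending in a rate-titration
  dissociation constant: with `k_on(c) = k_a·c` proportional to protein
  concentration and `k_off` concentration-independent,
  `K_D = k_off / k_a` is the concentration where the two fitted rate
  curves intersect;
* a **flow-extension chain** — tethered-bead trajectories fit to an
  exponential extension rise `A(1 − e^{−t/τ})`, hyperbolic concentration
  saturation `A(c) = A_max·c/(S_0.5 + c)`, washout decay, and
  inverted-pendulum force calibration from transverse fluctuations,
  `F = k_B T l / ⟨δy²⟩`, with the net force as the vector sum of magnetic
  lift and hydrodynamic drag.

No experimental traces are distributed with this package. Instead a
first-class synthetic-data module simulates two-state
continuous-time-Markov binding traces (exact Gillespie switching,
frame-midpoint discretization, Gaussian FRET emission, additive crosstalk
and backgrounds) and bead trajectories (saturating rise + equipartition
transverse noise), so every stage of the chain is validated by parameter
recovery against known truth. See the methods vignette
(`vignettes/smfret-flow-extension-methods.Rmd`) for the models,
assumptions, defaults, and known systematics.

## Worked example

Simulate 60 traces at study conditions (50 ms frames, 60 s traces, FRET
means 0.44/0.26, emission spread 0.1, `k_on` 0.46 s⁻¹, `k_off` 0.25 s⁻¹),
then run the chain:

```r
library(fretflow)

p   <- binding_sim_params(n_traces = 60, seed = 20260925)
sim <- simulate_binding_trace(p)

corr <- correction_params(p$background_donor, p$background_acceptor,
                          p$crosstalk)
fret <- lapply(sim$traces, function(tr)
  compute_fret(correct_intensities(tr, corr)))

model <- fit_hmm(fret, k_range = 1:4)
print(model)
#> Gaussian-emission HMM: 2 state(s), 72000 frames
#>   means:  0.441, 0.259
#>   sigmas: 0.100, 0.101
#>   logLik 58877.62, BIC -117676.94

paths  <- lapply(fret, viterbi_path, model = model)
dwells <- extract_dwells_all(paths)
estimate_rates(dwells)
#> kinetic rates
#>   k_on  = 0.4182 +/- 0.019 s^-1 (n = 480)
#>   k_off = 0.2375 +/- 0.011 s^-1 (n = 502)
#>   complete binding events: 502
```

BIC picks two states and recovers the generating means to ±0.005. The
dwell-based rates sit ~5–10% below the generating values: the Viterbi path
cannot resolve events shorter than a few frames, a documented property of
idealization at this SNR and frame rate (see the vignette); the EM
transition matrix itself carries unbiased rate information. The titration
largely cancels this systematic — running
`analysis/04_titration_kd.R` (five concentrations, true intercept 29 nM)
prints:

```
K_D = 28.8 +/- 1.1 nM (truth 29 nM); k_a = 0.00728 /nM/s, pooled k_off = 0.210 /s
```

The flow-extension arm (`analysis/05_flow_extension.R`):

```
saturation: A_max = 1001 +/- 0 nm, S_0.5 = 24.1 +/- 0.0 nM (truth 24 nM)
net force from components: 2.46 pN
equipartition forces: 2.51, 2.52, 2.53, 2.50, 2.55 pN (truth 2.5)
washout: rise A = 893 nm (tau 50 s), decay tau = 120 s
```

## Analysis workflow

The `analysis/` scripts are thin narrative drivers over the package, in
running order; each writes its tables under `results/` (figures under
`results/figures/`):

| script | what it does |
|---|---|
| `01_simulate_data.R` | generate the trace set and bead trajectories (CSV + truth sidecars) |
| `02_segment_traces.R` | correction → FRET → HMM → Viterbi → transition density |
| `03_dwell_kinetics.R` | dwell tables, MLE and histogram rate fits |
| `04_titration_kd.R` | five-point titration → `K_D` from the rate intercept |
| `05_flow_extension.R` | extension rises, saturation `S_0.5`, washout decay, force calibration |

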