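---
title: "Models and methods: smFRET binding kinetics and flow-extension analysis"
author: "fretflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: smFRET binding kinetics and flow-extension analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The measurement problem

A DNA mismatch-repair protein (MutL) binds single-stranded DNA transiently,
in an ATP- and salt-dependent way. Two single-molecule assays observe this:

1. **smFRET**: a donor dye on an ssDNA tail and an acceptor at the
   ssDNA/dsDNA junction report the tail's conformation through the FRET
   efficiency `E = I_A / (I_D + I_A)`. Protein binding stretches the tail
   and lowers E from ~0.44 (unbound) to ~0.26 (bound). A camera records
   both channels at 50 ms per frame for tens of seconds per molecule.
2. **Flow extension**: a long ssDNA tethers a super-paramagnetic bead in a
   laminar flow. Multiple proteins binding along the ssDNA lengthen it, so
   the bead position along the flow axis reports binding at the
   many-protein scale, sampled at 50 Hz.

`fretflow` implements the full inference chain for both arms, plus a
synthetic-data generator that produces traces with the exact statistical
structure the analysis assumes, so every stage is validated by parameter
recovery rather than by eye.

# Generative model (and what the simulator does and does not emulate)

Binding is a two-state continuous-time Markov chain: unbound → bound at the
effective first-order rate `k_on = k_a · c` (pseudo-first-order in protein
concentration `c`) and bound → unbound at `k_off`. Dwell times in each
state are exponential. The simulator draws the switching times exactly
(Gillespie waiting times) and then discretizes to camera frames by taking
the state at each frame midpoint, rather than flipping a per-frame
Bernoulli coin: this gives exact dwell statistics at any frame interval,
and events shorter than one frame are silently merged — exactly what a
50 ms camera does to the real process. No missed-event (dead-time)
correction is applied anywhere in the chain, matching the analysis the
assay community applies to such data.

Per frame, the ideal FRET value is the state mean plus Gaussian noise
(default emission spread `fret_sigma = 0.10`; the *marginal* spread seen on
real histograms, ~0.15, mixes state separation and shot noise, so the
per-state spread is deliberately smaller). Intensities are built as
`acceptor = E·I_total`, `donor = (1−E)·I_total` with `I_total` constant per
trace (E is scale-invariant, so blinking-free constant intensity loses no
generality), and then donor→acceptor crosstalk and additive channel
backgrounds are **added**, so the correction stage must genuinely invert
them. The magnitudes of crosstalk (0.06) and backgrounds (50/40 a.u. on
`I_total = 1000`) are configuration defaults in the range typical for
two-channel TIRF setups, not claims about any particular instrument; no
published values exist for this dataset. Optional exponential
photobleaching truncation exists but is off by default (the experiments
used an oxygen scavenger).

For the bead arm, the flow-parallel coordinate rises after protein
injection as `baseline + A(c)·(1 − exp(−(t − t_inj)/τ))` with plateau
`A(c) = A_max·c/(S_0.5 + c)`, optionally decaying back exponentially after
washout; the transverse coordinate is zero-mean Gaussian with the
inverted-pendulum equipartition variance `k_B·T·l/F`. Fluctuations are
white at 50 Hz — no Ornstein–Uhlenbeck correlation is modelled, because the
force calibration uses only the variance, and a correlation time is
invisible to that formula. Camera/EMCCD noise physics, bead image
formation, and hydrodynamic flow fields are out of scope: passing tests
demonstrate correct *inference given this generative model*, not
robustness to instrument pathologies absent from it.

# The smFRET chain

**Correction.** `donor' = donor − bg_D`, then
`acceptor' = acceptor − bg_A − crosstalk · donor'`, in that fixed order.
Negative corrected values are retained (clipping would bias the noise);
they are counted and reported.

**FRET.** `E = acceptor'/(donor' + acceptor')`. Values outside [0, 1] are
retained: the downstream HMM has Gaussian emissions, and clipping biases
the state means. Zero-total frames become missing values; gaps split a
trace, and dwells spanning a gap are censored.

**Segmentation.** A Gaussian-emission hidden Markov model is fit jointly
across the traces of one condition by expectation–maximization
(Baum–Welch), for each candidate state count K in 1..4, and the K with the
lowest BIC wins. Joint fitting pools statistical strength into the state
means (fitting per trace is available by passing a single trace). Choices
that matter:

* initialization: K-means seeded at the data quantiles
  `(k − 0.5)/K`, cluster standard deviations as starting sigmas, sticky
  transition matrix (0.9 on the diagonal), uniform initial probabilities;
* convergence: absolute log-likelihood change below `1e-6`, at most 500
  iterations; the per-iteration log-likelihood sequence is stored on the
  model and asserted non-decreasing in the tests;
* numerical floor `1e-4` on sigmas so that noise-free traces (a legitimate
  degenerate input) cannot drive the likelihood to infinity; emission
  weights are renormalized per frame before the forward pass so tiny
  sigmas cannot underflow it;
* a K larger than the number of distinct data values is marked infeasible
  (infinite BIC) rather than fitted;
* states are sorted by descending mean, which also fixes the biological
  labels: high-FRET = unbound, low-FRET = bound (binding lowers FRET);
* BIC uses `p = (K−1) + K(K−1) + 2K` free parameters and the total frame
  count.

The forward–backward and Viterbi inner loops are compiled (Rcpp), which
keeps a 250-trace × 1200-frame fit in the tens of seconds. The original
analysis style for such data is variational ("maximum evidence") model
selection; EM + BIC targets the same model class and the same selection
goal with fully specifiable machinery, and is the declared substitution
here — the recovered state means agree with the generating values to
±0.005 at study conditions.

**Idealization.** The Viterbi (most-probable) path under the fitted model,
decoded per trace; exact ties in the dynamic program resolve to the lower
state index. The transition-density plot is the 2D histogram of (state
mean before, state mean after) over all detected state changes, 50×50 bins
on [0, 1]².

**Dwells and rates.** Maximal constant-state runs become dwells of
duration run-length × frame interval. Runs touching a trace boundary or a
gap are censored on that side and excluded from rate fitting, matching the
plain exponential-fit convention. The default estimator is the unbinned
MLE `k = 1/mean(duration)` with `sem = k/√n` (delta method); a
histogram-based estimator (Freedman–Diaconis bins, least-squares fit of
`A·exp(−k·t)`) is retained for parity with histogram fitting and agrees
with the MLE within a few percent at n ≥ 1000. A note on the exclusion
rule: for exponential dwells on long traces, including censored dwells is
nearly bias-neutral (the observed remainder of a memoryless dwell is
itself exponential); the exclusion matters when trace ends cap dwells well
below their true length. The tests assert exactly that, rather than a
blanket claim.

**Known systematic of the dwell chain.** At the study conditions
(state separation 1.8 sigma, 50 ms frames, `k_on` 0.46 s⁻¹, `k_off`
0.25 s⁻¹) the MAP path absorbs most events shorter than ~5 frames —
they are individually unresolvable at this SNR — which merges the
neighbouring opposite-state dwells. Net effect, measured on simulations:
dwell-based rates land ~9–11% below the generating values (frame
discretization alone pushes them ~3–5% the other way). This is a property
of Viterbi dwell counting, not of the implementation: an independent HMM
implementation reproduces the same decoded paths and the same rates to
four decimals. The EM-fitted transition matrix itself is unbiased (implied
rates within ~2% of truth) and is the better rate estimator when no
idealized path is needed; the dwell chain is kept as the primary route
because dwell histograms are the assay's lingua franca. Recovery is
therefore validated against the quantities' quoted uncertainties (±0.04
and ±0.03 s⁻¹), not against the much smaller estimator s.e.m., and the
transition-matrix rates are asserted as a supporting check.

# The binding model

`k_on(c)` is fit by inverse-variance-weighted least squares **constrained
through the origin** — the proportionality is strict and there is no
binding at zero protein, so a free intercept would only absorb noise.
`k_off` is pooled across concentrations by inverse-variance weighting
(reducing to the plain mean under equal variances). The dissociation
constant is the concentration where the two fitted curves cross,

> `K_D = k_off,pooled / k_a`,

with its s.e.m. from first-order propagation of the two independent
uncertainties. Biases of the dwell chain largely cancel in this ratio
(both rates are depressed by similar factors), which is why the titration
recovers its generating intercept to ~3% even though the individual rates
sit ~10% low.

Event-frequency contrasts (e.g. ATP vs ADP) count transitions into the
bound state. The exposure matters: dividing by *total* observation time
mixes the on-rate with bound-state occupancy (conditions with slower
off-rates spend less time able to bind), so conditions are contrasted per
unit **unbound** time — the empirical on-rate — which is the quantity whose
ratio reflects the printed on-rates. `count_event_frequency()` divides by
whatever exposure it is given; `unbound_time()` computes the unbound
exposure from the idealized paths. With the ~3.3-fold on-rate contrast
between ATP and ADP conditions, the pipeline recovers a frequency ratio of
~3.0 (the absorption systematic above hits the fast condition slightly
harder), consistent with an approximately three-fold contrast.

Condition series (salt, ATP concentration, substrate) are tabulated with
fold-changes against the first (reference) condition. Single-condition
K_D bounds use `K_D = c·k_off/k_on`.

# The flow-extension arm

* **Rise fit**: baseline = median pre-injection position;
  `baseline + A(1 − exp(−(t − t_inj)/τ))` by Levenberg–Marquardt
  (`minpack.lm`), initialized from the last-decile mean and the time to
  half-amplitude. The extension *rate* is reported as `A/τ` (the initial
  slope) — the natural single-number rate for an exponential rise.
  Amplitudes below 3× the baseline RMS return an explicit null-extension
  result rather than a noise fit.
* **Saturation**: `A(c) = A_max·c/(S_0.5 + c)`, a rectangular hyperbola
  (Hill coefficient 1 — the minimal single-site form; the data constrain
  only the half-saturation point). Requires ≥3 distinct concentrations.
* **Washout decay**: exponential relaxation toward baseline after the
  washout time; a fitted timescale beyond 10× the observed window is
  reported as non-finite with `decayed = FALSE` rather than as a number.
* **Force calibration**: `F = k_B·T·l/⟨δy²⟩` with the transverse variance
  taken about the **global** mean (the running-mean alternative is not
  identifiable from the assay description; global-mean equipartition is
  the declared interpretation). Defaults: T = 296 K, so
  `k_B·T = 4.087 pN·nm`. The s.e. of F uses the chi-square spread of a
  Gaussian sample variance, `F·√(2/n)`.
* **Net force**: the magnetic lift (surface-normal) and hydrodynamic drag
  (flow-parallel) are orthogonal, so the tether tension is
  `√(F_mag² + F_drag²)`; 1.1 and 2.2 pN combine to 2.46 ≈ 2.5 pN.

The tether length `l` enters only as a scale factor in the calibration;
its default (1000 nm) corresponds to the extended length scale of the
construct, and all recovery tests are self-consistent in `l`.

# Problem sizes and reproducibility

All stochastic stages take explicit seeds; identical seeds reproduce
simulations bit-for-bit, and the pipeline report is deterministic given
its config. The packaged analyses use these sizes, chosen to give
uncertainties comfortably below the effects being measured: 250 traces of
60 s at 50 ms frames for the headline rate/mean recovery (~2,000 complete
events, matching the scale of the reference dataset's 2,362 transitions
from 257 traces); 100 traces per concentration for the five-point
titration; 100 traces per condition for the ATP/ADP contrast; 19 bead
trajectories (the reference dataset's n at 25 mM NaCl) for the amplitude
recovery; 20 replicate grids for the saturation fit. The headline
recovery run searches the full K = 1..4 model range; secondary
per-condition fits (titration concentrations, nucleotide contrast) search
K up to 3 and 2 respectively, since BIC selects K = 2 on two-state
conditions throughout and larger candidates only spend EM iterations. The
analysis scripts under `analysis/` use somewhat smaller sets (40–60
traces) so a full narrative run stays in minutes.

# Limitations

* The dwell-based rates carry the idealization systematic described above;
  treat them as the assay community does — estimates with a known
  camera-bandwidth bias — or read rates off the EM transition matrix.
* Censored dwells are excluded, not survival-corrected; fine while dwells
  are much shorter than traces, increasingly wasteful as they approach the
  trace length.
* The HMM assumes shared emission parameters across traces of a condition;
  per-molecule heterogeneity would be absorbed into the emission width.
* Multi-exponential dwell mixtures, >2-state kinetic schemes, and
  worm-like-chain elasticity of the tether are explicitly out of scope.
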