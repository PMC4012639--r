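---
title: "Temperature compensation of spike generation: model, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature compensation of spike generation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermospike)
```

## The scientific question

Poikilothermic animals operate their nervous systems across a wide range
of body temperatures, yet grasshopper auditory receptor neurons change
their firing rates only mildly with temperature (Q10 of the rate around
1.4–1.5, where many single biochemical rates have Q10 of 2–4). Because
these receptors receive no network input, whatever compensates must be
cell-intrinsic. `thermospike` implements the computational side of that
question: how the temperature dependencies of the ion conductances that
generate spikes combine into the temperature dependence of the
input–output function, which combinations are robust, what they cost
energetically, what they imply for rate coding, and what temperature
dependence of the upstream mechanotransduction step would best restore
the experimentally observed rate–level curves.

## The model

Spike generation is a single-compartment Connor–Stevens model — a type I
(continuous f–I onset) conductance model with transient sodium
(gates $m^3h$), delayed-rectifier potassium ($n^4$), A-type potassium
($a^3b$) and leak currents:

$$C_m \frac{dV}{dt} = I_C - \bar g_L (V{-}E_L) - \bar g_{Na} m^3 h (V{-}E_{Na})
  - \bar g_K n^4 (V{-}E_K) - \bar g_A a^3 b (V{-}E_A),$$

with first-order gate kinetics
$\dot x = (x_\infty(V) - x)/\tau_x(V)$. The reference parameter set is
defined at 18 °C: $\bar g_L = 0.003$, $\bar g_{Na} = 1.2$,
$\bar g_K = 0.2$, $\bar g_A = 0.477$ mS/mm²; $E_L = -17$, $E_{Na} = 55$,
$E_K = -72$, $E_A = -75$ mV. The membrane capacitance is not part of
that printed set; we adopt the conventional 1 µF/cm² (10 nF/mm²) from
the standard parameter source and expose it in `cs_neuron_params()`. A
unit subtlety worth recording: with conductances in mS/mm² and voltages
in mV, currents come out in µA/mm², and µA/nF is V/ms — the integrator
therefore converts $C_m$ to µF/mm² internally so that $\dot V$ is in
mV/ms.

Temperature enters in three places, each controlled by a Q10:

* peak conductances scale as $\bar g_X \cdot Q_{10}^{\Delta T/10}$,
* each gate's opening *and* closing rates share one factor
  $Q_{10}^{\Delta T/10}$ (so $x_\infty$ is unchanged and $\tau_x$ is
  divided by the factor),
* reversal potentials follow the Nernst ratio
  $E(T_0{+}\Delta T) = E(T_0)\,(1 + \Delta T/(T_0 + 273.15))$.

That gives nine free temperature-dependence parameters: four conductance
Q10s (physiological range [1.2, 2.0]) and five gating-rate Q10s
([2.0, 4.0]).

## Metrics

For each parameter combination the f–I curve (12 step currents,
0.05–0.60 µA/mm², 100 ms stimulus flanked by 50 ms silence) is computed
at 18 °C and 28 °C. The temperature robustness score is

$$\mathrm{RMSD} = \frac{\sqrt{\tfrac1N \sum_i (f_{i,\mathrm{cold}} - f_{i,\mathrm{hot}})^2}}
 {\tfrac1N \sum_i f_{i,\mathrm{cold}}},$$

the root-mean-squared rate change across all N = 12 amplitudes
(zero-rate entries included) normalized by the mean cold rate — 0.5
roughly corresponds to a rate Q10 of 1.5. Each curve is also fit by the
type I form $f = A\sqrt{I - I_0}$; the Q10s of slope and threshold
separate the two ways temperature deforms the curve. Energy observables
are the sodium load per spike ($\int |I_{Na}|\,dt$ over stimulus onset
to 20 ms past offset, divided by the spike count), charge-separation
efficiencies, and the resting costs evaluated at the fixed point of the
steady-state current balance. Mean Fisher information over a fixed
firing-rate interval summarizes rate coding; its closed forms are
proportional to $A^4$ for both Poisson and Gaussian rate noise, so
$Q_{10}(\langle J\rangle) = Q_{10}(A)^4$ regardless of the interval or
the noise scale (both are configurable and cancel; the default interval
is 10–300 Hz).

## Numerical choices

* **Integrator.** Fixed-step classical RK4 at dt = 0.01 ms, chosen for
  sweep throughput and strict reproducibility. An embedded
  Dormand–Prince 5(4) integrator with error control is kept as an
  independent oracle; the test suite checks spike-count agreement (±1)
  and subthreshold voltage agreement (< 1 mV) on random grid models.
* **Gating lookup table.** The fixed-step path interpolates the ten
  gating quantities from a 0.02 mV table (linear interpolation,
  relative error ~1e-8); `use_table = FALSE` evaluates the expressions
  exactly, and the two paths are compared in the tests. The adaptive
  oracle always evaluates exactly.
* **Initial condition.** The paper-side protocol does not state one; we
  start at the zero-current steady state (resting potential from
  bracketed root finding at tolerance 1e-9 mV, gates at
  $x_\infty(V_r)$), so the 50 ms pre-window carries no transient. The
  batched sweep path exploits this by not integrating the constant
  pre-window.
* **Resting fixed point.** The steady-state current balance can have
  three roots (N-shaped I–V curve) for some scaled parameter sets; the
  resting potential is defined as the most hyperpolarized root,
  bracketed by a 0.25 mV scan from below. Without this choice a root
  finder can silently land on a depolarized branch and corrupt the
  resting-cost Q10s.
* **Spike convention.** A spike is a strict upward crossing of −30 mV
  (the trace must exceed the threshold; touching it exactly does not
  count), linearly interpolated in time, with a 1 ms lockout. Rates
  count crossings in [stimulus onset, offset).
* **Square-root fit.** For fixed threshold $I_0$ the optimal slope is
  closed-form, so the fit is a 1-D search over $I_0$ constrained below
  the smallest spiking amplitude; zero-rate samples are excluded from
  the residual.
* **Removable singularities** of the two linear-over-exponential rate
  expressions are evaluated by a first-order series within 1e-6 mV of
  the singular voltage.
* **Gaussian Fisher information.** The closed form implemented here
  carries a factor 1/2 relative to a commonly quoted variant:
  $\langle J_G\rangle = A^4 \ln(f_{max}/f_{min}) / (2\sigma^2 (f_{max}^2 - f_{min}^2))$.
  This is the version consistent with direct quadrature of
  $J_G = (f')^2/\sigma^2$ (the package tests enforce agreement to 1e-6
  relative error); the constant factor cancels from every Q10, so no
  comparative statement is affected.

## The sweep and its analyses

`run_sweep()` evaluates every point of a full factorial grid
(`q10_grid(steps)`; 4 steps per parameter give the full 4⁹ = 262,144
models, 2 or 3 steps give smoke grids). Because the cold temperature
equals the reference temperature, the cold curve is Q10-independent and
computed once; resting-state quantities depend only on the four
conductance Q10s and are cached per conductance combination. Sensitivity
is quantified by grid-based elementary effects (`impact_scores()`): for
each parameter, the median of all neighbour differences of the
observable along that parameter's axis, normalized so absolute impacts
sum to one, with 25th/75th percentiles as error bars and a reliability
flag when both percentiles share the median's sign. This is a full
factorial, median-based relative of the Morris one-at-a-time screen.
`dimensional_stack()` renders the grid as a single image with
highest-impact parameters on the outermost axes (ties broken by the
fixed parameter ordering; the horizontal axis is filled first — an
arbitrary but fixed choice).

The RMSD can also be minimized continuously: `minimize_rmsd()` is an
elitist generational GA with 8-bit Gray-coded genes (Gray coding avoids
Hamming cliffs that otherwise stall convergence near the optimum),
binary tournament selection, uniform crossover and per-bit mutation.
The published settings (population 1000, 150 generations) are the
defaults; the test suite uses population 100 × 50 generations × 3
seeds, which reaches RMSD ≈ 0.22.

## Transduction reverse-engineering

The measured rate–level curve $r = \rho(I_{dB})$ is modelled as a
cascade of a sigmoidal mechanotransduction stage
$I_C = \theta(I_{dB}) = I_{C,sat}/(1 + e^{-(I_{dB} - I_{50})/w})$ and
spike generation $\phi(I_C) = A\sqrt{I_C - I_0}$. Given a model's
$(A, I_0)$ at each temperature and a representative receptor response,
`fit_transduction()` finds the $\theta$ minimizing the squared error on
a 32–88 dB grid (1 dB steps, the experimental stimulus range), by
bounded least squares with five deterministic starts; bounds keep
$I_{C,sat}$ within the characterized current range (0, 0.6] µA/mm².
The representative-response defaults (`representative_config()`: 300 Hz
saturation, 55 dB half-max, 4 dB width at 22 °C; parameter Q10s
1.4/1.0/0.8) are documented stand-ins, not measured medians — the
experimental medians are published only as box plots — and every
analysis takes the configuration as an input.

## The synthetic-recording generator

`generate_recordings()` stands in for the intracellular data set: nine
neurons, eight intensities rising 32–88 dB SPL, five trials each, 100 ms
stimuli, two temperatures (22 and 28.5 °C — the centres of the
experimental cold/hot ranges). Per-neuron cold sigmoid parameters are
drawn around the representative medians (log-normal 10% on saturation,
±3 dB on half-max, ±0.5 dB on width); parameter Q10s default to the
compensated values 1.4 (saturation), 1.0 (half-max) and 0.8 (width).
Trial counts are Poisson (or Gaussian with configurable SD, or
noise-free); spike times follow a piecewise-constant profile whose
early ([10, 40) ms) and late ([70, 100) ms) plateaus are directly
controllable, so early-to-late adaptation ratios are exact by
construction (the default is no adaptation, keeping rate recovery
unbiased). Optional 20 kHz traces render each spike as a Gaussian bump
of configured full width at half maximum (1.0 ms cold, width Q10 0.66)
on a −60 mV baseline with additive noise.

What the generator does **not** emulate: biophysical spike shapes,
intensity-dependent latency, serial correlations between trials,
bursting, or recording artefacts. A green recovery test therefore
establishes that the analysis chain (spike extraction → rate–level fit →
Q10 statistics) is unbiased and correctly calibrated for
sigmoid-structured Poisson data of the study's size — not that it would
be robust to every pathology of real recordings.

## Statistics conventions

Q10s of observables use $(x_{hot}/x_{cold})^{10/\Delta T}$ with each
neuron's own $\Delta T$. Box-plot whiskers use the 1.5 IQR rule; values
outside are reported as outliers. Population medians are tested against
1, 1.5 and 2 by two-sided Wilcoxon signed-rank tests (exact for n ≤ 25;
tied samples fall back to the mid-rank normal approximation), and
cold/hot trial rates are compared per intensity by two-sided rank-sum
tests. The slope at the cold half-max intensity is the analytic
derivative of the fitted sigmoid, and the hot curve is evaluated at the
*cold* half-max so the comparison is at a fixed stimulus.

## Scale and what the tests establish

The full 4⁹ sweep is deterministic but takes hours on one CPU; the test
suite therefore runs on desk-scale smoke surfaces: the 512-model corner
grid, a seeded 2000-model random subsample of the full grid (binomial
sampling error is added to each criterion's tolerance), and a scaled GA
budget. `scripts/full_grid.R` reproduces the full-grid figures when
given the time. During development, the complete 3-step grid (19,683
models) was run end to end: RMSD min/median/max 0.225/0.676/2.140,
19.1% of models below 0.5, and the same top-three impact ranking
(Q10(n) positive, Q10(ḡ_A) and Q10(ḡ_K) negative) as the corner grid —
consistent with the full-grid figures throughout.

## Known limitations

* Single compartment, deterministic gating; no channel noise, no
  synaptic input, no morphology.
* Energy accounting covers Na⁺/K⁺ flows only (no Ca²⁺, no pump
  kinetics).
* The representative receptor response is a configurable stand-in;
  conclusions that depend on its exact parameter values should be read
  as conditional on that configuration.
* The sensitivity measure is an elementary-effects screen: it ranks
  main-effect influence and does not decompose interactions.
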