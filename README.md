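# thermospike

Temperature compensation of spike generation in conductance-based neuron
models.

Auditory receptor neurons of grasshoppers barely change their firing
rates when the animal's temperature shifts by 10 °C (rate Q10 around
1.4–1.5), even though the ion-channel kinetics underneath have Q10s of
2–4. These receptors get no network input, so the compensation must be
cell-intrinsic. `thermospike` provides the computational machinery to
study that question in a generic type I spike generator (the
Connor–Stevens model: Na⁺, delayed-rectifier K⁺, A-type K⁺ and leak
currents):

* **Model core** — the temperature-scaled Connor–Stevens model
  (conductance Q10s, shared opening/closing-rate Q10s per gate, Nernst
  scaling of reversals), a fast fixed-step RK4 integrator (dt = 0.01 ms,
  with an adaptive Dormand–Prince oracle), spike detection, f–I curves
  and square-root fits `f = A·sqrt(I − I0)`.
* **Sweep** — the full factorial grid over the nine Q10 parameters
  (4⁹ = 262,144 models at default resolution), scored by the normalized
  RMSD between the 18 °C and 28 °C f–I curves
  (`RMSD = rms(f_cold − f_hot) / mean(f_cold)`; 0.5 ≈ a rate Q10 of
  1.5), plus a seedable genetic-algorithm minimizer.
* **Sensitivity** — grid-based elementary-effects impact scores
  (median neighbour difference per parameter, normalized to unit total)
  and impact-ordered dimensional stacking of the nine-dimensional grid
  into one image.
* **Energetics** — sodium load per spike, charge-separation efficiency,
  resting potential (fixed point of the steady-state current balance)
  and resting costs, with their Q10s.
* **Information** — closed-form mean Fisher information for Poisson and
  Gaussian rate noise over a firing-rate interval;
  `Q10(⟨J⟩) = Q10(A)⁴`.
* **Transduction** — reverse-engineering the sigmoidal
  mechanotransduction curve `θ(I_dB)` whose cascade with a given spike
  generator best matches a representative receptor rate–level curve, and
  the temperature dependence of its three parameters.
* **Synthetic data + analysis** — a seeded generator of
  intracellular-recording-like data sets (9 neurons, 8 intensities
  32–88 dB SPL, 5 trials, two temperatures, Poisson trial noise,
  optional 20 kHz traces with stylized spikes) and the corresponding
  analysis chain (threshold spike extraction, rate–level sigmoid fits,
  Q10 box-plot statistics with rank tests, AP-width and adaptation
  metrics).

See the methods vignette
(`vignettes/temperature-compensation.Rmd`) for the model equations,
parameter meanings, numerical choices and limitations.

## Worked example

```r
library(thermospike)

## f-I curves of the reference model at the two temperatures
fi_c <- compute_fi_curve(cs_neuron_params(), q10_set(), temperature = 18)
fi_h <- compute_fi_curve(cs_neuron_params(), q10_set(), temperature = 28)
head(as.data.frame(fi_c), 4)
#>      I rate
#> 1 0.05    0
#> 2 0.10   30
#> 3 0.15   80
#> 4 0.20  130

fc <- attr(fi_c, "fit", exact = TRUE)
fh <- attr(fi_h, "fit", exact = TRUE)
c(A = fc$A, I0 = fc$I0, R2 = fc$r_squared)
#> cold: A = 414.8  I0 = 0.0961  R2 = 0.995
#> hot:  A = 808.6  I0 = 0.1951  R2 = 0.988

rmsd(fi_c$rate, fi_h$rate)   # 0.734: the midpoint-Q10 model is NOT compensated
q10_of(fc$A, fh$A, dT = 10)  # 1.95: heating steepens the f-I curve
fisher_q10(1.95)             # 14.4: information transfer rises sharply
```

The slope always rises with heating; compensation, where it occurs on
the Q10 grid, comes from a balancing rise in threshold. Which Q10s
matter is an impact-score question:

```r
sw  <- run_sweep(q10_grid(2))          # 512-model corner grid, ~1 min
imp <- impact_scores(sw, "rmsd")
imp[order(-abs(imp$impact)), c("parameter", "impact", "reliable")]
#>  parameter  impact reliable      (top rows)
#>          n  +0.300     TRUE
#>        g_A  -0.208     TRUE
#>        g_K  -0.150     TRUE
```

— the three potassium-channel temperature dependencies dominate the
robustness of the firing rate. The energetic side reduces, at rest, to
the conductance Q10s alone:

```r
fr <- resting_cost_q10_fraction()  # 4^4 = 256 combinations, seconds
fr$percent
#> 76.6   # % of combinations whose Na-based resting cost falls on heating
```

## Command line

A thin CLI over the pipeline lives at `inst/cli/thermospike`
(`sweep`, `impacts`, `stack`, `transduce`, `synth`, `analyze`, `all`,
`info`); every run archives its configuration and hash beside the
outputs, and unchanged reruns are cache hits.
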