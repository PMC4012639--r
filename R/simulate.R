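# Model core: stimulation protocol, voltage simulation, spike detection,
# f-I curves and their square-root fits.

#' Step-current stimulation protocol
#'
#' Defaults reproduce the standard protocol: 50 ms silent pre-window, a
#' 100 ms step of constant current, 50 ms silent post-window, and N = 12
#' amplitudes from 0.05 to 0.60 uA/mm^2 in 0.05 steps.
#'
#' @param t_pre,t_stim,t_post Durations in ms (all > 0).
#' @param amplitudes Step-current amplitudes in uA/mm^2.
#' @return Object of class `stimulus_protocol` with fields `t_pre`,
#'   `t_stim`, `t_post`, `amplitudes`, and the stimulus window
#'   `t_start`/`t_stop` on the simulation clock (time 0 = start of the
#'   pre-window).
#' @export
stimulus_protocol <- function(t_pre = 50, t_stim = 100, t_post = 50,
                              amplitudes = seq(0.05, 0.6, by = 0.05)) {
  if (t_pre <= 0 || t_stim <= 0 || t_post <= 0)
    stop("durations must be > 0")
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  structure(list(t_pre = t_pre, t_stim = t_stim, t_post = t_post,
                 amplitudes = amplitudes,
                 t_start = t_pre, t_stop = t_pre + t_stim),
            class = "stimulus_protocol")
}

# Steady state of the full system at I = 0 for already-scaled parameters:
# resting potential plus gates at x_inf(V_rest).
initial_state <- function(scaled_params) {
  vr <- resting_potential(scaled_params)
  g <- gating_rates(vr)
  c(vr, g$m_inf, g$h_inf, g$n_inf, g$a_inf, g$b_inf)
}

#' Simulate the membrane-potential response to a current step
#'
#' Integrates the six-state system (V, m, h, n, a, b) of the
#' temperature-scaled Connor-Stevens model over the pre/stimulus/post
#' windows, with the step current applied only during the stimulus window.
#' The initial condition is the zero-current steady state, so the silent
#' pre-window absorbs residual transients. The default integrator is
#' fixed-step RK4 at `dt = 0.01` ms; `method = "adaptive"` uses an
#' embedded Dormand-Prince 5(4) pair with error control, which serves as an
#' independent cross-check of the fixed-step results.
#'
#' @param params Reference-temperature [cs_neuron_params()].
#' @param q10s A [q10_set()]; ignored for the temperature scaling when
#'   `dT = 0` (all multipliers are then 1).
#' @param dT Temperature difference from `params$T0` in degrees C.
#' @param amplitude Step-current amplitude in uA/mm^2 (>= 0).
#' @param protocol A [stimulus_protocol()]; its `amplitudes` field is not
#'   used here.
#' @param dt Time step in ms for the fixed-step integrator (<= 0.01 unless
#'   `relax_dt = TRUE`).
#' @param method `"rk4"` (fixed step) or `"adaptive"` (Dormand-Prince 5(4)).
#' @param use_table Use the precomputed gating lookup table (0.02 mV
#'   resolution, linearly interpolated) in the fixed-step integrator; set
#'   to `FALSE` for exact rate evaluation at every step.
#' @param threshold Spike-detection threshold in mV.
#' @param relax_dt Allow `dt > 0.01` ms (for quick experiments only).
#' @param rtol,atol Error tolerances for the adaptive integrator.
#' @return A `cs_trace` object: a data.frame with columns `time`, `V`, the
#'   five gating variables, the per-channel currents `I_Na`, `I_K`, `I_A`,
#'   `I_L` and the injected current `I_C`, with attributes `temperature`,
#'   `amplitude`, `dt`, `protocol` and `spike_times` (detected during
#'   integration). The adaptive method returns voltage only (sampled onto
#'   the fixed grid) plus spike times.
#' @export
simulate_voltage <- function(params = cs_neuron_params(),
                             q10s = q10_set(), dT = 0, amplitude,
                             protocol = stimulus_protocol(), dt = 0.01,
                             method = c("rk4", "adaptive"),
                             use_table = TRUE, threshold = -30,
                             relax_dt = FALSE, rtol = 1e-8, atol = 1e-8) {
  method <- match.arg(method)
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (method == "rk4" && dt > 0.01 + 1e-12 && !relax_dt)
    stop("dt must be <= 0.01 ms for the fixed-step integrator")
  sc <- temperature_scale(params, q10s, dT)
  p <- sc$params
  y0 <- initial_state(p)
  gbar <- c(p$g_L, p$g_Na, p$g_K, p$g_A)
  erev <- c(p$E_L, p$E_Na, p$E_K, p$E_A)
  if (method == "rk4") {
    res <- cs_simulate_cpp(gbar, erev, p$C_m, sc$rate_factors, amplitude,
                           protocol$t_pre, protocol$t_stim, protocol$t_post,
                           dt, threshold, y0, TRUE, use_table)
    tr <- as.data.frame(res$trace)
  } else {
    t_out <- seq(0, protocol$t_pre + protocol$t_stim + protocol$t_post,
                 by = dt)
    res <- cs_simulate_adaptive_cpp(gbar, erev, p$C_m, sc$rate_factors,
                                    amplitude, protocol$t_pre,
                                    protocol$t_stim, protocol$t_post,
                                    threshold, y0, t_out, rtol, atol)
    tr <- data.frame(time = t_out, V = res$V)
  }
  structure(tr, class = c("cs_trace", "data.frame"),
            temperature = params$T0 + dT, amplitude = amplitude, dt = dt,
            protocol = protocol, spike_times = res$spike_times,
            na_load = res$na_load, method = method)
}

#' Detect spikes as threshold crossings
#'
#' A spike is a strict upward crossing of the threshold:
#' `V[i] < threshold < V[i+1]`. The spike time is linearly interpolated
#' between the two samples. A trace that touches the threshold exactly
#' without exceeding it is not counted. A
#' refractory lockout (default 1 ms) suppresses double counting on noisy
#' traces.
#'
#' @param trace A `cs_trace` or any data.frame with `time` and `V` columns
#'   (alternatively pass `time` and `V` vectors via `V`).
#' @param threshold Threshold in mV.
#' @param lockout Minimum separation between successive spikes in ms.
#' @param time Optional time vector when `trace` is a plain voltage vector.
#' @return Numeric vector of spike times (ms); empty for subthreshold
#'   traces.
#' @export
detect_spikes <- function(trace, threshold = -30, lockout = 1,
                          time = NULL) {
  if (is.data.frame(trace)) {
    v <- trace$V
    t <- trace$time
  } else {
    v <- as.numeric(trace)
    t <- if (is.null(time)) seq_along(v) - 1 else time
  }
  if (length(v) == 0) stop("trace is empty")
  i <- which(v[-length(v)] < threshold & v[-1] > threshold)
  if (length(i) == 0) return(numeric(0))
  ts <- t[i] + (t[i + 1] - t[i]) * (threshold - v[i]) / (v[i + 1] - v[i])
  keep <- logical(length(ts))
  last <- -Inf
  for (k in seq_along(ts)) {
    if (ts[k] - last >= lockout) {
      keep[k] <- TRUE
      last <- ts[k]
    }
  }
  ts[keep]
}

#' Compute the f-I curve at one temperature
#'
#' Simulates the model response to every amplitude in the protocol and
#' converts spike counts to rates. The rate at each amplitude is the number
#' of detected spikes whose (interpolated) time falls in the stimulus
#' window `[t_start, t_stop)` divided by the stimulus duration. A
#' square-root fit (see [fit_sqrt()]) is attached when at least two
#' amplitudes elicit spikes.
#'
#' @inheritParams simulate_voltage
#' @param temperature Absolute temperature in degrees C (`dT` is derived as
#'   `temperature - params$T0`).
#' @param energy Also record the sodium/potassium load integrals per
#'   amplitude (used by the energy observables).
#' @return An `fi_curve` object: data.frame with columns `I` (uA/mm^2) and
#'   `rate` (Hz), attributes `temperature`, `fit` (list with `A`, `I0`,
#'   `r_squared`, or `NULL` with `fit_note` when undefined) and, when
#'   `energy = TRUE`, `energy` (per-amplitude load integrals and spike
#'   counts).
#' @export
compute_fi_curve <- function(params = cs_neuron_params(),
                             q10s = q10_set(), temperature = 18,
                             protocol = stimulus_protocol(), dt = 0.01,
                             use_table = TRUE, threshold = -30,
                             energy = TRUE) {
  if (length(protocol$amplitudes) < 2)
    stop("protocol must contain at least 2 amplitudes")
  dT <- temperature - params$T0
  sc <- temperature_scale(params, q10s, dT)
  p <- sc$params
  y0 <- initial_state(p)
  gbar <- c(p$g_L, p$g_Na, p$g_K, p$g_A)
  erev <- c(p$E_L, p$E_Na, p$E_K, p$E_A)
  res <- tryCatch(
    cs_fi_batch_cpp(gbar, erev, p$C_m, sc$rate_factors,
                    protocol$amplitudes, protocol$t_pre, protocol$t_stim,
                    protocol$t_post, dt, threshold, y0, use_table, TRUE),
    error = function(e) stop("simulation failed at one of the amplitudes: ",
                             conditionMessage(e), call. = FALSE))
  rate <- res$n_spikes_stim / (protocol$t_stim / 1000)  # Hz
  df <- data.frame(I = protocol$amplitudes, rate = rate)
  fit <- NULL
  fit_note <- NULL
  if (sum(rate > 0) >= 2) {
    fit <- fit_sqrt(df$I, df$rate)
  } else {
    fit_note <- "undefined: fewer than 2 suprathreshold amplitudes"
  }
  en <- NULL
  if (energy) {
    en <- data.frame(I = protocol$amplitudes,
                     n_spikes = res$n_spikes_stim,
                     na_load = res$na_load, k_load = res$k_load,
                     na_excess = res$na_excess, k_excess = res$k_excess)
  }
  structure(df, class = c("fi_curve", "data.frame"),
            temperature = temperature, fit = fit, fit_note = fit_note,
            energy = en, gate_min = min(res$gate_min),
            gate_max = max(res$gate_max), v_rest = y0[1],
            protocol = protocol, dt = dt)
}

#' Square-root fit of a type I f-I curve
#'
#' Fits `f(I) = A * sqrt(I - I0)` for `I > I0` (zero below) to the
#' suprathreshold samples of an f-I curve by least squares. Zero-rate
#' samples are excluded from the residual. For a fixed threshold `I0` the
#' optimal slope has the closed form
#' `A(I0) = sum(f*sqrt(I-I0)) / sum(I-I0)`, so the problem is solved by a
#' one-dimensional golden-section/parabolic search over `I0`, constrained
#' below the smallest spiking amplitude. The search is initialised at the
#' midpoint between the largest subthreshold and the smallest
#' suprathreshold amplitude.
#'
#' @param I Current amplitudes (uA/mm^2), same length as `rate`.
#' @param rate Firing rates (Hz).
#' @return List with `A` (Hz per sqrt(uA/mm^2)), `I0` (uA/mm^2),
#'   `r_squared` (over the fitted samples) and `n_fit`.
#' @export
fit_sqrt <- function(I, rate) {
  if (inherits(I, "fi_curve")) {
    rate <- I$rate
    I <- I$I
  }
  stopifnot(length(I) == length(rate))
  ord <- order(I)
  I <- I[ord]; rate <- rate[ord]
  spk <- rate > 0
  if (sum(spk) < 2) stop("insufficient suprathreshold points")
  i_min <- min(I[spk])
  sub <- I[!spk & I < i_min]
  hi <- i_min - 1e-9
  lo <- i_min - 10 * max(diff(range(I)), i_min, 1)
  Is <- I[spk]; fs <- rate[spk]
  sse <- function(i0) {
    s <- sqrt(Is - i0)
    a <- sum(fs * s) / sum(Is - i0)
    sum((fs - a * s)^2)
  }
  # bracket around the midpoint initialisation, then polish
  opt <- optimize(sse, lower = lo, upper = hi, tol = 1e-12)
  i0 <- opt$minimum
  s <- sqrt(Is - i0)
  a <- sum(fs * s) / sum(Is - i0)
  ss_res <- sum((fs - a * s)^2)
  ss_tot <- sum((fs - mean(fs))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else if (ss_res < 1e-12) 1 else NA_real_
  list(A = a, I0 = i0, r_squared = r2, n_fit = sum(spk))
}

#' Evaluate a square-root f-I fit
#' @param fit List with `A` and `I0` as returned by [fit_sqrt()].
#' @param I Currents at which to evaluate.
#' @return Rates in Hz (0 at and below threshold).
#' @export
predict_sqrt <- function(fit, I) {
  ifelse(I > fit$I0, fit$A * sqrt(pmax(I - fit$I0, 0)), 0)
}

#' Export an f-I curve as CSV
#' @param fi An `fi_curve`.
#' @param path Output file.
#' @export
write_fi_csv <- function(fi, path) {
  df <- data.frame(I_C = fi$I, rate = fi$rate,
                   temperature = attr(fi, "temperature"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
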