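# Synthetic intracellular-recording generator: sigmoidal rate-level
# structure with known parameter Q10s, trial noise, a controllable
# early/late adaptation profile, and optional stylized voltage traces.

#' Specification of a synthetic recording set
#'
#' Defaults emulate the shape of the experimental data set: nine receptor
#' neurons, eight sound intensities rising from 32 to 88 dB SPL, five
#' trials per intensity, 100 ms stimuli, recordings at ~22 and ~28.5 C,
#' Poisson trial noise, and sigmoidal rate-level curves whose parameter
#' Q10s default to 1.4 (saturation rate), 1.0 (half-max level) and 0.8
#' (dynamic-range width).
#'
#' @param n_neurons Number of neurons.
#' @param temperatures Two recording temperatures (degrees C), cold first.
#' @param intensities Strictly increasing sound intensities (dB SPL).
#' @param trials Trials per intensity and temperature (>= 1).
#' @param stim_ms,pre_ms,post_ms Stimulus / silent-window durations (ms).
#' @param noise `"poisson"`, `"gaussian"` (rate noise with SD `sigma` Hz)
#'   or `"none"` (deterministic counts).
#' @param sigma Gaussian rate-noise SD in Hz.
#' @param cold_params Optional data.frame with columns `sat`, `i50`,
#'   `width` (one row per neuron). When NULL, per-neuron parameters are
#'   drawn around the population medians (sat ~ 300 Hz lognormal 10%,
#'   i50 ~ N(55, 3) dB, width ~ N(4, 0.5) dB) deterministically from
#'   `seed`.
#' @param param_q10 Named Q10s of `sat`, `i50`, `width`.
#' @param adapt_early,adapt_late Rate multipliers of the early
#'   ([10, 40) ms) and late ([70, 100) ms) plateaus of the within-stimulus
#'   rate profile; the remainder of the stimulus is at the base rate.
#'   Defaults 1/1 (no adaptation) keep trial rates unbiased.
#' @param ap_width_cold Action-potential full width at half maximum (ms)
#'   at the cold temperature for rendered traces.
#' @param ap_width_q10 Q10 of the AP width (default 0.66, i.e. narrower
#'   spikes when warm).
#' @param render_traces Render 20 kHz voltage-like traces.
#' @param trace_fs Trace sampling rate (Hz).
#' @param trace_noise_sd Gaussian trace noise SD (mV).
#' @param seed RNG seed; fixes the entire data set.
#' @return A `generator_spec`.
#' @export
generator_spec <- function(n_neurons = 9, temperatures = c(22, 28.5),
                           intensities = seq(32, 88, length.out = 8),
                           trials = 5, stim_ms = 100, pre_ms = 50,
                           post_ms = 50,
                           noise = c("poisson", "gaussian", "none"),
                           sigma = 30, cold_params = NULL,
                           param_q10 = c(sat = 1.4, i50 = 1.0,
                                         width = 0.8),
                           adapt_early = 1, adapt_late = 1,
                           ap_width_cold = 1.0, ap_width_q10 = 0.66,
                           render_traces = FALSE, trace_fs = 20000,
                           trace_noise_sd = 0.5, seed = 1) {
  noise <- match.arg(noise)
  if (trials < 1) stop("trials must be >= 1")
  if (any(diff(intensities) <= 0))
    stop("intensities must be strictly increasing")
  if (length(temperatures) != 2 || temperatures[1] >= temperatures[2])
    stop("temperatures must be (cold, hot) with cold < hot")
  if (noise == "gaussian" && sigma < 0) stop("sigma must be >= 0")
  if (ap_width_cold <= 0 || ap_width_q10 <= 0) stop("widths must be > 0")
  structure(list(n_neurons = n_neurons, temperatures = temperatures,
                 intensities = intensities, trials = trials,
                 stim_ms = stim_ms, pre_ms = pre_ms, post_ms = post_ms,
                 noise = noise, sigma = sigma, cold_params = cold_params,
                 param_q10 = param_q10, adapt_early = adapt_early,
                 adapt_late = adapt_late, ap_width_cold = ap_width_cold,
                 ap_width_q10 = ap_width_q10,
                 render_traces = render_traces, trace_fs = trace_fs,
                 trace_noise_sd = trace_noise_sd, seed = seed),
            class = "generator_spec")
}

# Per-neuron cold sigmoid parameters: user-supplied or drawn around the
# population medians, deterministically from spec$seed.
resolve_neuron_params <- function(spec) {
  if (!is.null(spec$cold_params)) {
    stopifnot(nrow(spec$cold_params) == spec$n_neurons)
    return(spec$cold_params)
  }
  set.seed(spec$seed)
  data.frame(sat = 300 * exp(rnorm(spec$n_neurons, 0, 0.1)),
             i50 = rnorm(spec$n_neurons, 55, 3),
             width = pmax(rnorm(spec$n_neurons, 4, 0.5), 1.5))
}

#' Ground-truth parameters of a synthetic recording set
#'
#' @param spec A [generator_spec()].
#' @return Data frame with one row per neuron and parameter: cold and hot
#'   values plus the exact Q10 (`q10_of(cold, hot, dT)`).
#' @export
ground_truth_table <- function(spec) {
  cp <- resolve_neuron_params(spec)
  dT <- diff(spec$temperatures)
  f <- dT / 10
  out <- list()
  for (p in c("sat", "i50", "width")) {
    cold <- cp[[p]]
    hot <- cold * spec$param_q10[[p]]^f
    out[[p]] <- data.frame(neuron = seq_len(spec$n_neurons),
                           parameter = p, cold = cold, hot = hot,
                           q10 = q10_of(cold, hot, dT))
  }
  do.call(rbind, out)
}

# within-stimulus rate profile, piecewise-constant: base rate everywhere,
# early/late multipliers on [10,40) and [70,100) ms
adaptation_profile <- function(spec) {
  br <- c(0, 10, 40, 70, min(100, spec$stim_ms), spec$stim_ms)
  br <- unique(pmin(br, spec$stim_ms))
  lev <- c(1, spec$adapt_early, 1, spec$adapt_late, 1)[seq_len(length(br) - 1)]
  list(breaks = br, levels = lev)
}

sample_spike_times <- function(n, profile, stim_ms) {
  if (n == 0) return(numeric(0))
  w <- diff(profile$breaks) * profile$levels
  seg <- sample.int(length(w), n, replace = TRUE, prob = w)
  sort(profile$breaks[seg] + runif(n) * diff(profile$breaks)[seg])
}

#' Generate a synthetic recording set
#'
#' Draws, for every (neuron, temperature, intensity, trial), a spike count
#' from the configured noise model around `rho_T(I_dB) * duration`, places
#' the spikes according to the early/late adaptation profile, and
#' optionally renders voltage-like traces (stylized Gaussian action
#' potentials of the configured half-max width on a -60 mV baseline, with
#' a silent pre-window). The whole data set is a deterministic function of
#' `spec$seed`.
#'
#' @param spec A [generator_spec()].
#' @return A `synthetic_recordings` object: list with `spikes` (data.frame
#'   `neuron`, `temperature`, `intensity`, `trial`, `spike_time_ms`; times
#'   relative to stimulus onset), `rates` (per-trial rates in Hz),
#'   `traces` (nested list, or NULL), `ground_truth` and `spec`.
#' @export
generate_recordings <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  cp <- resolve_neuron_params(spec)
  gt <- ground_truth_table(spec)
  profile <- adaptation_profile(spec)
  dur_s <- spec$stim_ms / 1000
  set.seed(spec$seed + 1L)  # separate stream from the parameter draw
  n_int <- length(spec$intensities)
  n_rows <- spec$n_neurons * 2 * n_int * spec$trials
  rate_neuron <- integer(n_rows); rate_temp <- numeric(n_rows)
  rate_int <- numeric(n_rows); rate_trial <- integer(n_rows)
  rate_val <- numeric(n_rows)
  spike_list <- vector("list", n_rows)
  traces <- if (spec$render_traces) list() else NULL
  row <- 0L
  for (ni in seq_len(spec$n_neurons)) {
    if (spec$render_traces) traces[[ni]] <- list()
    for (ti in 1:2) {
      temp <- spec$temperatures[ti]
      f <- (temp - spec$temperatures[1]) / 10
      resp <- sigmoid_response(cp$sat[ni] * spec$param_q10[["sat"]]^f,
                               cp$i50[ni] * spec$param_q10[["i50"]]^f,
                               cp$width[ni] * spec$param_q10[["width"]]^f)
      if (spec$render_traces) traces[[ni]][[ti]] <- list()
      for (ii in seq_len(n_int)) {
        lambda <- sigmoid_eval(resp, spec$intensities[ii]) * dur_s
        if (spec$render_traces) traces[[ni]][[ti]][[ii]] <- list()
        for (tr in seq_len(spec$trials)) {
          count <- switch(spec$noise,
            poisson = rpois(1, lambda),
            gaussian = max(0L, as.integer(round(
              lambda + rnorm(1, 0, spec$sigma * dur_s)))),
            none = as.integer(round(lambda)))
          st <- sample_spike_times(count, profile, spec$stim_ms)
          row <- row + 1L
          rate_neuron[row] <- ni; rate_temp[row] <- temp
          rate_int[row] <- spec$intensities[ii]; rate_trial[row] <- tr
          rate_val[row] <- count / dur_s
          spike_list[[row]] <- st
          if (spec$render_traces)
            traces[[ni]][[ti]][[ii]][[tr]] <- render_trace(spec, temp, st)
        }
      }
    }
  }
  counts <- lengths(spike_list)
  spikes <- data.frame(
    neuron = rep(rate_neuron, counts),
    temperature = rep(rate_temp, counts),
    intensity = rep(rate_int, counts),
    trial = rep(rate_trial, counts),
    spike_time_ms = unlist(spike_list, use.names = FALSE))
  rates <- data.frame(neuron = rate_neuron, temperature = rate_temp,
                      intensity = rate_int, trial = rate_trial,
                      rate = rate_val)
  structure(list(spikes = spikes, rates = rates, traces = traces,
                 ground_truth = gt, spec = spec),
            class = "synthetic_recordings")
}

# Stylized voltage trace: -60 mV baseline, Gaussian bumps of 60 mV
# amplitude at each spike time (absolute time = pre_ms + spike time).
render_trace <- function(spec, temperature, spike_times) {
  dt_ms <- 1000 / spec$trace_fs
  t <- seq(0, spec$pre_ms + spec$stim_ms + spec$post_ms, by = dt_ms)
  v <- rep(-60, length(t))
  f <- (temperature - spec$temperatures[1]) / 10
  fwhm <- spec$ap_width_cold * spec$ap_width_q10^f
  s <- fwhm / (2 * sqrt(2 * log(2)))
  for (ts in spike_times) {
    tc <- spec$pre_ms + ts
    idx <- which(abs(t - tc) < 5 * s + 4 * dt_ms)
    v[idx] <- v[idx] + 60 * exp(-(t[idx] - tc)^2 / (2 * s^2))
  }
  if (spec$trace_noise_sd > 0)
    v <- v + rnorm(length(v), 0, spec$trace_noise_sd)
  structure(v, fs = spec$trace_fs, pre_ms = spec$pre_ms,
            stim_ms = spec$stim_ms, temperature = temperature,
            ap_fwhm = fwhm)
}

#' Write a synthetic recording set as per-neuron TSV directories
#' @param rec A `synthetic_recordings`.
#' @param dir Output directory; one subdirectory per neuron with a
#'   `spikes.tsv` (columns temperature, intensity, trial, spike_time_ms)
#'   plus a top-level `spec.json`.
#' @export
write_recordings <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ni in seq_len(rec$spec$n_neurons)) {
    nd <- file.path(dir, sprintf("neuron_%02d", ni))
    dir.create(nd, showWarnings = FALSE)
    sub <- rec$spikes[rec$spikes$neuron == ni,
                      c("temperature", "intensity", "trial",
                        "spike_time_ms")]
    write.table(sub, file.path(nd, "spikes.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  cfg <- rec$spec
  cfg$cold_params <- NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a recording directory written by [write_recordings()]
#' @param dir Directory path.
#' @return Data frame in the same layout as the `spikes` element of a
#'   `synthetic_recordings`.
#' @export
read_recordings <- function(dir) {
  nd <- sort(list.dirs(dir, recursive = FALSE))
  out <- list()
  for (k in seq_along(nd)) {
    sub <- read.delim(file.path(nd[k], "spikes.tsv"))
    sub$neuron <- k
    out[[k]] <- sub[, c("neuron", "temperature", "intensity", "trial",
                        "spike_time_ms")]
  }
  do.call(rbind, out)
}
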