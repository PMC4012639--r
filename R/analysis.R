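# Analysis of (synthetic or real) receptor recordings: spike extraction
# from traces, rate-level sigmoid fits, Q10 statistics with box-plot and
# rank-test conventions, AP-width Q10 and early/late adaptation ratios.

#' Extract spike times from a sampled voltage trace
#'
#' The detection threshold is set relative to the background: baseline
#' median of the silent pre-stimulus window plus `k` times the noise scale
#' (median absolute deviation of the same window). Spikes are strict
#' upward crossings of that threshold with a 1 ms lockout, linearly
#' interpolated between samples.
#'
#' @param trace Numeric voltage vector; attributes `fs` (Hz) and `pre_ms`
#'   are used when present, otherwise pass them explicitly.
#' @param fs Sampling rate in Hz.
#' @param pre_ms Duration of the pre-stimulus window (must be > 0).
#' @param k Threshold in noise-scale units above baseline (default 5).
#' @param lockout Refractory lockout in ms.
#' @return Spike times in ms from trace start.
#' @export
extract_spikes <- function(trace, fs = attr(trace, "fs"),
                           pre_ms = attr(trace, "pre_ms"), k = 5,
                           lockout = 1) {
  if (is.null(fs)) stop("sampling rate fs is required")
  if (is.null(pre_ms) || pre_ms <= 0)
    stop("a pre-stimulus window is required to estimate the noise level")
  v <- as.numeric(trace)
  t <- (seq_along(v) - 1) * 1000 / fs
  pre <- v[t < pre_ms]
  noise <- mad(pre)
  if (noise == 0) noise <- max(sd(pre), 1e-6)
  thr <- median(pre) + k * noise
  sp <- detect_spikes(v, threshold = thr, lockout = lockout, time = t)
  if (length(sp) < 2) return(sp)
  # hysteresis: a new event is only armed once the trace has dropped
  # halfway back towards baseline, which suppresses noise-driven
  # re-crossings on the falling flank
  rearm <- median(pre) + k * noise / 2
  keep <- logical(length(sp))
  keep[1] <- TRUE
  last <- sp[1]
  for (j in 2:length(sp)) {
    seg <- v[t > last & t < sp[j]]
    if (length(seg) && min(seg) < rearm) {
      keep[j] <- TRUE
      last <- sp[j]
    }
  }
  sp[keep]
}

#' Fit a three-parameter sigmoid to a rate-level curve
#'
#' Bounded nonlinear least squares of
#' `r(I_dB) = sat / (1 + exp(-(I_dB - i50)/width))` on per-intensity mean
#' rates, with a small deterministic multi-start. Requires at least four
#' intensities. Data the sigmoid describes poorly (R^2 < `r2_flag`) are
#' flagged rather than silently parameterized.
#'
#' @param intensity Sound intensities (dB SPL).
#' @param rate Mean firing rates (Hz).
#' @param r2_flag Flagging threshold for non-sigmoidal data.
#' @return List with `resp` (a [sigmoid_response()] or NULL when
#'   flagged), `r_squared`, `flagged`.
#' @export
fit_response_curve <- function(intensity, rate, r2_flag = 0.5) {
  if (length(intensity) < 4) stop("need >= 4 intensities")
  stopifnot(length(intensity) == length(rate))
  ord <- order(intensity)
  x <- intensity[ord]; y <- rate[ord]
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0)
    return(list(resp = NULL, r_squared = NA_real_, flagged = TRUE))
  span <- diff(range(x))
  lower <- c(max(y) * 0.2 + 1e-6, min(x) - span, 0.1)
  upper <- c(max(y) * 3 + 10, max(x) + span, 4 * span)
  half <- max(y) / 2
  i50_0 <- x[which.min(abs(y - half))]
  obj <- function(p)
    sum((y - p[1] / (1 + exp(-(x - p[2]) / p[3])))^2)
  starts <- rbind(c(max(y), i50_0, span / 8),
                  c(max(y) * 1.2, i50_0, span / 4),
                  c(max(y), i50_0 + span / 8, span / 16))
  best <- NULL
  for (kk in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(starts[kk, ], lower), upper)
    res <- tryCatch(
      optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best)) return(list(resp = NULL, r_squared = NA_real_,
                                 flagged = TRUE))
  r2 <- 1 - best$value / ss_tot
  if (r2 < r2_flag)
    return(list(resp = NULL, r_squared = r2, flagged = TRUE))
  list(resp = sigmoid_response(best$par[1], best$par[2], best$par[3]),
       r_squared = r2, flagged = FALSE)
}

#' Analyse a two-temperature recording set
#'
#' Computes per-trial firing rates (spikes in the stimulus window divided
#' by its duration), fits the rate-level sigmoid per neuron and
#' temperature, and derives the observables compared across temperatures:
#' the three sigmoid parameters, the rate at the cold half-max intensity
#' (both temperatures evaluated at the cold i50, so the comparison is at a
#' fixed stimulus) and the analytic slope of the fitted sigmoid at the
#' cold i50.
#'
#' @param rec A `synthetic_recordings`, a spikes data.frame in its layout,
#'   or a directory written by [write_recordings()].
#' @param stim_ms Stimulus duration in ms (taken from the recording spec
#'   when available).
#' @param trials Trials per intensity (for zero-spike trial accounting
#'   when only a spikes table is given).
#' @return A `recording_analysis`: list with `rates` (per-trial), `fits`
#'   (per neuron x temperature: parameters + R^2), `q10` (per neuron: Q10
#'   of each observable) and `temperatures`.
#' @export
analyze_recordings <- function(rec, stim_ms = NULL, trials = NULL) {
  if (is.character(rec)) rec <- read_recordings(rec)
  if (inherits(rec, "synthetic_recordings")) {
    rates <- rec$rates
    if (is.null(stim_ms)) stim_ms <- rec$spec$stim_ms
  } else {
    spikes <- rec
    if (is.null(stim_ms)) stop("stim_ms required for plain spike tables")
    if (is.null(trials)) trials <- max(spikes$trial)
    grid <- unique(spikes[, c("neuron", "temperature", "intensity")])
    grid <- expand.grid(
      neuron = sort(unique(spikes$neuron)),
      temperature = sort(unique(spikes$temperature)),
      intensity = sort(unique(spikes$intensity)),
      trial = seq_len(trials))
    cnt <- aggregate(
      spike_time_ms ~ neuron + temperature + intensity + trial,
      data = spikes[spikes$spike_time_ms >= 0 &
                      spikes$spike_time_ms < stim_ms, ],
      FUN = length)
    names(cnt)[5] <- "n"
    rates <- merge(grid, cnt, all.x = TRUE)
    rates$n[is.na(rates$n)] <- 0
    rates$rate <- rates$n / (stim_ms / 1000)
  }
  temps <- sort(unique(rates$temperature))
  stopifnot(length(temps) == 2)
  neurons <- sort(unique(rates$neuron))
  mean_rates <- aggregate(rate ~ neuron + temperature + intensity,
                          data = rates, FUN = mean)
  fits <- list()
  q10_rows <- list()
  dT_all <- diff(temps)
  for (ni in neurons) {
    per_temp <- list()
    for (ti in 1:2) {
      mr <- mean_rates[mean_rates$neuron == ni &
                         mean_rates$temperature == temps[ti], ]
      mr <- mr[order(mr$intensity), ]
      ft <- fit_response_curve(mr$intensity, mr$rate)
      per_temp[[ti]] <- c(ft, list(mean_rates = mr))
      fits[[length(fits) + 1]] <- data.frame(
        neuron = ni, temperature = temps[ti],
        sat = if (ft$flagged) NA_real_ else ft$resp$sat,
        i50 = if (ft$flagged) NA_real_ else ft$resp$i50,
        width = if (ft$flagged) NA_real_ else ft$resp$width,
        r_squared = ft$r_squared, flagged = ft$flagged)
    }
    fc <- per_temp[[1]]; fh <- per_temp[[2]]
    if (!fc$flagged && !fh$flagged) {
      i50c <- fc$resp$i50
      obs_c <- c(sat = fc$resp$sat, i50 = fc$resp$i50,
                 width = fc$resp$width,
                 rate_at_half = sigmoid_eval(fc$resp, i50c),
                 slope_at_half = sigmoid_slope(fc$resp, i50c))
      obs_h <- c(sat = fh$resp$sat, i50 = fh$resp$i50,
                 width = fh$resp$width,
                 rate_at_half = sigmoid_eval(fh$resp, i50c),
                 slope_at_half = sigmoid_slope(fh$resp, i50c))
      q10_rows[[length(q10_rows) + 1]] <- data.frame(
        neuron = ni, observable = names(obs_c), cold = obs_c,
        hot = obs_h, q10 = q10_of(obs_c, obs_h, dT_all))
    }
  }
  structure(list(rates = rates,
                 fits = do.call(rbind, fits),
                 q10 = if (length(q10_rows)) do.call(rbind, q10_rows)
                       else NULL,
                 temperatures = temps, stim_ms = stim_ms),
            class = "recording_analysis")
}

#' Population Q10 statistics and hypothesis tests
#'
#' Per observable: median and quartiles of the per-neuron Q10s, whiskers
#' and outliers under the 1.5 IQR rule (`[q1 - 1.5 iqr, q3 + 1.5 iqr]`),
#' and two-sided Wilcoxon signed-rank tests of the median against 1, 1.5
#' and 2. Additionally, a two-sided rank-sum test per neuron and intensity
#' compares the trial rates across temperatures. Exact signed-rank
#' distributions are used for n <= 25 without ties; tied samples fall back
#' to the mid-rank normal approximation.
#'
#' @param analysis A `recording_analysis`.
#' @return List with `stats` (per observable: median, q25, q75,
#'   whisker_lo, whisker_hi, n_outliers, p_vs_1, p_vs_1.5, p_vs_2) and
#'   `ranksum` (per neuron x intensity p-values plus the per-intensity
#'   median p).
#' @export
q10_statistics <- function(analysis) {
  stopifnot(inherits(analysis, "recording_analysis"))
  q <- analysis$q10
  if (is.null(q) || length(unique(q$neuron)) < 3)
    stop("need >= 3 neurons with valid fits")
  test_mu <- function(v, mu) {
    d <- v - mu
    if (all(d == 0)) return(1)
    suppressWarnings(wilcox.test(v, mu = mu, exact = length(v) <= 25)$p.value)
  }
  stats <- do.call(rbind, lapply(split(q, q$observable), function(s) {
    v <- s$q10
    q1 <- quantile(v, 0.25, names = FALSE)
    q3 <- quantile(v, 0.75, names = FALSE)
    iqr <- q3 - q1
    lo <- q1 - 1.5 * iqr; hi <- q3 + 1.5 * iqr
    inside <- v >= lo & v <= hi
    data.frame(observable = s$observable[1], n = length(v),
               median = median(v), q25 = q1, q75 = q3,
               whisker_lo = min(v[inside]), whisker_hi = max(v[inside]),
               n_outliers = sum(!inside),
               p_vs_1 = test_mu(v, 1), p_vs_1.5 = test_mu(v, 1.5),
               p_vs_2 = test_mu(v, 2))
  }))
  rownames(stats) <- NULL
  r <- analysis$rates
  temps <- analysis$temperatures
  combos <- unique(r[, c("neuron", "intensity")])
  ranks <- lapply(seq_len(nrow(combos)), function(k) {
    sub <- r[r$neuron == combos$neuron[k] &
               r$intensity == combos$intensity[k], ]
    a <- sub$rate[sub$temperature == temps[1]]
    b <- sub$rate[sub$temperature == temps[2]]
    p <- if (length(a) && length(b) &&
             (length(unique(c(a, b))) > 1))
      suppressWarnings(wilcox.test(a, b)$p.value) else NA_real_
    data.frame(neuron = combos$neuron[k],
               intensity = combos$intensity[k], p = p)
  })
  ranksum <- do.call(rbind, ranks)
  spl <- split(ranksum$p, ranksum$intensity)
  med_p <- data.frame(
    intensity = as.numeric(names(spl)),
    p = vapply(spl, function(v)
      if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE),
      numeric(1)))
  rownames(med_p) <- NULL
  list(stats = stats, ranksum = ranksum, ranksum_by_intensity = med_p)
}

#' AP-width and adaptation metrics from rendered traces
#'
#' For every trace, spikes are extracted ([extract_spikes()]), the width
#' of each action potential is measured at half-maximum amplitude (time
#' between the interpolated half-max crossings around the peak; spikes
#' truncated at the trace edges are excluded), and widths are pooled per
#' temperature. The early/late adaptation ratio compares mean rates in
#' the [10, 40) and [70, 100) ms windows of the stimulus.
#'
#' @param rec A `synthetic_recordings` with rendered traces.
#' @param k Spike-detection threshold factor (see [extract_spikes()]).
#' @return List with `widths` (per spike), `q10_ap_width` (Q10 of the
#'   median width, pooled across neurons and intensities),
#'   `early_late` (per neuron x temperature x intensity ratios) and
#'   `early_late_by_temp` (mean ratio per temperature).
#' @export
waveform_metrics <- function(rec, k = 5) {
  stopifnot(inherits(rec, "synthetic_recordings"))
  if (is.null(rec$traces))
    stop("recording set has no rendered traces")
  spec <- rec$spec
  fs <- spec$trace_fs
  dt_ms <- 1000 / fs
  width_rows <- list()
  for (ni in seq_along(rec$traces)) {
    for (ti in seq_along(rec$traces[[ni]])) {
      temp <- spec$temperatures[ti]
      for (ii in seq_along(rec$traces[[ni]][[ti]])) {
        for (tr in seq_along(rec$traces[[ni]][[ti]][[ii]])) {
          v <- rec$traces[[ni]][[ti]][[ii]][[tr]]
          sp <- tryCatch(extract_spikes(v, k = k),
                         error = function(e) numeric(0))
          if (!length(sp)) next
          t <- (seq_along(v) - 1) * dt_ms
          base <- median(v[t < spec$pre_ms])
          for (s in sp) {
            win <- which(t >= s - 3 & t <= s + 3)
            if (min(win) <= 1 || max(win) >= length(v)) next
            pk <- win[which.max(v[win])]
            half <- base + (v[pk] - base) / 2
            li <- pk
            while (li > 1 && v[li - 1] > half) li <- li - 1
            ri <- pk
            while (ri < length(v) && v[ri + 1] > half) ri <- ri + 1
            if (li == 1 || ri == length(v)) next
            tl <- t[li - 1] + dt_ms * (half - v[li - 1]) /
              (v[li] - v[li - 1])
            tr2 <- t[ri] + dt_ms * (half - v[ri]) / (v[ri + 1] - v[ri])
            width_rows[[length(width_rows) + 1]] <- data.frame(
              neuron = ni, temperature = temp,
              intensity = spec$intensities[ii], trial = tr,
              width_ms = tr2 - tl)
          }
        }
      }
    }
  }
  widths <- if (length(width_rows)) do.call(rbind, width_rows) else NULL
  if (is.null(widths)) stop("no action potentials found in any trace")
  temps <- spec$temperatures
  wc <- widths$width_ms[widths$temperature == temps[1]]
  wh <- widths$width_ms[widths$temperature == temps[2]]
  q10_w <- if (length(wc) && length(wh))
    q10_of(median(wc), median(wh), diff(temps)) else NA_real_
  el <- early_late_ratios(rec)
  list(widths = widths, q10_ap_width = q10_w, early_late = el$per_cell,
       early_late_by_temp = el$by_temp)
}

# early ([10,40) ms) vs late ([70,100) ms) rates from the spike table
early_late_ratios <- function(rec) {
  sp <- rec$spikes
  spec <- rec$spec
  combos <- unique(sp[, c("neuron", "temperature", "intensity")])
  out <- lapply(seq_len(nrow(combos)), function(kk) {
    sub <- sp[sp$neuron == combos$neuron[kk] &
                sp$temperature == combos$temperature[kk] &
                sp$intensity == combos$intensity[kk], ]
    n_tr <- spec$trials
    early <- sum(sub$spike_time_ms >= 10 & sub$spike_time_ms < 40) /
      (n_tr * 0.030)
    late <- sum(sub$spike_time_ms >= 70 & sub$spike_time_ms < 100) /
      (n_tr * 0.030)
    data.frame(combos[kk, ], early = early, late = late,
               ratio = ifelse(late > 0, early / late, NA_real_))
  })
  per_cell <- do.call(rbind, out)
  by_temp <- aggregate(ratio ~ temperature, data = per_cell, FUN = mean,
                       na.action = stats::na.omit)
  list(per_cell = per_cell, by_temp = by_temp)
}
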