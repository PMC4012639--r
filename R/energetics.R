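# Energetics: sodium load per spike, charge-separation efficiency, resting
# potential and resting costs, and their temperature coefficients.
#
# Sign conventions, stated once: the simulator stores signed membrane
# currents I_X = g_X(V) * (V - E_X), so the sodium current is negative
# (inward) during a spike. The "load" integrals use |I_X| because a load is
# a magnitude. The resting costs follow the driving-force convention
# I_Na,rest = g_Na(V_r) * (E_Na - V_r) (positive) and
# I_K,rest = g_K(V_r) * (E_K - V_r) + g_A(V_r) * (E_A - V_r) (negative).
# Q10s of resting costs are computed on magnitudes.

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Sodium load per action potential
#'
#' Integrates the magnitude of the sodium current over the window from
#' stimulus onset to 20 ms after stimulus offset (trapezoidal rule on the
#' trace grid) and divides by the number of spikes in that window.
#'
#' @param trace A `cs_trace` (or data.frame with `time` and `I_Na`).
#' @param spikes Spike times in ms; defaults to the trace's detected
#'   spikes.
#' @param t_start,t_stop Stimulus onset/offset in ms; default from the
#'   trace's protocol.
#' @return Load per spike in uA*ms/mm^2.
#' @export
sodium_load_per_spike <- function(trace, spikes = NULL, t_start = NULL,
                                  t_stop = NULL) {
  pr <- attr(trace, "protocol")
  if (is.null(t_start)) t_start <- pr$t_start
  if (is.null(t_stop)) t_stop <- pr$t_stop
  if (is.null(spikes)) spikes <- attr(trace, "spike_times")
  w <- trace$time >= t_start & trace$time <= t_stop + 20
  ns <- sum(spikes >= t_start & spikes <= t_stop + 20)
  if (ns == 0) stop("no spikes in the integration window")
  trapz(trace$time[w], abs(trace$I_Na[w])) / ns
}

#' Charge-separation efficiency of a spike train
#'
#' The sodium-referenced efficiency is the fraction of the sodium current
#' not simultaneously counterbalanced by the total potassium current
#' `I_K,total = I_K + I_A`:
#' `int max(0, |I_Na| - |I_K,total|) dt / int |I_Na| dt`. The
#' potassium-referenced variant swaps the roles. Both lie in [0, 1].
#'
#' @param trace A `cs_trace` (needs `I_Na`, `I_K`, `I_A`).
#' @param window Length-2 vector (ms); default stimulus onset to offset
#'   + 20 ms.
#' @return List with `na_referenced` and `k_referenced`.
#' @export
charge_separation_efficiency <- function(trace, window = NULL) {
  pr <- attr(trace, "protocol")
  if (is.null(window)) window <- c(pr$t_start, pr$t_stop + 20)
  w <- trace$time >= window[1] & trace$time <= window[2]
  t <- trace$time[w]
  na <- abs(trace$I_Na[w])
  kt <- abs(trace$I_K[w] + trace$I_A[w])
  den_na <- trapz(t, na)
  den_k <- trapz(t, kt)
  if (den_na <= 0) stop("reference integral of |I_Na| is zero")
  if (den_k <= 0) stop("reference integral of |I_K,total| is zero")
  list(na_referenced = trapz(t, pmax(na - kt, 0)) / den_na,
       k_referenced = trapz(t, pmax(kt - na, 0)) / den_k)
}

#' Resting potential of the (scaled) model
#'
#' Solves the zero-current fixed point with all gates at steady state,
#' i.e. the root of
#' `g_L (V-E_L) + g_Na m_inf^3 h_inf (V-E_Na) + g_K n_inf^4 (V-E_K) +
#'  g_A a_inf^3 b_inf (V-E_A) = 0`
#' by bracketed root finding on `[min E_X, max E_X]` (tolerance 1e-9 mV).
#' Because only steady states enter, the result is independent of all
#' gating-rate Q10s; it depends on the conductance Q10s and the Nernst
#' scaling of the reversals only.
#'
#' @param scaled_params A [cs_neuron_params()] whose conductances and
#'   reversals are already at the target temperature (see
#'   [temperature_scale()]).
#' @return Resting potential in mV.
#' @export
resting_potential <- function(scaled_params) {
  p <- scaled_params
  if (p$g_L <= 0 && p$g_Na <= 0 && p$g_K <= 0 && p$g_A <= 0)
    stop("at least one conductance must be > 0")
  net <- function(V) {
    g <- gating_rates(V)
    p$g_L * (V - p$E_L) +
      p$g_Na * g$m_inf^3 * g$h_inf * (V - p$E_Na) +
      p$g_K * g$n_inf^4 * (V - p$E_K) +
      p$g_A * g$a_inf^3 * g$b_inf * (V - p$E_A)
  }
  lo <- min(p$E_L, p$E_Na, p$E_K, p$E_A)
  hi <- max(p$E_L, p$E_Na, p$E_K, p$E_A)
  # the fixed point can be non-unique (N-shaped steady-state I-V); the
  # resting potential is the most hyperpolarized root, so bracket the
  # first sign change from below (net() is vectorized)
  vv <- seq(lo, hi, by = 0.25)
  fv <- net(vv)
  if (fv[1] == 0) return(lo)
  ch <- which(sign(fv[-1]) != sign(fv[-length(fv)]))
  if (!length(ch))
    stop("no sign change of the net current in [min E, max E]")
  i <- ch[1]
  uniroot(net, c(vv[i], vv[i + 1]), tol = 1e-9)$root
}

#' Resting ionic currents (resting costs)
#'
#' Evaluates the sodium- and potassium-based resting costs at the resting
#' potential: `I_Na,rest = g_Na(V_r) (E_Na - V_r)` and
#' `I_K,rest = g_K(V_r) (E_K - V_r) + g_A(V_r) (E_A - V_r)`, with gates at
#' steady state.
#'
#' @param scaled_params Scaled parameters (see [resting_potential()]).
#' @param v_r Resting potential; computed if missing.
#' @return List with `v_r`, `i_na_rest`, `i_k_rest` and `i_leak` (the leak
#'   current `g_L (E_L - V_r)`, so that the three sum to zero at the fixed
#'   point).
#' @export
resting_costs <- function(scaled_params, v_r = NULL) {
  p <- scaled_params
  if (is.null(v_r)) v_r <- resting_potential(p)
  g <- gating_rates(v_r)
  g_na <- p$g_Na * g$m_inf^3 * g$h_inf
  g_k <- p$g_K * g$n_inf^4
  g_a <- p$g_A * g$a_inf^3 * g$b_inf
  list(v_r = v_r,
       i_na_rest = g_na * (p$E_Na - v_r),
       i_k_rest = g_k * (p$E_K - v_r) + g_a * (p$E_A - v_r),
       i_leak = p$g_L * (p$E_L - v_r))
}

#' Temperature coefficient of the spiking cost
#'
#' Per-amplitude Q10s of the sodium load per spike, restricted to
#' amplitudes that elicit spikes at both temperatures, averaged
#' arithmetically (`method = "per_amplitude"`, the default). The
#' alternative `"ratio_of_means"` computes one Q10 from the mean loads.
#'
#' @param loads_cold,loads_hot Per-amplitude load-per-spike vectors (NA
#'   where no spikes).
#' @param dT Temperature difference in degrees C (default 10).
#' @param method See above.
#' @return The Q10 of the spiking cost, or `NA` (with a warning) when no
#'   amplitude spikes at both temperatures.
#' @export
spiking_cost_q10 <- function(loads_cold, loads_hot, dT = 10,
                             method = c("per_amplitude",
                                        "ratio_of_means")) {
  method <- match.arg(method)
  ok <- is.finite(loads_cold) & is.finite(loads_hot) &
    loads_cold > 0 & loads_hot > 0
  if (!any(ok)) {
    warning("no amplitude spikes at both temperatures")
    return(NA_real_)
  }
  if (method == "per_amplitude") {
    mean(q10_of(loads_cold[ok], loads_hot[ok], dT))
  } else {
    q10_of(mean(loads_cold[ok]), mean(loads_hot[ok]), dT)
  }
}

#' Fraction of models whose Na-based resting cost drops with heating
#'
#' The resting potential and resting costs depend only on the four
#' conductance Q10s (gates enter at steady state), so the full-grid
#' fraction reduces to the conductance subgrid: `steps^4` combinations.
#' For each combination the resting potential is solved at both
#' temperatures and the Q10 of |I_Na,rest| is computed.
#'
#' @param params Reference [cs_neuron_params()].
#' @param steps Grid steps per conductance Q10 (default 4, values evenly
#'   spaced in `range`).
#' @param range Conductance Q10 range (default `c(1.2, 2)`).
#' @param T_cold,T_hot Temperatures in degrees C.
#' @return List: `fraction` (of combinations with Q10(|I_Na,rest|) < 1),
#'   `percent`, `n`, and the per-combination data.frame `detail`.
#' @export
resting_cost_q10_fraction <- function(params = cs_neuron_params(),
                                      steps = 4, range = c(1.2, 2),
                                      T_cold = 18, T_hot = 28) {
  vals <- seq(range[1], range[2], length.out = steps)
  combos <- expand.grid(g_L = vals, g_Na = vals, g_K = vals, g_A = vals,
                        KEEP.OUT.ATTRS = FALSE)
  dT <- T_hot - T_cold
  q10 <- numeric(nrow(combos))
  q10_k <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    q <- q10_set(g_L = combos$g_L[i], g_Na = combos$g_Na[i],
                 g_K = combos$g_K[i], g_A = combos$g_A[i],
                 check = "none")
    cold <- resting_costs(temperature_scale(params, q, T_cold - params$T0)$params)
    hot <- resting_costs(temperature_scale(params, q, T_hot - params$T0)$params)
    q10[i] <- q10_of(abs(cold$i_na_rest), abs(hot$i_na_rest), dT)
    q10_k[i] <- q10_of(abs(cold$i_k_rest), abs(hot$i_k_rest), dT)
  }
  detail <- cbind(combos, q10_na_rest = q10, q10_k_rest = q10_k)
  list(fraction = mean(q10 < 1), percent = 100 * mean(q10 < 1),
       n = nrow(combos), detail = detail)
}
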