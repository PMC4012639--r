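# Model core: gating kinetics, temperature scaling, simulation, spike
# detection, f-I curves, square-root fits.

test_that("gating rates match their printed expressions and limits", {
  g <- gating_rates(-29.7)
  expect_equal(g$alpha_m, 3.8, tolerance = 1e-9)   # L'Hopital limit
  # cross-check the limit by approaching the singularity
  gl <- gating_rates(-29.7 + 1e-6)
  gr <- gating_rates(-29.7 - 1e-6)
  expect_equal(g$alpha_m, (gl$alpha_m + gr$alpha_m) / 2, tolerance = 1e-7)

  expect_equal(gating_rates(-45.7)$alpha_n, 0.2, tolerance = 1e-9)
  expect_equal(gating_rates(-53.3)$b_inf, 0.0625, tolerance = 1e-12)

  # spot values away from singularities against direct evaluation
  V <- -50
  expect_equal(gating_rates(V)$alpha_m,
               0.38 * (V + 29.7) / (1 - exp(-0.1 * (V + 29.7))))
  expect_equal(gating_rates(V)$beta_h, 3.8 / (1 + exp(-0.1 * (V + 18))))

  # derived quantities are consistent
  g <- gating_rates(-40)
  expect_equal(g$m_inf, g$alpha_m / (g$alpha_m + g$beta_m))
  expect_equal(g$tau_n, 1 / (g$alpha_n + g$beta_n))
  expect_error(gating_rates(Inf), "finite")
})

test_that("C++ gating evaluation agrees with the R reference", {
  V <- seq(-120, 60, by = 0.37)
  cpp <- thermospike:::cs_gating_cpp(V)
  r <- gating_rates(V)
  expect_equal(cpp$m_inf, r$m_inf, tolerance = 1e-12)
  expect_equal(cpp$tau_h, r$tau_h, tolerance = 1e-12)
  expect_equal(cpp$a_inf, r$a_inf, tolerance = 1e-12)
  expect_equal(cpp$tau_b, r$tau_b, tolerance = 1e-12)
})

test_that("temperature scaling follows the Q10 and Nernst rules", {
  p <- cs_neuron_params()
  q <- q10_set(g_K = 1.2, n = 4)

  sc0 <- temperature_scale(p, q, 0)
  expect_equal(unclass(sc0$params)[1:9], unclass(p)[1:9])
  expect_equal(unname(sc0$rate_factors), rep(1, 5))

  sc10 <- temperature_scale(p, q, 10)
  expect_equal(sc10$params$E_Na, 55 * (1 + 10 / 291.15))
  expect_equal(sc10$params$g_K, 0.2 * 1.2)

  sc5 <- temperature_scale(p, q10_set(n = 4), 5)
  expect_equal(unname(sc5$rate_factors["n"]), 2)  # 4^(5/10)

  # steady-state invariance and tau scaling: x_inf unchanged, tau / factor
  V <- c(-70, -45, -20)
  g <- gating_rates(V)
  f <- sc10$rate_factors["n"]
  expect_equal(g$alpha_n * f / (g$alpha_n * f + g$beta_n * f), g$n_inf)
  expect_equal(g$tau_n / f, 1 / (g$alpha_n * f + g$beta_n * f))
})

test_that("q10_set enforces the physiological ranges", {
  expect_error(q10_set(g_L = 1.1), "1.2")
  expect_error(q10_set(m = 4.5), "2.0")
  expect_silent(q10_set(g_L = 1.1, check = "positive"))
  expect_error(q10_set(m = -1, check = "positive"), "> 0")
})

test_that("zero-current simulation stays at rest; blow-up raises", {
  tr <- simulate_voltage(cs_neuron_params(), amplitude = 0, dT = 0)
  expect_lt(diff(range(tr$V)), 1e-6)
  expect_length(attr(tr, "spike_times"), 0)
})

test_that("detect_spikes uses strict interpolated crossings with lockout", {
  # monotone subthreshold decay
  expect_length(detect_spikes(data.frame(time = 0:10,
                                         V = seq(-40, -80, length.out = 11))),
                0)
  # triangle wave crossing -30 upward three times, analytic crossings
  t <- seq(0, 30, by = 0.1)
  v <- -50 + 30 * abs(((t / 10) %% 2) - 1)  # peaks -20 at t=0,20; troughs -50
  # upward crossings where v rises through -30: v = -50+30*s, s=2/3
  sp <- detect_spikes(data.frame(time = t, V = v))
  expect_equal(sp, c(10 + 20 / 3), tolerance = 1e-9)  # one rise in [10,20]
  t2 <- seq(0, 70, by = 0.05)
  v2 <- -50 + 30 * abs(((t2 / 10) %% 2) - 1)
  expect_equal(detect_spikes(data.frame(time = t2, V = v2)),
               c(10, 30, 50) + 20 / 3, tolerance = 1e-9)

  # touching the threshold exactly without exceeding: not a spike
  v3 <- c(-50, -30, -50, -30, -50)
  expect_length(detect_spikes(data.frame(time = 0:4, V = v3)), 0)

  # lockout suppresses double counts
  t4 <- c(0, 0.1, 0.2, 0.3, 0.4, 0.5)
  v4 <- c(-50, -20, -50, -20, -50, -20)
  expect_length(detect_spikes(data.frame(time = t4, V = v4), lockout = 1), 1)
})

test_that("fit_sqrt recovers exact square-root curves", {
  I <- seq(0.05, 0.6, by = 0.05)
  rate <- ifelse(I > 0.1, 2 * sqrt(pmax(I - 0.1, 0)), 0)
  f <- fit_sqrt(I, rate)
  expect_equal(f$A, 2, tolerance = 1e-4)
  expect_equal(f$I0, 0.1, tolerance = 1e-4)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)

  # higher-rate realistic magnitudes, 4 significant digits
  rate <- ifelse(I > 0.085, 412.3 * sqrt(pmax(I - 0.085, 0)), 0)
  f <- fit_sqrt(I, rate)
  expect_equal(f$A, 412.3, tolerance = 1e-4)
  expect_equal(f$I0, 0.085, tolerance = 1e-3)

  expect_error(fit_sqrt(c(0.1, 0.2, 0.3), c(0, 0, 10)),
               "insufficient suprathreshold")
})

test_that("reference f-I curve is type I with a good square-root fit", {
  fi <- reference_cold_fi()
  expect_true(all(diff(fi$rate) >= 0))
  f <- attr(fi, "fit", exact = TRUE)
  expect_gt(f$r_squared, 0.97)
  expect_gt(f$A, 0)
  expect_lt(f$I0, min(fi$I[fi$rate > 0]))

  # type I onset: small rate at the first suprathreshold amplitude and
  # decreasing toward rheobase as the grid is refined
  i_first <- min(fi$I[fi$rate > 0])
  expect_lt(fi$rate[fi$I == i_first], 50)
  fine <- compute_fi_curve(
    cs_neuron_params(), q10_set(), 18,
    stimulus_protocol(amplitudes = f$I0 + c(0.002, 0.005, 0.01, 0.02)))
  expect_true(all(diff(fine$rate) >= 0))
  expect_lt(fine$rate[1], fi$rate[fi$I == i_first])
})

test_that("all-subthreshold protocols give a zero curve, fit undefined", {
  fi <- compute_fi_curve(cs_neuron_params(), q10_set(), 18,
                         stimulus_protocol(amplitudes = c(0.01, 0.02)))
  expect_true(all(fi$rate == 0))
  expect_null(attr(fi, "fit", exact = TRUE))
  expect_match(attr(fi, "fit_note"), "undefined")
})

test_that("heating increases the slope of the f-I curve", {
  fi_c <- reference_cold_fi()
  fi_h <- compute_fi_curve(cs_neuron_params(), q10_set(), 28)
  q10_A <- q10_of(attr(fi_c, "fit", exact = TRUE)$A, attr(fi_h, "fit", exact = TRUE)$A, 10)
  expect_gt(q10_A, 1)
})

test_that("dt = 0 identity: scaled dT=0 simulation is bit-identical", {
  p <- cs_neuron_params()
  q <- q10_set(g_A = 1.7, n = 3.3, check = "none")
  tr1 <- simulate_voltage(p, q, dT = 0, amplitude = 0.3)
  tr2 <- simulate_voltage(p, q10_set(), dT = 0, amplitude = 0.3)
  expect_identical(tr1$V, tr2$V)
  expect_identical(attr(tr1, "spike_times"), attr(tr2, "spike_times"))
})

test_that("table-based and exact gating integration agree", {
  p <- cs_neuron_params()
  tr1 <- simulate_voltage(p, amplitude = 0.3, dT = 0, use_table = TRUE)
  tr2 <- simulate_voltage(p, amplitude = 0.3, dT = 0, use_table = FALSE)
  expect_equal(length(attr(tr1, "spike_times")),
               length(attr(tr2, "spike_times")))
  expect_lt(max(abs(tr1$V - tr2$V)), 0.05)
})

test_that("fixed-step RK4 agrees with the adaptive solver oracle", {
  p <- cs_neuron_params()
  for (amp in c(0.2, 0.6)) {
    tr <- simulate_voltage(p, amplitude = amp, dT = 0)
    tro <- simulate_voltage(p, amplitude = amp, dT = 0,
                            method = "adaptive")
    expect_lte(abs(length(attr(tr, "spike_times")) -
                     length(attr(tro, "spike_times"))), 1)
  }
})

test_that("rheobase bracketing: just-subthreshold amplitude is silent", {
  p <- cs_neuron_params()
  count_at <- function(amp) {
    fi <- compute_fi_curve(p, q10_set(), 18,
                           stimulus_protocol(amplitudes = c(amp, 0.6)))
    fi$rate[1]
  }
  lo <- 0.01; hi <- 0.2
  for (k in 1:12) {
    mid <- (lo + hi) / 2
    if (count_at(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal(count_at(lo), 0)
  expect_gt(count_at(hi), 0)
  expect_lt(hi - lo, 1e-4)
})

test_that("membrane-equation residual is below solver tolerance", {
  tr <- simulate_voltage(cs_neuron_params(), amplitude = 0.4, dT = 0)
  # numeric dV/dt vs (I_C - sum I)/C_m on interior samples
  dt <- attr(tr, "dt")
  n <- nrow(tr)
  dv <- (tr$V[3:n] - tr$V[1:(n - 2)]) / (2 * dt)
  rhs <- (tr$I_C - tr$I_Na - tr$I_K - tr$I_A - tr$I_L) /
    (cs_neuron_params()$C_m / 1000)
  mid <- 2:(n - 1)
  # exclude the stimulus on/offset discontinuities and spike upstrokes
  ok <- abs(rhs[mid]) < 50 & tr$time[mid] > 51 & tr$time[mid] < 149
  expect_lt(median(abs(dv[ok] - rhs[mid][ok])), 0.5)
})
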