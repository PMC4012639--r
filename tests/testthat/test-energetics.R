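# Energy observables: loads, charge-separation efficiency, resting
# potential and costs.

# helper: build a fake trace with prescribed current waveforms
fake_trace <- function(time, i_na, i_k = 0, i_a = 0, protocol = NULL) {
  tr <- data.frame(time = time, V = -60, I_Na = i_na, I_K = i_k,
                   I_A = i_a, I_L = 0, I_C = 0)
  if (is.null(protocol))
    protocol <- stimulus_protocol(t_pre = 10, t_stim = 50, t_post = 40)
  structure(tr, protocol = protocol, spike_times = numeric(0))
}

test_that("sodium load per spike equals analytic pulse area / count", {
  t <- seq(0, 100, by = 0.01)
  # rectangular |I_Na| pulse of height 2 on [20, 30]: area 20
  ina <- ifelse(t >= 20 & t <= 30, -2, 0)
  tr <- fake_trace(t, ina)
  expect_equal(sodium_load_per_spike(tr, spikes = c(22, 28)), 10,
               tolerance = 1e-3)
  expect_error(sodium_load_per_spike(tr, spikes = numeric(0)), "no spikes")
  # spikes outside the window do not count
  expect_error(sodium_load_per_spike(tr, spikes = c(5, 95)), "no spikes")
})

test_that("sodium load of the reference model matches the adaptive oracle", {
  p <- cs_neuron_params()
  tr <- simulate_voltage(p, amplitude = 0.3, dT = 0)
  spikes <- attr(tr, "spike_times")
  load <- sodium_load_per_spike(tr)
  # cross-solver oracle: the adaptive integrator accumulates the same
  # |I_Na| integral along its own trajectory
  tro <- simulate_voltage(p, amplitude = 0.3, dT = 0, method = "adaptive")
  ns <- sum(spikes >= 50 & spikes <= 170)
  load_o <- attr(tro, "na_load") / ns
  expect_equal(load, load_o, tolerance = 0.01)
  expect_gt(load, 0)
})

test_that("charge-separation efficiency handles analytic overlap cases", {
  t <- seq(0, 100, by = 0.01)
  pr <- stimulus_protocol(t_pre = 10, t_stim = 50, t_post = 40)
  # disjoint pulses -> efficiency 1
  tr <- fake_trace(t, ifelse(t >= 20 & t < 30, -1, 0),
                   i_k = ifelse(t >= 40 & t < 50, 1, 0), protocol = pr)
  eff <- charge_separation_efficiency(tr)
  expect_equal(eff$na_referenced, 1, tolerance = 1e-3)
  expect_equal(eff$k_referenced, 1, tolerance = 1e-3)
  # perfectly counterbalanced -> 0
  tr <- fake_trace(t, ifelse(t >= 20 & t < 30, -1, 0),
                   i_k = ifelse(t >= 20 & t < 30, 1, 0), protocol = pr)
  eff <- charge_separation_efficiency(tr)
  expect_equal(eff$na_referenced, 0, tolerance = 1e-6)
  # half-overlapping equal rectangles -> 0.5
  tr <- fake_trace(t, ifelse(t >= 20 & t < 30, -1, 0),
                   i_k = ifelse(t >= 25 & t < 35, 1, 0), protocol = pr)
  eff <- charge_separation_efficiency(tr)
  expect_equal(eff$na_referenced, 0.5, tolerance = 1e-3)
  expect_equal(eff$k_referenced, 0.5, tolerance = 1e-3)
  # I_K,total combines both potassium currents
  tr <- fake_trace(t, ifelse(t >= 20 & t < 30, -1, 0),
                   i_k = ifelse(t >= 20 & t < 30, 0.5, 0),
                   i_a = ifelse(t >= 20 & t < 30, 0.5, 0), protocol = pr)
  expect_equal(charge_separation_efficiency(tr)$na_referenced, 0,
               tolerance = 1e-6)
  # zero reference integral raises
  tr <- fake_trace(t, 0, i_k = ifelse(t >= 20 & t < 30, 1, 0),
                   protocol = pr)
  expect_error(charge_separation_efficiency(tr), "I_Na")
})

test_that("efficiencies on a real spiking trace lie in [0, 1]", {
  tr <- simulate_voltage(cs_neuron_params(), amplitude = 0.4, dT = 0)
  eff <- charge_separation_efficiency(tr)
  expect_gte(eff$na_referenced, 0); expect_lte(eff$na_referenced, 1)
  expect_gte(eff$k_referenced, 0); expect_lte(eff$k_referenced, 1)
})

test_that("resting potential solves the fixed point", {
  p <- cs_neuron_params()
  # all voltage-gated conductances zero -> V_r = E_L
  p0 <- cs_neuron_params(g_Na = 0, g_K = 0, g_A = 0)
  expect_equal(resting_potential(p0), -17, tolerance = 1e-6)
  # reference model: agrees with a long unstimulated simulation
  vr <- resting_potential(p)
  pr <- stimulus_protocol(t_pre = 100, t_stim = 300, t_post = 100)
  tr <- simulate_voltage(p, amplitude = 0, dT = 0, protocol = pr)
  expect_equal(vr, tr$V[nrow(tr)], tolerance = 0.1)
  # independent of gating-rate Q10s
  q1 <- q10_set(m = 2, h = 4, n = 2.7, a = 3.1, b = 3.9)
  q2 <- q10_set(m = 4, h = 2, n = 3.9, a = 2.2, b = 2.1)
  v1 <- resting_potential(temperature_scale(p, q1, 10)$params)
  v2 <- resting_potential(temperature_scale(p, q2, 10)$params)
  expect_identical(v1, v2)
  # more delayed-rectifier conductance hyperpolarizes
  vs <- sapply(c(0.5, 1, 2, 4), function(s) {
    pp <- p; pp$g_K <- p$g_K * s
    resting_potential(pp)
  })
  expect_true(all(diff(vs) < 0))
  expect_error(resting_potential(cs_neuron_params(g_L = 0, g_Na = 0,
                                                  g_K = 0, g_A = 0)),
               "conductance")
})

test_that("resting costs satisfy Kirchhoff and printed sign conventions", {
  p <- cs_neuron_params()
  rc <- resting_costs(p)
  expect_lt(abs(rc$i_na_rest + rc$i_k_rest + rc$i_leak), 1e-6)
  expect_gt(rc$i_na_rest, 0)  # E_Na above rest: inward driving force
  expect_lt(rc$i_k_rest, 0)
  expect_equal(resting_costs(cs_neuron_params(g_Na = 0))$i_na_rest, 0)
})

test_that("spiking-cost Q10 follows the per-amplitude averaging rule", {
  expect_equal(spiking_cost_q10(c(3, 5), c(3, 5)), 1)
  expect_equal(spiking_cost_q10(c(3, 5), c(1.5, 2.5)), 0.5)
  expect_equal(spiking_cost_q10(c(2, 4), c(1, 3)), mean(c(0.5, 0.75)))
  expect_equal(spiking_cost_q10(c(2, 4), c(1, 3),
                                method = "ratio_of_means"), 4 / 6)
  # only amplitudes spiking at both temperatures enter
  expect_equal(spiking_cost_q10(c(NA, 4), c(1, 2)), 0.5)
  expect_warning(out <- spiking_cost_q10(c(NA, NA), c(1, 2)), "no amplitude")
  expect_true(is.na(out))
  # dT rescaling follows the Q10 exponent
  expect_equal(spiking_cost_q10(2, 1, dT = 5), 0.25)
})

test_that("conductance-only subgrid determines the resting-cost fraction", {
  fr <- resting_cost_q10_fraction(steps = 2)
  expect_equal(fr$n, 16)
  # rate Q10s are irrelevant by construction: verified via the identity of
  # resting_potential under different rate Q10s above; here check the
  # detail table is deterministic and in range
  expect_true(all(fr$detail$q10_na_rest > 0))
  fr2 <- resting_cost_q10_fraction(steps = 2)
  expect_identical(fr$detail, fr2$detail)
})
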