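# Synthetic recording generator: determinism, rate structure, ground
# truth, adaptation profile, trace rendering.

test_that("generator is deterministic under seed and distinct across seeds", {
  s1 <- generator_spec(seed = 3)
  a <- generate_recordings(s1)
  b <- generate_recordings(s1)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$ground_truth, b$ground_truth)
  c2 <- generate_recordings(generator_spec(seed = 4))
  expect_false(identical(a$spikes, c2$spikes))
})

test_that("noise-free trials reproduce the sigmoid rates exactly", {
  spec <- generator_spec(noise = "none", seed = 1)
  rec <- generate_recordings(spec)
  gt <- rec$ground_truth
  dur_s <- spec$stim_ms / 1000
  for (ni in c(1, 5, 9)) {
    sat <- gt$cold[gt$neuron == ni & gt$parameter == "sat"]
    i50 <- gt$cold[gt$neuron == ni & gt$parameter == "i50"]
    w <- gt$cold[gt$neuron == ni & gt$parameter == "width"]
    expect_rate <- round(sigmoid_eval(sigmoid_response(sat, i50, w),
                                      spec$intensities) * dur_s) / dur_s
    got <- rec$rates[rec$rates$neuron == ni &
                       rec$rates$temperature == spec$temperatures[1] &
                       rec$rates$trial == 1, ]
    got <- got[order(got$intensity), ]
    expect_equal(got$rate, expect_rate)
  }
})

test_that("Poisson trial means converge to the programmed rate", {
  spec <- generator_spec(n_neurons = 1, trials = 10000,
                         intensities = c(60, 61), seed = 9,
                         cold_params = data.frame(sat = 300, i50 = 55,
                                                  width = 4))
  rec <- generate_recordings(spec)
  r <- rec$rates[rec$rates$intensity == 60 &
                   rec$rates$temperature == spec$temperatures[1], "rate"]
  lambda <- sigmoid_eval(sigmoid_response(300, 55, 4), 60) * 0.1
  se <- sqrt(lambda / length(r)) / 0.1
  expect_lt(abs(mean(r) - lambda / 0.1), 3 * se)
})

test_that("ground truth is internally consistent", {
  spec <- generator_spec(seed = 2)
  gt <- ground_truth_table(spec)
  dT <- diff(spec$temperatures)
  expect_equal(gt$q10, q10_of(gt$cold, gt$hot, dT))
  # default fixture shape: 9 neurons, 8 intensities, 5 trials, 2 temps
  expect_equal(spec$n_neurons, 9)
  expect_length(spec$intensities, 8)
  expect_equal(range(spec$intensities), c(32, 88))
  expect_equal(spec$trials, 5)
  rec <- generate_recordings(spec)
  expect_equal(nrow(rec$rates), 9 * 2 * 8 * 5)
  # all Q10 = 1 when parameters are temperature invariant
  flat <- generator_spec(param_q10 = c(sat = 1, i50 = 1, width = 1))
  expect_true(all(ground_truth_table(flat)$q10 == 1))
})

test_that("rate-level curves are nondecreasing in expectation", {
  spec <- generator_spec(noise = "none", seed = 6)
  rec <- generate_recordings(spec)
  mr <- aggregate(rate ~ neuron + temperature + intensity,
                  data = rec$rates, FUN = mean)
  for (ni in 1:3) {
    sub <- mr[mr$neuron == ni & mr$temperature == spec$temperatures[1], ]
    expect_true(all(diff(sub$rate[order(sub$intensity)]) >= -1e-9))
  }
})

test_that("adaptation profile controls the early/late ratio", {
  spec <- generator_spec(n_neurons = 1, trials = 300,
                         intensities = c(70, 80), noise = "none",
                         adapt_early = 2, adapt_late = 1, seed = 5,
                         cold_params = data.frame(sat = 300, i50 = 55,
                                                  width = 4))
  rec <- generate_recordings(spec)
  sp <- rec$spikes
  early <- sum(sp$spike_time_ms >= 10 & sp$spike_time_ms < 40)
  late <- sum(sp$spike_time_ms >= 70 & sp$spike_time_ms < 100)
  expect_equal(early / late, 2, tolerance = 0.1)
})

test_that("rendered APs have the configured width at half maximum", {
  spec <- generator_spec(n_neurons = 1, trials = 2, intensities = c(70, 80),
                         render_traces = TRUE, trace_noise_sd = 0,
                         ap_width_cold = 1.0, ap_width_q10 = 0.66,
                         noise = "none", seed = 7,
                         cold_params = data.frame(sat = 120, i50 = 50,
                                                  width = 4))
  rec <- generate_recordings(spec)
  tr <- rec$traces[[1]][[1]][[1]][[1]]
  dt_ms <- 1000 / spec$trace_fs
  sp <- extract_spikes(tr)
  expect_gt(length(sp), 0)
  # measure the first AP width at half max
  # with zero trace noise the detection threshold sits at the bump foot,
  # so the peak lies up to ~2.5 ms after the crossing
  t <- (seq_along(tr) - 1) * dt_ms
  pk <- which(t >= sp[1] & t <= sp[1] + 4)
  pk <- pk[which.max(tr[pk])]
  half <- -60 + (tr[pk] - (-60)) / 2
  above <- which(tr > half)
  seg <- above[above >= pk - 50 & above <= pk + 50]
  width <- (max(seg) - min(seg)) * dt_ms
  expect_equal(width, 1.0, tolerance = 2 * dt_ms / 1.0)
  # hot trace is narrower by the configured factor
  trh <- rec$traces[[1]][[2]][[1]][[1]]
  expect_equal(attr(trh, "ap_fwhm"),
               1.0 * 0.66^(diff(spec$temperatures) / 10))
})

test_that("recording sets round-trip through the directory layout", {
  spec <- generator_spec(n_neurons = 3, seed = 8)
  rec <- generate_recordings(spec)
  d <- withr::local_tempdir()
  write_recordings(rec, d)
  expect_true(file.exists(file.path(d, "neuron_01", "spikes.tsv")))
  expect_true(file.exists(file.path(d, "spec.json")))
  back <- read_recordings(d)
  expect_equal(nrow(back), nrow(rec$spikes))
  expect_equal(back$spike_time_ms, rec$spikes$spike_time_ms,
               tolerance = 1e-9)
})
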