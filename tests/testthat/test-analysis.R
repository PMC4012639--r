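# Analysis of recordings: spike extraction, sigmoid fits, Q10 statistics,
# waveform metrics.

test_that("extract_spikes is quiet on flat traces and finds rendered APs", {
  fs <- 20000
  flat <- structure(rnorm(4000, -60, 0.3), fs = fs, pre_ms = 50)
  expect_length(extract_spikes(flat), 0)
  expect_error(extract_spikes(rnorm(100), fs = fs, pre_ms = NULL),
               "pre-stimulus")

  # hand-placed, well-separated action potentials
  spec <- generator_spec(n_neurons = 1, render_traces = TRUE,
                         trace_noise_sd = 0.5, seed = 12)
  set.seed(12)
  truth <- c(10, 25, 40, 60, 85)
  tr <- thermospike:::render_trace(spec, spec$temperatures[1], truth)
  got <- extract_spikes(tr)
  expect_length(got, length(truth))
  # detections sit on the rising flank just before each bump peak
  expect_equal(sort(got), truth + spec$pre_ms, tolerance = 0.03)

  # robustness: detection count invariant to noise at 10% of AP amplitude
  noisy <- structure(as.numeric(tr) + rnorm(length(tr), 0, 6),
                     fs = attr(tr, "fs"), pre_ms = attr(tr, "pre_ms"))
  expect_length(extract_spikes(noisy), length(truth))
})

test_that("fit_response_curve recovers noiseless sigmoids exactly", {
  x <- seq(32, 88, length.out = 8)
  truth <- sigmoid_response(300, 55, 4)
  ft <- fit_response_curve(x, sigmoid_eval(truth, x))
  expect_false(ft$flagged)
  expect_equal(ft$resp$sat, 300, tolerance = 1e-3)
  expect_equal(ft$resp$i50, 55, tolerance = 1e-3)
  expect_equal(ft$resp$width, 4, tolerance = 1e-3)
  expect_equal(ft$r_squared, 1, tolerance = 1e-9)

  expect_error(fit_response_curve(c(40, 50, 60), c(1, 2, 3)), ">= 4")
  flat <- fit_response_curve(x, rep(100, 8))
  expect_true(flat$flagged)
})

test_that("analysis pipeline recovers generator Q10s on the default fixture", {
  spec <- generator_spec(seed = 31)
  rec <- generate_recordings(spec)
  an <- analyze_recordings(rec)
  # every response curve well fit (the experimental benchmark)
  expect_true(all(an$fits$r_squared > 0.95))
  q <- an$q10
  med_sat <- median(q$q10[q$observable == "sat"])
  expect_gt(med_sat, 1.25)
  expect_lt(med_sat, 1.55)
  med_w <- median(q$q10[q$observable == "width"])
  expect_lt(med_w, 1)
  # pipeline determinism
  an2 <- analyze_recordings(generate_recordings(spec))
  expect_identical(an$q10, an2$q10)
})

test_that("q10_statistics handles identity and exact-doubling datasets", {
  spec <- generator_spec(seed = 13, noise = "none",
                         param_q10 = c(sat = 1, i50 = 1, width = 1))
  rec <- generate_recordings(spec)
  an <- analyze_recordings(rec)
  expect_true(all(abs(an$q10$q10 - 1) < 0.05))
  st <- q10_statistics(an)
  expect_true(all(st$stats$n_outliers >= 0))

  # doubling all hot rates: every rate-scale Q10 is exactly 2 (dT = 10)
  spec2 <- generator_spec(seed = 14, noise = "none",
                          temperatures = c(20, 30),
                          param_q10 = c(sat = 2, i50 = 1, width = 1))
  an2 <- analyze_recordings(generate_recordings(spec2))
  sat2 <- an2$q10$q10[an2$q10$observable == "sat"]
  expect_equal(sat2, rep(2, length(sat2)), tolerance = 0.02)
  st2 <- q10_statistics(an2)
  p2 <- st2$stats$p_vs_2[st2$stats$observable == "sat"]
  expect_gt(p2, 0.5)  # median not distinguishable from 2
  p1 <- st2$stats$p_vs_1[st2$stats$observable == "sat"]
  expect_lt(p1, 0.05)  # clearly different from 1
})

test_that("rank-sum p-values are small where rates differ strongly", {
  spec <- generator_spec(seed = 15, sigma = 10, noise = "gaussian",
                         param_q10 = c(sat = 1.8, i50 = 1, width = 1))
  an <- analyze_recordings(generate_recordings(spec))
  st <- q10_statistics(an)
  byi <- st$ranksum_by_intensity
  hi <- byi$p[which.max(byi$intensity)]
  expect_lte(hi, median(byi$p, na.rm = TRUE))
})

test_that("waveform metrics reproduce the constructed width Q10", {
  spec <- generator_spec(n_neurons = 2, trials = 2,
                         intensities = c(60, 70, 80, 88),
                         temperatures = c(20, 30),
                         render_traces = TRUE, trace_noise_sd = 0.2,
                         ap_width_cold = 1.0, ap_width_q10 = 0.66,
                         noise = "none", seed = 16,
                         cold_params = data.frame(sat = c(100, 120),
                                                  i50 = c(55, 50),
                                                  width = c(4, 5)))
  rec <- generate_recordings(spec)
  wm <- waveform_metrics(rec)
  # dT = 10, widths 1.0 -> 0.66 ms: Q10(AP width) = 0.66
  expect_equal(wm$q10_ap_width, 0.66, tolerance = 0.05)
  expect_true(all(wm$widths$width_ms > 0))

  # equal early/late plateaus -> ratio 1 at both temperatures
  el <- wm$early_late_by_temp
  expect_equal(el$ratio, rep(1, 2), tolerance = 0.25)
})
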