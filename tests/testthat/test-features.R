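test_that("frequency is count over analyzed time", {
  expect_equal(compute_frequency(500, 10), 50)
  expect_equal(compute_frequency(0, 10), 0)
  expect_equal(compute_frequency(10001, 100), 100.01)
  expect_error(compute_frequency(10, 0), class = "purkinjetrain_validation_error")
})

test_that("frequency mode uses left-closed 2.5 Hz bins with low tie-break", {
  # all ISIs 0.01 s -> 100 Hz -> bin [100, 102.5) -> center 101.25
  expect_equal(compute_frequency_mode(rep(0.01, 50)), 101.25)
  # majority bin wins: 200 Hz has one more member than 50 Hz
  expect_equal(compute_frequency_mode(c(rep(0.02, 10), rep(0.005, 11))), 201.25)
  # exact tie between [50, 52.5) and [200, 202.5): lowest bin wins
  expect_equal(compute_frequency_mode(c(rep(0.02, 10), rep(0.005, 10))), 51.25)
  expect_error(compute_frequency_mode(numeric(0)),
               class = "purkinjetrain_insufficient_data")
})

test_that("CV and CV2 match closed forms for degenerate and renewal trains", {
  expect_equal(compute_cv(rep(0.02, 100)), 0)
  expect_equal(compute_cv2(rep(0.02, 100)), 0)
  # alternating ISIs 0.01/0.03: every adjacent pair gives 2*0.02/0.04 = 1
  expect_equal(compute_cv2(rep(c(0.01, 0.03), 50)), 1.0)
  # population-SD convention (explicit oracle, not stats::sd)
  v <- c(0.01, 0.02, 0.04)
  expect_equal(compute_cv(v), sqrt(sum((v - mean(v))^2) / 3) / mean(v))
  # analytic oracles: CV(gamma k) = 1/sqrt(k); CV(exp) = CV2(exp) = 1
  set.seed(7)
  isis <- rgamma(1e5, shape = 4, rate = 4 * 60)
  expect_equal(compute_cv(isis), 0.5, tolerance = 0.02)
  isis <- rexp(1e5, 60)
  expect_equal(compute_cv(isis), 1.0, tolerance = 0.02)
  expect_equal(compute_cv2(isis), 1.0, tolerance = 0.02)
  expect_error(compute_cv(0.1), class = "purkinjetrain_insufficient_data")
  expect_error(compute_cv2(0.1), class = "purkinjetrain_insufficient_data")
})

test_that("CV is within 3 SE of 1/sqrt(k) for gamma-renewal trains", {
  for (k in c(1, 2, 4, 16)) {
    s <- generate_renewal(60, 200, "gamma_renewal", gamma_shape = k, seed = k)
    isis <- compute_isis(s$times)
    cv <- compute_cv(isis)
    n <- length(isis$isis_s)
    # SE of the sample CV for gamma ISIs, via the delta method:
    # Var(cv) ~ cv^2 * (1/(2 k) + cv^2) / n  (adequate at these n)
    se <- sqrt((1 / k) * (0.5 / k + 1 / k) / n)
    expect_lt(abs(cv - 1 / sqrt(k)), 3 * se + 1e-3)
  }
})

test_that("pause percentage sums supra-threshold ISIs over recording time", {
  isis <- c(rep(1, 9), 11)  # mean 2, threshold 10, one 11 s pause
  expect_equal(compute_pause_percent(isis, 20), 0.55)
  expect_equal(compute_pause_percent(rep(0.01, 100), 1), 0)
  # analytic oracle for exponential ISIs: E[X 1{X>5mu}]/mu = 6 e^-5
  set.seed(11)
  isis <- rexp(1e5, 60)
  expect_equal(compute_pause_percent(isis, sum(isis)), 6 * exp(-5),
               tolerance = 0.005 / 0.04)
  expect_error(compute_pause_percent(c(1, 2), 0),
               class = "purkinjetrain_validation_error")
})

test_that("statistics are invariant under time translation", {
  s <- generate_renewal(60, 100, "gamma_renewal", gamma_shape = 2, seed = 3)
  isis0 <- compute_isis(s$times)
  isis1 <- compute_isis(s$times + 13.7)
  expect_equal(compute_cv(isis1), compute_cv(isis0))
  expect_equal(compute_cv2(isis1), compute_cv2(isis0))
  expect_equal(compute_pause_percent(isis1, 100), compute_pause_percent(isis0, 100))
  a0 <- compute_autocorrelogram(s$times, recording_duration_s = 100)
  a1 <- compute_autocorrelogram(s$times + 13.7, recording_duration_s = 100)
  expect_identical(a0$counts, a1$counts)
})

test_that("extract_features composes the statistics and keeps the books", {
  # pure regular train: zero variability, no complex events
  s <- spike_series(seq(0.02, 120, by = 0.02), 120, cell_id = "reg")
  fv <- extract_features(s)
  expect_equal(fv$cv, 0)
  expect_equal(fv$cv2, 0)
  expect_equal(fv$pause_percent, 0)
  expect_equal(fv$cs_frequency_hz, 0)
  expect_equal(fv$frequency_hz, 50)
  expect_equal(fv$frequency_mode_hz, 51.25)
  expect_false(fv$heterogeneous_cs)

  # one injected complex spike reduces the simple-spike frequency by 1/T
  tt <- seq(0.02, 120, by = 0.02)
  s2 <- spike_series(sort(c(tt, 120.005)), 121,
                     amplitudes = c(rep(1, length(tt)), 2),
                     spikelet_counts = c(rep(0L, length(tt)), 4L))
  all_ev <- compute_frequency(length(s2$times), 121)
  fv2 <- extract_features(s2)
  expect_equal(fv2$frequency_hz, all_ev - 1 / 121)
  expect_equal(fv2$cs_frequency_hz, 1 / 121)

  # determinism: identical input -> identical vector
  s3 <- generate_series(generator_spec("gamma_renewal", rate_hz = 60,
                                       duration_s = 90, doublet_rate_hz = 0.3,
                                       cs_rate_hz = 0.2, seed = 5))
  expect_identical(extract_features(s3), extract_features(s3))

  # too few simple spikes -> flagged, not dropped
  few <- spike_series(seq(1, 9), 80)
  expect_error(extract_features(few), "simple spikes",
               class = "purkinjetrain_insufficient_data")
})

test_that("removed events leave a single bridging ISI (time conservation)", {
  tt <- seq(0.02, 60, by = 0.02)
  spikelets <- rep(0L, length(tt)); spikelets[1500] <- 4L  # one complex spike
  s <- spike_series(tt, 60, spikelet_counts = spikelets)
  cl <- classify_events(s)
  st <- s$times[cl$labels == "simple"]
  isis <- compute_isis(st)
  expect_equal(sum(isis$isis_s), max(st) - min(st))
  # the bridge interval spans the removed spike
  expect_equal(max(isis$isis_s), 0.04)
  expect_equal(sum(isis$isis_s > 0.03), 1L)
})
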