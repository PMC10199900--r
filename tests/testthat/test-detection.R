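test_that("zero-phase filter is transparent at DC and matches its transfer energy", {
  flat <- trace_recording(rep(1.5, 5000), 1e5)
  expect_equal(lowpass_filter(flat)$samples, rep(1.5, 5000), tolerance = 1e-8)
  expect_error(lowpass_filter(flat, cutoff_Hz = 6e4), "Nyquist")

  # single-pass impulse-response energy vs numeric integral of |H(w)|^2
  filt <- signal::butter(2, 0.2, type = "low")
  h <- signal::filter(filt, c(1, rep(0, 8191)))
  w <- seq(0, pi, length.out = 20001)
  Hw <- vapply(w, function(wi)
    Mod(sum(filt$b * exp(-1i * wi * (seq_along(filt$b) - 1))) /
        sum(filt$a * exp(-1i * wi * (seq_along(filt$a) - 1)))), numeric(1))
  analytic <- mean(Hw^2)  # (1/pi) * integral over [0, pi]
  expect_lt(abs(sum(h^2) - analytic) / analytic, 0.01)
})

test_that("baseline tracker follows drift and bridges masked events", {
  fs <- 1e5
  flat <- trace_recording(rep(2, fs), fs)
  expect_equal(estimate_baseline(flat, 0.3), rep(2, fs), tolerance = 1e-12)
  expect_error(estimate_baseline(flat, 2), "longer than the trace")

  drift_rate <- 0.5  # nA per second
  x <- 2 + drift_rate * seq_len(fs) / fs
  b <- estimate_baseline(trace_recording(x, fs), 0.3)
  expect_lt(max(abs(b - x)), drift_rate * 0.15 + 1e-9)  # half-window lag bound

  # masked event: baseline inside the event stays near the surroundings
  set.seed(1)
  y <- 2 + rnorm(fs, sd = 0.01)
  y[40001:40500] <- y[40001:40500] - 1
  mask <- rep(FALSE, fs); mask[39900:40600] <- TRUE
  bm <- estimate_baseline(trace_recording(y, fs), 0.3, event_mask = mask)
  expect_lt(max(abs(bm[40001:40500] - 2)), 0.01)
})

test_that("false positives on a flat noisy trace stay within the Gaussian tail bound", {
  set.seed(2)
  tr <- trace_recording(3 + rnorm(1e6, sd = 0.01), 1e5)
  filtered <- lowpass_filter(tr)
  base <- estimate_baseline(filtered, 0.3)
  ev <- detect_events(filtered, base)
  # 5-sigma one-sided tail ~ 2.9e-7/sample -> expected < 0.3 raw excursions
  # on 10 s; allow a few-sigma Poisson fluctuation on top
  expect_lte(nrow(ev), 3)
  # no noise excursion survives the 0.1 ms dwell filter
  expect_equal(nrow(filter_events(ev, 1e-4)), 0)
})

test_that("noiseless rectangular events are recovered exactly (oracle route)", {
  cfg <- simulation_config(duration = 10, event_rate = 10, noise_rms = 0,
                           acquisition_cutoff_Hz = NA,
                           analytes = data.frame(label = "long", device = "toy"),
                           seed = 21)
  sim <- simulate_trace(cfg, toy_library())
  ev <- detect_noiseless(sim$trace)
  expect_equal(nrow(ev), nrow(sim$truth))
  expect_true(all(abs(ev$start_index - sim$truth$start_index) <= 1))
  expect_true(all(abs(ev$end_index - sim$truth$end_index) <= 1))
  expect_equal(ev$dI_nA, sim$truth$dI_nA, tolerance = 1e-3)
  expect_true(all(ev$rel_blockade > 0 & ev$rel_blockade <= 1))
})

test_that("detection recovers >= 95% of default-noise synthetic events with matching depths", {
  run <- peak_run("G", "Device #4", n_events = 2000, seed = 101)
  tr <- run$truth; ev <- run$events
  # the event list is truncated to the first n_events detections, so only
  # score ground truth up to the last detection
  tr <- tr[tr$start_s + tr$dwell_s <= max(ev$start_s + ev$dwell_s), ]
  long_truth <- tr[tr$dwell_s >= 3e-4, ]
  mid <- long_truth$start_s + long_truth$dwell_s / 2
  hit <- vapply(seq_len(nrow(long_truth)), function(i)
    any(ev$start_s <= mid[i] & ev$start_s + ev$dwell_s >= mid[i]), logical(1))
  expect_gte(mean(hit), 0.95)  # recall on dwell >= 0.3 ms
  # precision: every detected event midpoint lies inside a true event
  evmid <- ev$start_s + ev$dwell_s / 2
  j <- findInterval(evmid, tr$start_s)
  inside <- j >= 1 & evmid <= tr$start_s[pmax(j, 1)] + tr$dwell_s[pmax(j, 1)]
  expect_gte(mean(inside), 0.95)
  expect_true(all(ev$rel_blockade > 0 & ev$rel_blockade <= 1))
})

test_that("dwell filter is inclusive at the boundary and conserves records", {
  ev <- data.frame(start_index = c(0L, 100L, 200L), end_index = c(5L, 110L, 220L),
                   start_s = c(0, 1e-3, 2e-3), dwell_s = c(5e-5, 1e-4, 2e-4),
                   I0_nA = 3, dI_nA = 0.3, rel_blockade = 0.1)
  expect_identical(filter_events(ev, 0), ev)
  kept <- filter_events(ev, 1e-4)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$dwell_s, c(1e-4, 2e-4))
  expect_identical(kept, ev[2:3, ][, names(ev)], ignore_attr = TRUE)
})

test_that("display downsampling preserves DC and produces the expected length", {
  fs <- 1e5
  tr <- trace_recording(rep(2.5, fs), fs)
  expect_identical(downsample_for_display(tr, fs), tr)
  ds <- downsample_for_display(tr, 1e4)
  expect_equal(length(ds$samples), 1e4)
  expect_equal(mean(ds$samples), 2.5, tolerance = 1e-9)
})

test_that("the detection chain is reproducible on identical inputs", {
  cfg <- simulation_config(duration = 2, event_rate = 20,
                           analytes = data.frame(label = "deep", device = "toy"),
                           seed = 33)
  sim <- simulate_trace(cfg, toy_library())
  d1 <- suppressWarnings(detect_pipeline(sim$trace))
  d2 <- suppressWarnings(detect_pipeline(sim$trace))
  expect_identical(d1$events, d2$events)
  expect_identical(d1$sigma, d2$sigma)
})
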