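test_that("voltage scaling of the blockade is linear and sign-checked", {
  expect_equal(scale_blockade_with_voltage(0.129, 200, 200), 0.129)
  expect_equal(scale_blockade_with_voltage(0.129, 300, 200), 0.1935)
  expect_equal(scale_blockade_with_voltage(0.129, 100, 200), 0.0645)
  v <- seq(150, 350, by = 50)
  expect_true(all(diff(scale_blockade_with_voltage(0.2, v, 200)) > 0))
  expect_error(scale_blockade_with_voltage(0.129, -200, 200), "same sign")
})

test_that("zero event rate yields a flat noisy baseline and empty truth", {
  cfg <- simulation_config(duration = 0.5, event_rate = 0, noise_rms = 0.01,
                           analytes = data.frame(label = "shallow", device = "toy"),
                           seed = 1)
  sim <- simulate_trace(cfg, toy_library())
  expect_equal(nrow(sim$truth), 0)
  expect_lt(abs(mean(sim$trace$samples) - 3), 0.01)
  expect_lt(sd(sim$trace$samples), 0.02)
})

test_that("event counts follow the thinned Poisson arrival process", {
  cfg <- simulation_config(duration = 60, event_rate = 10, noise_rms = 0,
                           acquisition_cutoff_Hz = NA,
                           analytes = data.frame(label = "shallow", device = "toy"),
                           seed = 42)
  sim <- simulate_trace(cfg, toy_library())
  expect_lt(abs(nrow(sim$truth) - 600), 3 * sqrt(600))
  expect_false(is.unsorted(sim$truth$start_s))
  # non-overlap
  expect_true(all(diff(sim$truth$start_s) >
                    sim$truth$dwell_s[-nrow(sim$truth)]))
})

test_that("noiseless unfiltered traces equal the annotated ground truth exactly", {
  cfg <- simulation_config(duration = 5, event_rate = 20, noise_rms = 0,
                           acquisition_cutoff_Hz = NA,
                           analytes = data.frame(label = "deep", device = "toy"),
                           seed = 7)
  sim <- simulate_trace(cfg, toy_library())
  x <- sim$trace$samples
  inside <- rep(FALSE, length(x))
  for (i in seq_len(nrow(sim$truth))) {
    s <- sim$truth$start_index[i] + 1L; e <- sim$truth$end_index[i]
    expect_equal(x[s:e], rep(3 - sim$truth$dI_nA[i], e - s + 1L))
    inside[s:e] <- TRUE
  }
  expect_true(all(x[!inside] == 3))
})

test_that("identical config and seed reproduce the trace bit for bit", {
  cfg <- simulation_config(duration = 1, event_rate = 20,
                           analytes = data.frame(label = "deep", device = "toy"),
                           seed = 9)
  s1 <- simulate_trace(cfg, toy_library())
  s2 <- simulate_trace(cfg, toy_library())
  expect_identical(s1$trace$samples, s2$trace$samples)
  expect_identical(s1$truth, s2$truth)
})

test_that("a deep blockade at high duty cycle makes the current histogram bimodal", {
  lib <- signal_library(list(
    aa_signal_model("blocker", mean = 0.7, sd = 0.02, device = "toy",
                    dwell_median_s = 5e-3, dwell_sigma_log = 0.3)))
  cfg <- simulation_config(duration = 4, event_rate = 60, noise_rms = 0.01,
                           analytes = data.frame(label = "blocker", device = "toy"),
                           seed = 3)
  sim <- simulate_trace(cfg, lib)
  f <- kde_fit(sim$trace$samples, min_rel_density = 0.05)
  expect_gte(nrow(f$modes), 2)
  locs <- range(f$modes$location)
  expect_lt(abs(locs[2] - 3), 0.1)        # open-pore mode
  expect_lt(abs(locs[1] - 3 * 0.3), 0.25) # blocked-level mode
})

test_that("simulation refuses configs that cannot place non-overlapping events", {
  lib <- signal_library(list(
    aa_signal_model("slow", mean = 0.3, sd = 0.02, device = "toy",
                    dwell_median_s = 0.05, dwell_sigma_log = 0.2)))
  cfg <- simulation_config(duration = 2, event_rate = 50,
                           analytes = data.frame(label = "slow", device = "toy"),
                           seed = 1)
  expect_error(simulate_trace(cfg, lib), "duty cycle")
})

test_that("voltage sign incompatible with the analyte charge is rejected", {
  cfg <- simulation_config(duration = 0.5, voltage = -200,
                           analytes = data.frame(label = "shallow", device = "toy"),
                           seed = 1)
  expect_error(simulate_trace(cfg, toy_library()), "cannot drive")
})

test_that("acquisition chain calibrates post-filter noise and has unit DC gain", {
  flat <- trace_recording(rep(2, 20000), 1e5)
  out <- add_acquisition_chain(flat, 1e4, 2, noise_rms = 0)
  expect_equal(out$samples[2000:20000], rep(2, 18001), tolerance = 1e-9)
  expect_error(add_acquisition_chain(out, 1e4), "already applied")

  noisy <- add_acquisition_chain(trace_recording(rep(0, 2e5), 1e5), 1e4, 2,
                                 noise_rms = 0.01, seed = 1)
  expect_lt(abs(sd(noisy$samples[1000:2e5]) - 0.01) / 0.01, 0.10)

  expect_error(add_acquisition_chain(trace_recording(rep(0, 100), 1e5),
                                     cutoff_Hz = 6e4), "Nyquist")
})

test_that("a 20 kHz tone is attenuated by the filter's own transfer magnitude", {
  fs <- 1e5; cutoff <- 1e4
  t <- seq(0, 0.2, by = 1 / fs)
  tone <- trace_recording(sin(2 * pi * 2e4 * t), fs)
  out <- add_acquisition_chain(tone, cutoff, 2, noise_rms = 0)
  measured <- sqrt(2) * sd(out$samples[5000:length(t)])
  # closed-form |H(e^{jw})| from the designed coefficients
  filt <- signal::butter(2, 2 * cutoff / fs, type = "low")
  w <- 2 * pi * 2e4 / fs
  H <- sum(filt$b * exp(-1i * w * (seq_along(filt$b) - 1))) /
       sum(filt$a * exp(-1i * w * (seq_along(filt$a) - 1)))
  expect_lt(abs(measured - Mod(H)) / Mod(H), 0.05)
  expect_lt(measured, 1 / sqrt(17) + 0.05)  # at or below the analog 2nd-order bound
})
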