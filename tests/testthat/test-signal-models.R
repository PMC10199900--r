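test_that("parameter table parsing builds the expected models", {
  lib <- published_library()

  g4 <- get_signal_model(lib, "G", "Device #4")
  expect_equal(g4$mean, 0.229)
  expect_equal(g4$sd, 0.016)
  expect_equal(g4$weight, 1)
  expect_identical(g4$units, "relative")
  expect_identical(g4$charge_sign, -1L)

  h6 <- get_signal_model(lib, "H", "Device #6")
  expect_equal(h6$mean, c(0.298, 0.389))
  expect_equal(h6$sd, c(0.026, 0.068))
  expect_equal(h6$weight, c(0.5, 0.5))

  g3 <- get_signal_model(lib, "G", "Device #3")
  expect_identical(g3$units, "nA")
  expect_equal(g3$mean, 0.129)

  kr <- get_signal_model(lib, "R", "Device #5")
  expect_identical(kr$charge_sign, 1L)
})

test_that("table validation rejects degenerate input", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines("label\tdevice\tcomponent\tweight\tmean\tsd\tunits\tcharge_sign", tmp)
  expect_error(load_signal_library(tmp), "no data rows|empty")

  writeLines(c("label\tdevice\tcomponent\tweight\tmean\tsd\tunits\tcharge_sign",
               "G\tD1\t1\t0.5\t0.2\t0.01\trelative\t-1",
               "G\tD1\t1\t0.5\t0.3\t0.01\trelative\t-1"), tmp)
  expect_error(load_signal_library(tmp), "duplicate")

  writeLines(c("label\tdevice\tcomponent\tweight\tmean\tsd\tunits\tcharge_sign",
               "G\tD1\t1\t1.0\t0.2\t0\trelative\t-1"), tmp)
  expect_error(load_signal_library(tmp), "sd must be > 0")

  expect_error(aa_signal_model("X", mean = c(0.1, 0.2), sd = c(0.01, 0.01),
                               weight = c(0.6, 0.6)), "sum to 1")
})

test_that("library serialization round-trips every field", {
  lib <- published_library()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_signal_library(lib, tmp)
  lib2 <- load_signal_library(tmp)
  expect_setequal(names(lib2$entries), names(lib$entries))
  for (k in names(lib$entries)) expect_equal(lib2$entries[[k]], lib$entries[[k]])
})

test_that("blockade sampler matches its generative distribution", {
  g4 <- get_signal_model(published_library(), "G", "Device #4")
  expect_length(sample_blockades(g4, 0), 0)
  expect_identical(sample_blockades(g4, 100, seed = 5), sample_blockades(g4, 100, seed = 5))

  x <- sample_blockades(g4, 10000, seed = 1)
  expect_true(all(x > 0 & x <= 1))
  expect_lt(abs(mean(x) - 0.229), 3 * 0.016 / sqrt(10000))

  x50 <- sample_blockades(g4, 50000, seed = 2)
  expect_lt(abs(sd(x50) - 0.016) / 0.016, 0.05)
})

test_that("bimodal sampler is recovered by an independent mixture fit", {
  h6 <- get_signal_model(published_library(), "H", "Device #6")
  x <- sample_blockades(h6, 10000, seed = 3)
  fit <- fit_gaussian_mixture(x, k = 2, seed = 4)
  expect_lt(abs(fit$components$mean[1] - 0.298), 0.01)
  expect_lt(abs(fit$components$mean[2] - 0.389), 0.01)

  skip_if_not_installed("mclust")
  # independent EM implementation agrees on the component means
  mclustBIC <- mclust::mclustBIC  # Mclust looks this up unqualified
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(as.numeric(mc$parameters$mean)), fit$components$mean,
               tolerance = 0.01)
})

test_that("dwell sampler is positive, reproducible, and mostly above 0.1 ms", {
  m <- get_signal_model(published_library(), "G", "Device #4")
  expect_length(sample_dwells(m, 0), 0)
  d <- sample_dwells(m, 10000, seed = 6)
  expect_true(all(d > 0))
  frac_short <- mean(d < 1e-4)
  expect_lt(frac_short, 0.05)
  # agreement with the lognormal CDF at the dwell-filter cutoff
  expected <- plnorm(1e-4, log(5e-4), 0.6)
  expect_lt(abs(frac_short - expected), 3 * sqrt(expected * (1 - expected) / 10000) + 1e-3)
})
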