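# Shared fixtures, computed once per test run and cached. Heavy
# simulate->detect->fit runs are reused across unit and acceptance tests.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, fn) {
  if (is.null(.fixtures[[key]])) assign(key, fn(), envir = .fixtures)
  .fixtures[[key]]
}

published_library <- function() fixture("library", function() load_signal_library())

# Full simulate -> detect -> peak-call run for one analyte, cached by key.
peak_run <- function(label, device, n_events = 2000L, seed = 101L, ...) {
  key <- paste("peak", label, device, n_events, seed, sep = "|")
  fixture(key, function()
    suppressWarnings(recover_blockade_peak(published_library(), label, device,
                                           n_events = n_events, seed = seed, ...)))
}

# Bootstrap standard error of the KDE mode of a sample.
kde_mode_se <- function(values, B = 100L, seed = 1L) {
  set.seed(seed)
  stats::sd(vapply(seq_len(B), function(b)
    kde_mode(sample(values, replace = TRUE)), numeric(1)))
}

# Balanced two-class classification experiment, cached.
classification_run <- function(label_a, label_b, device, n_per_class = 2000L,
                               seed = 202L) {
  key <- paste("cls", label_a, label_b, device, n_per_class, seed, sep = "|")
  fixture(key, function()
    classification_experiment(published_library(),
                              data.frame(label = c(label_a, label_b),
                                         device = device),
                              n_per_class = n_per_class, classifier = "bayes",
                              seed = seed))
}

# Small synthetic library for fast detector/classifier unit tests.
toy_library <- function() fixture("toy_library", function() {
  signal_library(list(
    aa_signal_model("shallow", mean = 0.10, sd = 0.01, device = "toy"),
    aa_signal_model("deep", mean = 0.50, sd = 0.01, device = "toy"),
    aa_signal_model("long", mean = 0.30, sd = 0.02, device = "toy",
                    dwell_median_s = 1e-3, dwell_sigma_log = 0.25)))
})

# Noiseless, unfiltered detection (oracle route): two-pass baseline with
# event masking, no detection filter, absolute fallback threshold.
detect_noiseless <- function(trace, config = detection_config()) {
  base1 <- estimate_baseline(trace, config$baseline_window_s)
  ev1 <- detect_events(trace, base1, config)
  mask <- rep(FALSE, length(trace$samples))
  for (i in seq_len(nrow(ev1)))
    mask[(ev1$start_index[i] + 1L):ev1$end_index[i]] <- TRUE
  base2 <- estimate_baseline(trace, config$baseline_window_s, event_mask = mask)
  detect_events(trace, base2, config)
}
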