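#' Trace recording container
#'
#' A uniformly sampled ionic-current time series in nA with its sampling
#' rate and provenance metadata.
#'
#' @param samples Numeric vector of current samples, nA. Must be finite.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param meta Named list of provenance fields (seed, config, filter chain).
#' @return An object of class `trace_recording`.
#' @export
trace_recording <- function(samples, sampling_rate, meta = list()) {
  stopifnot(is.numeric(samples), sampling_rate > 0)
  if (any(!is.finite(samples))) stop("trace samples must be finite")
  structure(list(samples = as.numeric(samples),
                 sampling_rate = as.numeric(sampling_rate),
                 meta = meta),
            class = "trace_recording")
}

#' @export
print.trace_recording <- function(x, ...) {
  cat(sprintf("<trace_recording> %d samples @ %g Hz (%.3f s), mean %.3f nA\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, mean(x$samples)))
  invisible(x)
}

#' Simulation configuration
#'
#' Conditions of one synthetic measurement. Defaults mirror the
#' experimental setup: 100 kHz digitisation followed by a 10 kHz low-pass
#' acquisition filter, a +/-200 mV driving bias, and about 0.01 nA of
#' post-filter baseline noise.
#'
#' @param duration Recording length, seconds.
#' @param sampling_rate Hz; must be at least twice the acquisition cutoff.
#' @param I0 Open-pore current at `voltage`, nA.
#' @param voltage Applied bias on the trans chamber, mV (signed). Its sign
#'   must be opposite to the charge sign of every analyte simulated.
#' @param reference_voltage mV at which the library blockade values were
#'   tabulated (default 200); blockade amplitudes are scaled linearly with
#'   |voltage| / |reference_voltage|.
#' @param noise_rms Target post-filter baseline noise RMS, nA.
#' @param event_rate Poisson arrival rate, events per second.
#' @param analytes Data frame with columns `label`, `device`, `abundance`
#'   (relative abundances, summing to 1).
#' @param acquisition_cutoff_Hz,acquisition_order Low-pass acquisition
#'   filter applied causally to signal plus noise (the simulator's stand-in
#'   for the recording hardware's anti-alias filter). Set
#'   `acquisition_cutoff_Hz = NA` for a raw, unfiltered trace.
#' @param seed Integer RNG seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(duration, analytes,
                              sampling_rate = 1e5, I0 = 3, voltage = 200,
                              reference_voltage = 200, noise_rms = 0.01,
                              event_rate = 10,
                              acquisition_cutoff_Hz = 1e4, acquisition_order = 2,
                              seed = 1L) {
  stopifnot(duration > 0, sampling_rate > 0, I0 > 0, event_rate >= 0,
            voltage != 0, reference_voltage != 0, noise_rms >= 0)
  if (!is.na(acquisition_cutoff_Hz) && sampling_rate < 2 * acquisition_cutoff_Hz)
    stop("sampling_rate must be at least twice the acquisition cutoff")
  analytes <- as.data.frame(analytes)
  stopifnot(all(c("label", "device") %in% names(analytes)))
  if (is.null(analytes$abundance)) analytes$abundance <- 1 / nrow(analytes)
  if (abs(sum(analytes$abundance) - 1) > 1e-9) stop("analyte abundances must sum to 1")
  structure(list(duration = duration, sampling_rate = sampling_rate, I0 = I0,
                 voltage = voltage, reference_voltage = reference_voltage,
                 noise_rms = noise_rms, event_rate = event_rate,
                 analytes = analytes,
                 acquisition_cutoff_Hz = acquisition_cutoff_Hz,
                 acquisition_order = acquisition_order,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Scale a blockade amplitude with the applied voltage
#'
#' Blockade amplitudes grow with the driving bias; an ohmic (linear)
#' scaling in |voltage| is used, anchored at the tabulation voltage.
#'
#' @param dI_at_reference Blockade at `reference_voltage`, nA.
#' @param voltage,reference_voltage mV, nonzero and of the same sign.
#' @return Scaled blockade, nA; strictly increasing in |voltage|.
#' @export
scale_blockade_with_voltage <- function(dI_at_reference, voltage, reference_voltage) {
  stopifnot(all(voltage != 0), all(reference_voltage != 0))
  if (any(sign(voltage) != sign(reference_voltage)))
    stop("voltage and reference_voltage must have the same sign")
  dI_at_reference * abs(voltage) / abs(reference_voltage)
}

# Variance gain of a digital filter: sum of squared impulse response.
filter_variance_gain <- function(filt, n = 8192L) {
  h <- signal::filter(filt, c(1, rep(0, n - 1L)))
  sum(h^2)
}

#' Apply the acquisition chain to a raw trace
#'
#' Adds white Gaussian noise pre-scaled so that the *post-filter* baseline
#' RMS matches `noise_rms`, then applies a causal low-pass Butterworth
#' filter of the given order and cutoff, mimicking the real-time hardware
#' filter of the recording chain. Recorded in the trace metadata; applying
#' the chain twice is refused.
#'
#' @param trace A [trace_recording] of the noiseless signal.
#' @param cutoff_Hz Low-pass cutoff (must be below Nyquist).
#' @param order Filter order (default 2).
#' @param noise_rms Target post-filter noise RMS in nA (0 for none).
#' @param seed Optional RNG seed for the noise draw.
#' @return A filtered [trace_recording].
#' @export
add_acquisition_chain <- function(trace, cutoff_Hz = 1e4, order = 2,
                                  noise_rms = 0, seed = NULL) {
  stopifnot(inherits(trace, "trace_recording"))
  if (isTRUE(trace$meta$acquisition_applied)) stop("acquisition chain already applied")
  if (cutoff_Hz >= trace$sampling_rate / 2) stop("cutoff must be below Nyquist")
  if (!is.null(seed)) set.seed(seed)
  filt <- signal::butter(order, 2 * cutoff_Hz / trace$sampling_rate, type = "low")
  x <- trace$samples
  if (noise_rms > 0) {
    gain <- sqrt(filter_variance_gain(filt))
    x <- x + stats::rnorm(length(x), sd = noise_rms / gain)
  }
  y <- as.numeric(signal::filter(filt, x))
  meta <- trace$meta
  meta$acquisition_applied <- TRUE
  meta$acquisition <- list(type = "butterworth", order = order,
                           cutoff_Hz = cutoff_Hz, noise_rms = noise_rms)
  trace_recording(y, trace$sampling_rate, meta)
}

# Draw non-overlapping event placements: Poisson arrivals thinned so that
# any arrival landing before the previous event has cleared (plus a guard
# gap) is dropped. Returns start times and dwells, both in seconds.
place_events <- function(duration, rate, dwells, guard_s) {
  n_target <- length(dwells)
  if (n_target == 0L) return(list(start = numeric(0), dwell = numeric(0)))
  if (rate * mean(dwells) > 0.5)
    stop("event_rate x mean dwell approaches duty cycle 1; cannot place non-overlapping events")
  starts <- numeric(n_target); kept <- 0L
  t <- guard_s
  free_from <- guard_s
  i <- 1L
  while (kept < n_target) {
    t <- t + stats::rexp(1L, rate)
    if (t > duration - guard_s) break
    if (t < free_from) next  # overlap with previous event: thinned out
    kept <- kept + 1L
    starts[kept] <- t
    free_from <- t + dwells[kept] + guard_s
  }
  list(start = starts[seq_len(kept)], dwell = dwells[seq_len(kept)])
}

#' Simulate a nanopore current recording
#'
#' Generates a ground-truthed synthetic trace: an open-pore baseline `I0`
#' carrying Gaussian noise, interrupted by electrophoretically driven
#' translocation events. Each event is a rectangular blockade whose depth
#' is drawn from the analyte's signal model (scaled linearly with voltage
#' relative to the tabulation voltage) and whose dwell is drawn from the
#' analyte's lognormal dwell model; arrivals are Poisson, thinned to forbid
#' overlap. The acquisition chain (noise + causal low-pass filter) is
#' applied last unless disabled via the config.
#'
#' Events are drawn only in the interior of the recording, leaving a short
#' guard of clean baseline around each event and at the trace edges.
#'
#' @param config A [simulation_config].
#' @param library A [signal_library] resolving every configured analyte.
#' @return A list with `trace` (a [trace_recording]) and `truth`, a data
#'   frame with one row per injected event: `label`, `device`, `start_s`,
#'   `dwell_s`, `dI_nA`, `rel_blockade`, `start_index`, `end_index`
#'   (0-based, half-open).
#' @export
simulate_trace <- function(config, library) {
  stopifnot(inherits(config, "simulation_config"), inherits(library, "signal_library"))
  set.seed(config$seed)
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  models <- lapply(seq_len(nrow(config$analytes)), function(i)
    get_signal_model(library, config$analytes$label[i], config$analytes$device[i]))
  for (m in models)
    if (sign(config$voltage) != -m$charge_sign)
      stop(sprintf("voltage sign %+d cannot drive %s (charge %+d)",
                   sign(config$voltage), m$label, m$charge_sign))

  guard_s <- 2e-3  # clean baseline around events and at trace edges
  truth <- NULL
  x <- rep(config$I0, n)
  if (config$event_rate > 0) {
    # draw a generous batch of dwells, then keep what fits
    n_max <- stats::qpois(1 - 1e-9, config$event_rate * config$duration) + 10L
    comp <- sample.int(nrow(config$analytes), n_max, replace = TRUE,
                       prob = config$analytes$abundance)
    dwells <- numeric(n_max)
    for (i in seq_len(n_max)) dwells[i] <- sample_dwells(models[[comp[i]]], 1L)
    placed <- place_events(config$duration, config$event_rate, dwells, guard_s)
    k <- length(placed$start)
    if (k > 0L) {
      comp <- comp[seq_len(k)]
      depth_nA <- rel <- numeric(k)
      for (i in seq_len(k)) {
        m <- models[[comp[i]]]
        b <- sample_blockades(m, 1L)
        dI_ref <- if (m$units == "relative") b * config$I0 else b
        depth_nA[i] <- scale_blockade_with_voltage(dI_ref, abs(config$voltage),
                                                   abs(config$reference_voltage))
        depth_nA[i] <- min(depth_nA[i], config$I0)  # cannot block below 0 nA
        rel[i] <- depth_nA[i] / config$I0
      }
      start_idx <- round(placed$start * fs)
      end_idx <- pmin(start_idx + pmax(1L, round(placed$dwell * fs)), n)
      for (i in seq_len(k))
        x[(start_idx[i] + 1L):end_idx[i]] <- config$I0 - depth_nA[i]
      truth <- data.frame(
        label = config$analytes$label[comp], device = config$analytes$device[comp],
        start_s = start_idx / fs, dwell_s = (end_idx - start_idx) / fs,
        dI_nA = depth_nA, rel_blockade = rel,
        start_index = start_idx, end_index = end_idx,
        stringsAsFactors = FALSE)
    }
  }
  if (is.null(truth))
    truth <- data.frame(label = character(0), device = character(0),
                        start_s = numeric(0), dwell_s = numeric(0),
                        dI_nA = numeric(0), rel_blockade = numeric(0),
                        start_index = integer(0), end_index = integer(0))

  meta <- list(seed = config$seed, I0 = config$I0, voltage = config$voltage,
               units = "nA", simulated = TRUE)
  tr <- trace_recording(x, fs, meta)
  if (!is.na(config$acquisition_cutoff_Hz)) {
    tr <- add_acquisition_chain(tr, config$acquisition_cutoff_Hz,
                                config$acquisition_order, config$noise_rms)
  } else if (config$noise_rms > 0) {
    tr <- trace_recording(x + stats::rnorm(n, sd = config$noise_rms), fs, meta)
  }
  list(trace = tr, truth = truth)
}
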