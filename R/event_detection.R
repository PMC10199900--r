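#' Event-detection configuration
#'
#' Parameters of the trace-processing chain: a zero-phase 2nd-order
#' Butterworth low-pass at 10 kHz, a 300 ms moving-average baseline, a
#' dual-threshold detector (an event opens when the current drops more than
#' `threshold_k` local-noise SDs below baseline; its boundaries are the
#' surrounding crossings of the shallower `boundary_k`-SD level), and a
#' dwell filter that drops events shorter than 0.1 ms.
#'
#' @param filter_cutoff_Hz Detection-filter cutoff (Hz).
#' @param filter_order Butterworth order.
#' @param baseline_window_s Moving-average window, seconds.
#' @param threshold_k Detection threshold, multiples of the noise SD.
#' @param boundary_k Boundary threshold, multiples of the noise SD; must be
#'   smaller than `threshold_k`.
#' @param min_dwell_s Minimum retained dwell (inclusive), seconds.
#' @param min_events_warning Warn when fewer events survive (population
#'   statistics below this count are considered unreliable).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(filter_cutoff_Hz = 1e4, filter_order = 2,
                             baseline_window_s = 0.3,
                             threshold_k = 5, boundary_k = 2.5,
                             min_dwell_s = 1e-4, min_events_warning = 300L) {
  stopifnot(boundary_k < threshold_k, min_dwell_s >= 0, baseline_window_s > 0)
  structure(list(filter_cutoff_Hz = filter_cutoff_Hz, filter_order = filter_order,
                 baseline_window_s = baseline_window_s,
                 threshold_k = threshold_k, boundary_k = boundary_k,
                 min_dwell_s = min_dwell_s,
                 min_events_warning = as.integer(min_events_warning)),
            class = "detection_config")
}

#' Zero-phase low-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering, so that event
#' boundaries are smoothed symmetrically and dwell times are not shifted.
#'
#' @param trace A [trace_recording].
#' @param cutoff_Hz Cutoff frequency, below Nyquist.
#' @param order Filter order.
#' @return The filtered [trace_recording]; metadata records the operation.
#' @export
lowpass_filter <- function(trace, cutoff_Hz = 1e4, order = 2) {
  stopifnot(inherits(trace, "trace_recording"))
  if (cutoff_Hz >= trace$sampling_rate / 2) stop("cutoff must be below Nyquist")
  filt <- signal::butter(order, 2 * cutoff_Hz / trace$sampling_rate, type = "low")
  # odd-reflection padding suppresses the forward-backward edge transients
  x <- trace$samples
  n <- length(x)
  npad <- min(n - 1L, 10L * ceiling(trace$sampling_rate / cutoff_Hz))
  xp <- c(2 * x[1] - x[(npad + 1L):2],
          x,
          2 * x[n] - x[(n - 1L):(n - npad)])
  y <- signal::filtfilt(filt, xp)[(npad + 1L):(npad + n)]
  meta <- trace$meta
  meta$detection_filter <- list(type = "butterworth", order = order,
                                cutoff_Hz = cutoff_Hz, zero_phase = TRUE)
  trace_recording(as.numeric(y), trace$sampling_rate, meta)
}

# Centered moving average with shrinking edge windows; NA entries in x are
# excluded from the average (cumsum trick, O(n)).
masked_moving_average <- function(x, half_w) {
  n <- length(x)
  ok <- !is.na(x)
  xv <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(xv)); cn <- c(0, cumsum(ok))
  i <- seq_len(n)
  lo <- pmax(i - half_w, 1L); hi <- pmin(i + half_w, n)
  s <- cs[hi + 1L] - cs[lo]
  m <- cn[hi + 1L] - cn[lo]
  out <- ifelse(m > 0, s / m, NA_real_)
  if (anyNA(out)) {  # windows fully masked: interpolate across them
    out <- stats::approx(i[!is.na(out)], out[!is.na(out)], xout = i, rule = 2)$y
  }
  out
}

#' Moving-average baseline estimate
#'
#' Centered moving average over a 300 ms (default) window. Samples under
#' `event_mask` are excluded and bridged by interpolation, so deep events
#' do not drag the baseline down; window edges shrink at the trace ends.
#'
#' @param trace A [trace_recording] (already detection-filtered).
#' @param window_s Window length, seconds; must cover >= 10 samples and be
#'   no longer than the trace.
#' @param event_mask Optional logical vector, `TRUE` on samples inside
#'   (or near) events.
#' @return Numeric baseline series, same length as the trace, nA.
#' @export
estimate_baseline <- function(trace, window_s = 0.3, event_mask = NULL) {
  stopifnot(inherits(trace, "trace_recording"))
  n <- length(trace$samples)
  w <- round(window_s * trace$sampling_rate)
  if (w < 10) stop("baseline window must span at least 10 samples")
  if (w > n) stop("baseline window is longer than the trace")
  x <- trace$samples
  if (!is.null(event_mask)) {
    stopifnot(length(event_mask) == n)
    x[event_mask] <- NA_real_
  }
  masked_moving_average(x, half_w = w %/% 2L)
}

# Robust noise SD from baseline residuals outside events.
estimate_noise_sd <- function(samples, baseline, event_mask = NULL) {
  r <- samples - baseline
  if (!is.null(event_mask)) r <- r[!event_mask]
  stats::mad(r, center = 0)
}

# Expand each run of below-detection-threshold samples outward to the
# nearest crossings of the boundary level, merge overlaps. `below_b` is the
# logical vector current < baseline - boundary_k*sigma.
expand_to_boundaries <- function(det_runs, below_b, n) {
  if (nrow(det_runs) == 0L) return(det_runs)
  # run-length structure of below_b: for each sample, the start/end of its run
  r <- rle(below_b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_id <- rep.int(seq_along(r$lengths), r$lengths)
  out_s <- integer(nrow(det_runs)); out_e <- integer(nrow(det_runs))
  for (i in seq_len(nrow(det_runs))) {
    rid <- run_id[det_runs$start[i]]   # detection samples are below_b too
    out_s[i] <- starts[rid]
    rid2 <- run_id[det_runs$end[i]]
    out_e[i] <- ends[rid2]
  }
  ev <- unique(data.frame(start = out_s, end = out_e))
  ev[order(ev$start), , drop = FALSE]
}

#' Detect translocation events in a trace
#'
#' Dual-threshold detection against a running baseline: an event opens when
#' the current falls below `baseline - threshold_k * sigma` (sigma is the
#' robust noise SD of the event-free residuals) and its boundaries are the
#' nearest surrounding crossings of `baseline - boundary_k * sigma`. The
#' blockade depth is the baseline minus the mean of the in-event samples,
#' with a few edge samples trimmed (half a filter rise time per side) so the
#' low-pass ramps do not bias the depth; for events too short to trim, the
#' deepest samples are used.
#'
#' On a noiseless trace (sigma ~ 0) the detector falls back to an absolute
#' threshold of 1% of the baseline.
#'
#' @param trace A filtered [trace_recording].
#' @param baseline Baseline series from [estimate_baseline()].
#' @param config A [detection_config].
#' @param sigma Optional externally estimated noise SD.
#' @return A data frame of events sorted by start: `start_index`,
#'   `end_index` (0-based, half-open), `start_s`, `dwell_s`, `I0_nA`,
#'   `dI_nA`, `rel_blockade`.
#' @export
detect_events <- function(trace, baseline, config = detection_config(), sigma = NULL) {
  stopifnot(inherits(trace, "trace_recording"), length(baseline) == length(trace$samples))
  x <- trace$samples
  n <- length(x)
  if (is.null(sigma)) sigma <- estimate_noise_sd(x, baseline)
  if (sigma < 1e-6 * stats::median(baseline)) {
    thr_det <- 0.01 * baseline
    thr_bnd <- 0.5 * thr_det
  } else {
    thr_det <- rep(config$threshold_k * sigma, n)
    thr_bnd <- rep(config$boundary_k * sigma, n)
  }
  below_d <- x < baseline - thr_det
  below_b <- x < baseline - thr_bnd
  if (!any(below_d)) return(empty_event_frame())
  r <- rle(below_d)
  ends <- cumsum(r$lengths)
  det_runs <- data.frame(start = (ends - r$lengths + 1L)[r$values],
                         end = ends[r$values])
  ev <- expand_to_boundaries(det_runs, below_b, n)

  fs <- trace$sampling_rate
  n_trim <- ceiling(0.5 * fs / config$filter_cutoff_Hz)
  k <- nrow(ev)
  I0 <- dI <- numeric(k)
  for (i in seq_len(k)) {
    s <- ev$start[i]; e <- ev$end[i]
    I0[i] <- mean(baseline[s:e])
    len <- e - s + 1L
    trim <- min(n_trim, (len - 1L) %/% 2L)
    core <- x[(s + trim):(e - trim)]
    if (len - 2L * trim < 3L) core <- sort(x[s:e])[seq_len(min(3L, len))]
    dI[i] <- I0[i] - mean(core)
  }
  out <- data.frame(
    start_index = ev$start - 1L, end_index = ev$end,
    start_s = (ev$start - 1L) / fs, dwell_s = (ev$end - ev$start + 1L) / fs,
    I0_nA = I0, dI_nA = dI, rel_blockade = dI / I0)
  out <- out[out$dI_nA > 0 & out$rel_blockade <= 1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_event_frame <- function() {
  data.frame(start_index = integer(0), end_index = integer(0),
             start_s = numeric(0), dwell_s = numeric(0),
             I0_nA = numeric(0), dI_nA = numeric(0), rel_blockade = numeric(0))
}

#' Dwell-filter an event table
#'
#' Retains events with dwell time at least `min_dwell_s` (inclusive at the
#' boundary: an event of exactly 0.1 ms survives the default filter).
#' Retained rows are unchanged and keep their order.
#'
#' @param events Event data frame from [detect_events()].
#' @param min_dwell_s Minimum dwell, seconds.
#' @return Filtered event data frame.
#' @export
filter_events <- function(events, min_dwell_s = 1e-4) {
  stopifnot(is.data.frame(events), min_dwell_s >= 0)
  out <- events[events$dwell_s >= min_dwell_s, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Decimate a trace for display
#'
#' Anti-aliased decimation to a lower rate, for plotting only; detection
#' always runs on the full-rate trace.
#'
#' @param trace A [trace_recording].
#' @param target_rate_Hz Target rate; must divide into the sampling rate.
#' @return A decimated [trace_recording].
#' @export
downsample_for_display <- function(trace, target_rate_Hz = 1e4) {
  stopifnot(inherits(trace, "trace_recording"), target_rate_Hz <= trace$sampling_rate)
  if (target_rate_Hz == trace$sampling_rate) return(trace)
  fac <- trace$sampling_rate / target_rate_Hz
  if (abs(fac - round(fac)) > 1e-9) stop("sampling_rate must be an integer multiple of target_rate_Hz")
  fac <- as.integer(round(fac))
  y <- lowpass_filter(trace, cutoff_Hz = 0.4 * target_rate_Hz, order = 4)$samples
  idx <- seq(1L, length(y), by = fac)
  meta <- trace$meta
  meta$display_downsampled_from_Hz <- trace$sampling_rate
  trace_recording(y[idx] - mean(y[idx]) + mean(trace$samples[idx]),
                  target_rate_Hz, meta)
}

#' Run the full detection chain on a raw trace
#'
#' Zero-phase low-pass filter, two-pass baseline (a first pass without a
#' mask, then a second with detected events masked out so they do not bias
#' the baseline or the noise estimate), dual-threshold detection, and the
#' dwell filter.
#'
#' @param trace A raw [trace_recording].
#' @param config A [detection_config].
#' @return A list: `events` (dwell-filtered data frame), `filtered` (the
#'   filtered trace), `baseline`, `sigma` (noise SD, nA).
#' @export
detect_pipeline <- function(trace, config = detection_config()) {
  filtered <- lowpass_filter(trace, config$filter_cutoff_Hz, config$filter_order)
  base1 <- estimate_baseline(filtered, config$baseline_window_s)
  ev1 <- detect_events(filtered, base1, config)
  mask <- rep(FALSE, length(filtered$samples))
  if (nrow(ev1) > 0L) {
    pad <- ceiling(filtered$sampling_rate / config$filter_cutoff_Hz)
    for (i in seq_len(nrow(ev1))) {
      lo <- max(1L, ev1$start_index[i] + 1L - pad)
      hi <- min(length(mask), ev1$end_index[i] + pad)
      mask[lo:hi] <- TRUE
    }
  }
  base2 <- estimate_baseline(filtered, config$baseline_window_s, event_mask = mask)
  sigma <- estimate_noise_sd(filtered$samples, base2, event_mask = mask)
  ev <- detect_events(filtered, base2, config, sigma = sigma)
  ev <- filter_events(ev, config$min_dwell_s)
  if (nrow(ev) < config$min_events_warning)
    warning(sprintf("only %d events survive the dwell filter (< %d): population statistics may be unreliable",
                    nrow(ev), config$min_events_warning))
  list(events = ev, filtered = filtered, baseline = base2, sigma = sigma)
}
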