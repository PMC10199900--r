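#' Simulate a labelled set of event snippets
#'
#' Generates standalone, ground-truthed translocation-event waveforms —
#' one short recording per event (baseline context, rectangular blockade,
#' noise, causal acquisition filter) — without the cost of a full
#' continuous trace. This is the input generator for classifier
#' experiments, where only per-event waveforms and features matter; event
#' arrival statistics play no role.
#'
#' Event features are *measured* from the noisy, filtered snippet exactly
#' as the detector would measure them: the local open-pore current is the
#' mean of the surrounding context, and the blockade depth is the baseline
#' minus the trimmed in-event mean.
#'
#' @param library A [signal_library].
#' @param analytes Data frame with columns `label`, `device`; one class per
#'   row. All must share a charge sign.
#' @param n_per_class Events per class.
#' @param I0 Open-pore current, nA.
#' @param voltage Driving bias, mV; defaults to -200 x charge sign.
#' @param reference_voltage Tabulation voltage, mV.
#' @param sampling_rate Hz.
#' @param noise_rms Post-filter noise RMS, nA.
#' @param cutoff_Hz,order Acquisition filter.
#' @param context_s Baseline context on each side of the event, seconds.
#' @param seed RNG seed.
#' @return An `event_set`: `events` (data frame `label`, `device`,
#'   `dwell_s`, `I0_nA`, `dI_nA`, `rel_blockade`), `waveforms` (list of
#'   snippets, nA), `event_span` (matrix of in-snippet start/end sample of
#'   each event, 1-based inclusive), `sampling_rate`.
#' @export
simulate_event_set <- function(library, analytes, n_per_class = 1000L,
                               I0 = 3, voltage = NULL, reference_voltage = 200,
                               sampling_rate = 1e5, noise_rms = 0.01,
                               cutoff_Hz = 1e4, order = 2,
                               context_s = 1e-3, seed = 1L) {
  stopifnot(inherits(library, "signal_library"))
  analytes <- as.data.frame(analytes)
  models <- lapply(seq_len(nrow(analytes)), function(i)
    get_signal_model(library, analytes$label[i], analytes$device[i]))
  signs <- unique(vapply(models, `[[`, integer(1), "charge_sign"))
  if (length(signs) != 1L) stop("all analytes in one event set must share a charge sign")
  if (is.null(voltage)) voltage <- -200 * signs
  if (sign(voltage) != -signs) stop("voltage sign cannot drive these analytes")
  set.seed(seed)
  fs <- sampling_rate
  ctx <- max(10L, round(context_s * fs))
  pad <- 4L * ctx  # filter warm-up, dropped after filtering
  filt <- signal::butter(order, 2 * cutoff_Hz / fs, type = "low")
  noise_in <- if (noise_rms > 0) noise_rms / sqrt(filter_variance_gain(filt)) else 0
  n_trim <- ceiling(0.5 * fs / cutoff_Hz)

  total <- n_per_class * nrow(analytes)
  waveforms <- vector("list", total)
  span <- matrix(NA_integer_, total, 2L)
  lab <- dev <- character(total)
  dwell <- I0m <- dI <- numeric(total)
  row <- 0L
  for (ci in seq_len(nrow(analytes))) {
    m <- models[[ci]]
    for (j in seq_len(n_per_class)) {
      row <- row + 1L
      dw <- sample_dwells(m, 1L)
      len <- max(1L, round(dw * fs))
      b <- sample_blockades(m, 1L)
      dI_ref <- if (m$units == "relative") b * I0 else b
      depth <- min(scale_blockade_with_voltage(dI_ref, abs(voltage),
                                               abs(reference_voltage)), I0)
      raw <- rep(I0, pad + ctx + len + ctx)
      raw[(pad + ctx + 1L):(pad + ctx + len)] <- I0 - depth
      if (noise_in > 0) raw <- raw + stats::rnorm(length(raw), sd = noise_in)
      y <- as.numeric(signal::filter(filt, raw))[-seq_len(pad)]
      s <- ctx + 1L; e <- ctx + len
      base_local <- mean(y[c(seq_len(ctx - n_trim), (e + n_trim):(length(y)))])
      trim <- min(n_trim, (len - 1L) %/% 2L)
      core <- y[(s + trim):(e - trim)]
      if (len - 2L * trim < 3L) core <- sort(y[s:e])[seq_len(min(3L, len))]
      waveforms[[row]] <- y
      span[row, ] <- c(s, e)
      lab[row] <- m$label; dev[row] <- m$device
      dwell[row] <- len / fs
      I0m[row] <- base_local
      dI[row] <- base_local - mean(core)
    }
  }
  structure(list(events = data.frame(label = lab, device = dev, dwell_s = dwell,
                                     I0_nA = I0m, dI_nA = dI,
                                     rel_blockade = dI / I0m,
                                     stringsAsFactors = FALSE),
                 waveforms = waveforms, event_span = span, sampling_rate = fs),
            class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> %d events @ %g Hz: %s\n", nrow(x$events),
              x$sampling_rate,
              paste(names(table(x$events$label)), table(x$events$label),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Encode an event set for classification
#'
#' Applies the standard event encoding (20% dwell context each side,
#' resampled to `L` points, normalized by the local open-pore current) to
#' every snippet in an [simulate_event_set()] result.
#'
#' @param event_set An `event_set`.
#' @param L Encoded length.
#' @return An `encoded_events` object with labels.
#' @export
encode_event_set <- function(event_set, L = 128L) {
  stopifnot(inherits(event_set, "event_set"))
  n <- nrow(event_set$events)
  X <- matrix(NA_real_, n, L)
  for (i in seq_len(n)) {
    w <- event_set$waveforms[[i]]
    s <- event_set$event_span[i, 1L]; e <- event_set$event_span[i, 2L]
    ctx <- max(1L, round(0.2 * (e - s + 1L)))
    lo <- max(1L, s - ctx); hi <- min(length(w), e + ctx)
    X[i, ] <- encode_snippet(w[lo:hi], event_set$events$I0_nA[i], L)
  }
  new_encoded_events(X, event_set$events, L)
}
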