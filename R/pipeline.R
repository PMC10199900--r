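#' Simulate one analyte and recover its blockade peak
#'
#' The core parameter-recovery experiment: simulate a recording of one
#' analyte from its library model, run the full detection chain (filter,
#' two-pass baseline, dual-threshold detection, dwell filter), and call
#' the blockade peak by KDE (unimodal models) or a two-component
#' Gaussian-mixture EM fit (bimodal models).
#'
#' The number of simulated events is controlled through `n_events`; the
#' recording duration is sized so the Poisson arrival process delivers at
#' least that many events, and the event list is truncated to the first
#' `n_events` detections for determinism of the sample size.
#'
#' @param library A [signal_library].
#' @param label,device Analyte to simulate.
#' @param n_events Target number of detected, dwell-filtered events.
#' @param I0 Open-pore current, nA.
#' @param event_rate Arrival rate, events/s.
#' @param noise_rms Post-filter noise RMS, nA.
#' @param seed RNG seed.
#' @param mixture_k Components for the peak call; defaults to the number
#'   of components in the generative model.
#' @return A list: `events` (detected, dwell-filtered), `fit` (a
#'   `density_fit` on the feature matching the model's units), `modes`
#'   (mode/component-mean locations), `peak` (the primary peak: the
#'   highest-density KDE mode, or the lower component mean of a mixture
#'   fit), `truth`, `sigma`, `feature` (`"dI_nA"` or `"rel_blockade"`).
#' @export
recover_blockade_peak <- function(library, label, device, n_events = 1000L,
                                  I0 = 3, event_rate = 25, noise_rms = 0.01,
                                  seed = 1L, mixture_k = NULL) {
  model <- get_signal_model(library, label, device)
  voltage <- -200 * model$charge_sign
  # ~15% head-room over the target count for dwell-filter and edge losses
  duration <- 1.15 * n_events / event_rate
  cfg <- simulation_config(duration = duration,
                           analytes = data.frame(label = label, device = device,
                                                 abundance = 1),
                           I0 = I0, voltage = voltage, event_rate = event_rate,
                           noise_rms = noise_rms, seed = seed)
  sim <- simulate_trace(cfg, library)
  det <- detect_pipeline(sim$trace)
  ev <- det$events
  if (nrow(ev) > n_events) ev <- ev[seq_len(n_events), , drop = FALSE]
  feature <- if (model$units == "nA") "dI_nA" else "rel_blockade"
  k <- if (is.null(mixture_k)) length(model$mean) else mixture_k
  fit <- if (k >= 2L)
    fit_gaussian_mixture(ev[[feature]], k = k, restarts = 10L)
  else kde_fit(ev[[feature]])
  modes <- if (k >= 2L) fit$components$mean else fit$modes$location
  peak <- if (k >= 2L) fit$components$mean[1L]
          else fit$modes$location[which.max(fit$modes$density)]
  list(events = ev, fit = fit, modes = modes, peak = peak, truth = sim$truth,
       sigma = det$sigma, feature = feature)
}

#' Two-analyte classification experiment
#'
#' Generates a balanced labelled event set from two library models on the
#' same device context, encodes it, splits it 70/15/15 stratified, trains
#' the requested classifier, and evaluates it on the held-out test set.
#'
#' @param library A [signal_library].
#' @param analytes Data frame (`label`, `device`), one class per row.
#' @param n_per_class Events per class.
#' @param classifier `"bayes"` or `"lstm"`.
#' @param L Encoded waveform length.
#' @param seed RNG seed (event generation and split; the LSTM additionally
#'   uses its config seed).
#' @param lstm_config Optional [sequence_classifier_config()].
#' @param noise_rms Post-filter noise RMS, nA.
#' @return A list: `report` (a `classifier_report` on the test set),
#'   `model`, `split`, `event_set`.
#' @export
classification_experiment <- function(library, analytes, n_per_class = 2000L,
                                      classifier = c("bayes", "lstm"),
                                      L = 128L, seed = 1L, lstm_config = NULL,
                                      noise_rms = 0.01) {
  classifier <- match.arg(classifier)
  es <- simulate_event_set(library, analytes, n_per_class = n_per_class,
                           noise_rms = noise_rms, seed = seed)
  enc <- encode_event_set(es, L = L)
  split <- split_dataset(enc, seed = seed + 1L)
  model <- if (classifier == "bayes") {
    train_bayes_baseline(split$train)
  } else {
    cfg <- if (is.null(lstm_config)) sequence_classifier_config(seed = seed + 2L)
           else lstm_config
    train_sequence_classifier(split$train, split$validation, cfg)
  }
  pred <- classify(model, split$test)
  list(report = evaluate_classifier(pred$labels, split$test$labels),
       model = model, split = split, event_set = es)
}
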