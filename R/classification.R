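#' Encode detected events for classification
#'
#' Each event waveform is linearly resampled to `L` points over the window
#' `[start - 0.2 dwell, end + 0.2 dwell]` (20% baseline context on each
#' side), divided by its local open-pore current so that 1 means open pore
#' and 0 a full blockade, and clipped to [-0.2, 1.2]. Two scalar features,
#' the relative blockade and log10 dwell, ride along; encoding is therefore
#' invariant to the absolute baseline level.
#'
#' @param trace The filtered [trace_recording] the events were detected in.
#' @param events Event data frame ([detect_events()] output), optionally
#'   with a `label` column.
#' @param L Encoded waveform length (points).
#' @return An `encoded_events` object: `X` (n x L waveform matrix),
#'   `features` (n x 2 matrix: `rel_blockade`, `log10_dwell`), `labels`
#'   (factor or NULL), `L`.
#' @export
encode_events <- function(trace, events, L = 128L) {
  stopifnot(inherits(trace, "trace_recording"), is.data.frame(events))
  n <- nrow(events)
  x <- trace$samples
  X <- matrix(NA_real_, n, L)
  for (i in seq_len(n)) {
    s <- events$start_index[i] + 1L
    e <- events$end_index[i]
    len <- e - s + 1L
    ctx <- max(1L, round(0.2 * len))
    lo <- max(1L, s - ctx); hi <- min(length(x), e + ctx)
    X[i, ] <- encode_snippet(x[lo:hi], events$I0_nA[i], L)
  }
  new_encoded_events(X, events, L)
}

encode_snippet <- function(w, I0, L) {
  v <- if (length(w) == 1L) rep(w, L)
       else stats::approx(seq_along(w), w, xout = seq(1, length(w), length.out = L))$y
  pmin(pmax(v / I0, -0.2), 1.2)
}

new_encoded_events <- function(X, events, L) {
  labels <- if (!is.null(events$label)) factor(events$label) else NULL
  structure(list(X = X,
                 features = cbind(rel_blockade = events$rel_blockade,
                                  log10_dwell = log10(events$dwell_s)),
                 labels = labels, L = as.integer(L)),
            class = "encoded_events")
}

#' @export
print.encoded_events <- function(x, ...) {
  cat(sprintf("<encoded_events> n = %d, L = %d%s\n", nrow(x$X), x$L,
              if (is.null(x$labels)) "" else
                paste0(", classes: ", paste(levels(x$labels), collapse = "/"))))
  invisible(x)
}

subset_encoded <- function(enc, idx) {
  structure(list(X = enc$X[idx, , drop = FALSE],
                 features = enc$features[idx, , drop = FALSE],
                 labels = if (is.null(enc$labels)) NULL else droplevels(enc$labels[idx]),
                 L = enc$L),
            class = "encoded_events")
}

#' Stratified train/validation/test split
#'
#' Splits labelled encoded events class by class into disjoint train,
#' validation, and test subsets; reproducible under a fixed seed.
#'
#' @param encoded An `encoded_events` object with labels.
#' @param fractions Length-3 numeric summing to 1.
#' @param seed RNG seed.
#' @param min_per_class Error if any class has fewer events.
#' @return List of `encoded_events`: `train`, `validation`, `test`.
#' @export
split_dataset <- function(encoded, fractions = c(0.7, 0.15, 0.15), seed = 1L,
                          min_per_class = 20L) {
  stopifnot(inherits(encoded, "encoded_events"), !is.null(encoded$labels),
            length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9)
  tab <- table(encoded$labels)
  small <- names(tab)[tab < min_per_class]
  if (length(small)) stop("classes below minimum size: ", paste(small, collapse = ", "))
  set.seed(seed)
  idx_tr <- idx_va <- idx_te <- integer(0)
  for (cl in levels(encoded$labels)) {
    idx <- sample(which(encoded$labels == cl))
    n <- length(idx)
    n_tr <- round(fractions[1] * n)
    n_va <- round(fractions[2] * n)
    idx_tr <- c(idx_tr, idx[seq_len(n_tr)])
    idx_va <- c(idx_va, idx[n_tr + seq_len(n_va)])
    idx_te <- c(idx_te, idx[(n_tr + n_va + 1L):n])
  }
  list(train = subset_encoded(encoded, sort(idx_tr)),
       validation = subset_encoded(encoded, sort(idx_va)),
       test = subset_encoded(encoded, sort(idx_te)))
}

# Class-conditional density of one feature: Gaussian, or a two-component
# mixture when the class is visibly bimodal (BIC-preferred at n >= 200).
fit_feature_density <- function(x, allow_mixture = TRUE) {
  g1 <- list(k = 1L, weight = 1, mean = mean(x), sd = stats::sd(x))
  if (g1$sd == 0) g1$sd <- 1e-6
  if (!allow_mixture || length(x) < 200L) return(g1)
  bic1 <- 2 * log(length(x)) - 2 * sum(stats::dnorm(x, g1$mean, g1$sd, log = TRUE))
  fit2 <- tryCatch(fit_gaussian_mixture(x, k = 2L, restarts = 5L), error = function(e) NULL)
  if (is.null(fit2) || fit2$bic >= bic1) return(g1)
  list(k = 2L, weight = fit2$components$weight, mean = fit2$components$mean,
       sd = fit2$components$sd)
}

feature_logdens <- function(fd, x) {
  d <- 0
  for (j in seq_len(fd$k)) d <- d + fd$weight[j] * stats::dnorm(x, fd$mean[j], fd$sd[j])
  log(pmax(d, 1e-300))
}

#' Gaussian-Bayes baseline classifier
#'
#' Transparent reference classifier on the two scalar features: per class,
#' an independent Gaussian (or, where the blockade population is bimodal
#' and BIC prefers it, a two-component Gaussian mixture) on the relative
#' blockade and a Gaussian on log10 dwell; decisions are maximum posterior
#' with equal class priors. Because the generative model writes all class
#' information into these two features, this baseline operates close to the
#' Bayes optimum on synthetic data and anchors the sequence classifier.
#'
#' @param train An `encoded_events` object with >= 2 classes.
#' @return A `bayes_classifier` model.
#' @export
train_bayes_baseline <- function(train) {
  stopifnot(inherits(train, "encoded_events"), !is.null(train$labels))
  classes <- levels(train$labels)
  if (length(classes) < 2L) stop("need at least 2 classes")
  dens <- lapply(classes, function(cl) {
    i <- train$labels == cl
    list(blockade = fit_feature_density(train$features[i, 1L]),
         dwell = fit_feature_density(train$features[i, 2L], allow_mixture = FALSE))
  })
  names(dens) <- classes
  structure(list(classes = classes, densities = dens), class = "bayes_classifier")
}

#' Classify encoded events
#'
#' Returns the per-class posterior probabilities (rows sum to 1) and the
#' argmax label; ties break towards the earlier class in the model's class
#' order.
#'
#' @param model A trained `bayes_classifier` or `lstm_classifier`.
#' @param encoded `encoded_events` to classify.
#' @return List: `labels` (factor), `prob` (n x classes matrix).
#' @export
classify <- function(model, encoded) UseMethod("classify")

#' @export
classify.bayes_classifier <- function(model, encoded) {
  stopifnot(inherits(encoded, "encoded_events"))
  n <- nrow(encoded$X)
  if (n == 0L) return(empty_prediction(model$classes))
  ll <- vapply(model$classes, function(cl) {
    fd <- model$densities[[cl]]
    feature_logdens(fd$blockade, encoded$features[, 1L]) +
      feature_logdens(fd$dwell, encoded$features[, 2L])
  }, numeric(n))
  ll <- matrix(ll, nrow = n)
  finish_prediction(ll, model$classes)
}

empty_prediction <- function(classes) {
  list(labels = factor(character(0), levels = classes),
       prob = matrix(numeric(0), 0L, length(classes),
                     dimnames = list(NULL, classes)))
}

finish_prediction <- function(logits, classes) {
  m <- apply(logits, 1L, max)
  p <- exp(logits - m)
  p <- p / rowSums(p)
  colnames(p) <- classes
  pick <- apply(p, 1L, which.max)  # which.max breaks ties towards class order
  list(labels = factor(classes[pick], levels = classes), prob = p)
}

#' Confusion-matrix evaluation
#'
#' Confusion matrix (true x predicted), per-class precision/recall/F1, and
#' average accuracy. F1 is defined as 0 where precision + recall is 0.
#'
#' @param predicted Factor/character of predicted labels.
#' @param truth Factor/character of true labels, same length; every truth
#'   label must be known to the prediction's level set.
#' @return A `classifier_report`: `confusion`, `per_class` (data frame),
#'   `average_accuracy`, `n`.
#' @export
evaluate_classifier <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  classes <- if (is.factor(predicted)) levels(predicted) else sort(unique(as.character(predicted)))
  if (any(!as.character(truth) %in% classes))
    stop("truth contains labels unknown to the classifier: ",
         paste(setdiff(unique(as.character(truth)), classes), collapse = ", "))
  truth <- factor(as.character(truth), levels = classes)
  predicted <- factor(as.character(predicted), levels = classes)
  conf <- table(truth = truth, predicted = predicted)
  tp <- diag(conf)
  prec <- ifelse(colSums(conf) > 0, tp / colSums(conf), 0)
  rec <- ifelse(rowSums(conf) > 0, tp / rowSums(conf), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(confusion = conf,
                 per_class = data.frame(class = classes, precision = as.numeric(prec),
                                        recall = as.numeric(rec), f1 = as.numeric(f1)),
                 average_accuracy = sum(tp) / length(truth),
                 n = length(truth)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> accuracy %.2f%% on %d events\n",
              100 * x$average_accuracy, x$n))
  print(x$confusion)
  print(x$per_class, digits = 3)
  invisible(x)
}

#' Analytic Bayes accuracy for two unimodal signal models
#'
#' Numerically integrates the two blockade densities to obtain the best
#' achievable two-class accuracy from the relative blockade alone (equal
#' priors). Used as a quadrature oracle for classifier sanity checks.
#'
#' @param model_a,model_b [aa_signal_model]s in the same units.
#' @return Bayes accuracy in [0.5, 1].
#' @export
bayes_accuracy_two_class <- function(model_a, model_b) {
  lo <- min(model_a$mean - 8 * max(model_a$sd), model_b$mean - 8 * max(model_b$sd))
  hi <- max(model_a$mean + 8 * max(model_a$sd), model_b$mean + 8 * max(model_b$sd))
  x <- seq(lo, hi, length.out = 20001L)
  fa <- blockade_density(model_a, x); fb <- blockade_density(model_b, x)
  # accuracy = 0.5 * integral of max(fa, fb)
  0.5 * sum(pmax(fa, fb)) * (x[2] - x[1])
}
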