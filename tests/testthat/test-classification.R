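make_rect_trace <- function(I0, depth, len = 200L, ctx = 100L, fs = 1e5) {
  x <- rep(I0, ctx + len + ctx)
  x[(ctx + 1L):(ctx + len)] <- I0 - depth
  list(trace = trace_recording(x, fs),
       events = data.frame(start_index = ctx, end_index = ctx + len,
                           start_s = ctx / fs, dwell_s = len / fs,
                           I0_nA = I0, dI_nA = depth,
                           rel_blockade = depth / I0))
}

test_that("event encoding is normalized, clipped, and baseline invariant", {
  r <- make_rect_trace(I0 = 1, depth = 0.3)
  enc <- encode_events(r$trace, r$events, L = 64)
  # plateau of a depth-0.3 relative event sits at 0.7
  expect_equal(median(enc$X[1, ]), 0.7, tolerance = 1e-6)
  expect_true(all(enc$X >= -0.2 & enc$X <= 1.2))
  expect_equal(enc$features[1, "rel_blockade"], 0.3, ignore_attr = TRUE)

  r5 <- make_rect_trace(I0 = 5, depth = 1.5)  # proportional blockade
  enc5 <- encode_events(r5$trace, r5$events, L = 64)
  expect_equal(enc$X, enc5$X, tolerance = 1e-12)
})

test_that("stratified splitting is exact, disjoint, and reproducible", {
  set.seed(20)
  n <- 100
  ev <- data.frame(label = rep(c("a", "b"), each = n),
                   dwell_s = rlnorm(2 * n, log(5e-4), 0.6),
                   I0_nA = 3, dI_nA = 0.3, rel_blockade = rnorm(2 * n, 0.2, 0.02))
  enc <- porecall:::new_encoded_events(matrix(0, 2 * n, 8), ev, 8L)
  sp <- split_dataset(enc, seed = 1)
  expect_equal(as.numeric(table(sp$train$labels)), c(70, 70))
  expect_equal(nrow(sp$validation$X), 30)
  expect_equal(nrow(sp$test$X), 30)
  expect_equal(nrow(sp$train$X) + nrow(sp$validation$X) + nrow(sp$test$X), 2 * n)
  sp2 <- split_dataset(enc, seed = 1)
  expect_identical(sp$train$features, sp2$train$features)
  expect_error(split_dataset(enc, min_per_class = 200), "below minimum")
})

test_that("Bayes baseline separates distant classes and tracks the quadrature optimum", {
  lib <- toy_library()
  sep <- classification_experiment(lib,
    data.frame(label = c("shallow", "deep"), device = "toy"),
    n_per_class = 150, classifier = "bayes", seed = 30)
  expect_gte(sep$report$average_accuracy, 0.999)

  run <- classification_run("G", "A", "Device #4")
  acc <- run$report$average_accuracy
  cap <- published_library()
  bayes_opt <- bayes_accuracy_two_class(get_signal_model(cap, "G", "Device #4"),
                                        get_signal_model(cap, "A", "Device #4"))
  expect_lt(abs(acc - bayes_opt), 0.03)

  one <- porecall:::new_encoded_events(matrix(0, 30, 8),
    data.frame(label = rep("a", 30), dwell_s = 5e-4, I0_nA = 3,
               dI_nA = 0.3, rel_blockade = 0.1), 8L)
  expect_error(train_bayes_baseline(one), "at least 2 classes")
})

test_that("classifier probabilities are proper and training beats held-out", {
  run <- classification_run("G", "A", "Device #4")
  pred <- classify(run$model, run$split$test)
  expect_equal(rowSums(pred$prob), rep(1, nrow(pred$prob)), tolerance = 1e-6)
  tr_acc <- evaluate_classifier(classify(run$model, run$split$train)$labels,
                                run$split$train$labels)$average_accuracy
  expect_gte(tr_acc, run$report$average_accuracy - 0.02)
  empty <- porecall:::subset_encoded(run$split$test, integer(0))
  expect_equal(length(classify(run$model, empty)$labels), 0)
})

test_that("confusion-matrix metrics match hand-computed values", {
  perfect <- evaluate_classifier(factor(c("a", "b")), factor(c("a", "b")))
  expect_equal(perfect$average_accuracy, 1)
  expect_true(all(perfect$per_class$f1 == 1))

  onesided <- evaluate_classifier(factor(rep("a", 10), levels = c("a", "b")),
                                  factor(rep(c("a", "b"), each = 5)))
  expect_equal(onesided$average_accuracy, 0.5)
  expect_equal(onesided$per_class$recall, c(1, 0))

  pred <- factor(rep(c("x", "y", "z"), c(12, 10, 10))[c(1:32)])
  truth <- factor(c(rep(c("x", "y", "z"), c(10, 2, 0)),
                    rep(c("x", "y", "z"), c(1, 8, 1)),
                    rep(c("x", "y", "z"), c(0, 3, 7))))
  # reorder so the confusion matrix is truth 10/2/0, 1/8/1, 0/3/7
  pred <- factor(c(rep("x", 10), rep("y", 2),
                   rep("x", 1), rep("y", 8), rep("z", 1),
                   rep("y", 3), rep("z", 7)), levels = c("x", "y", "z"))
  truth <- factor(rep(c("x", "y", "z"), c(12, 10, 10)), levels = c("x", "y", "z"))
  rep3 <- evaluate_classifier(pred, truth)
  expect_equal(rep3$average_accuracy, 25 / 32)
  expect_equal(rep3$per_class$precision, c(10 / 11, 8 / 13, 7 / 8))
  expect_equal(rep3$per_class$recall, c(10 / 12, 8 / 10, 7 / 10))
  expect_equal(rep3$per_class$f1,
               2 * rep3$per_class$precision * rep3$per_class$recall /
                 (rep3$per_class$precision + rep3$per_class$recall))
  expect_equal(sum(rep3$confusion), rep3$n)

  expect_error(evaluate_classifier(factor(c("a", "b")), factor(c("a", "c"))),
               "unknown")
})

small_lstm_cfg <- function(seed = 1) {
  sequence_classifier_config(lstm_hidden = 12, fc_widths = c(16, 12, 8, 6),
                             epochs = 30, batch_size = 32, learning_rate = 5e-3,
                             patience = 8, seed = seed)
}

test_that("LSTM classifier learns separable classes and matches the Bayes baseline", {
  lib <- toy_library()
  run <- classification_experiment(lib,
    data.frame(label = c("shallow", "deep"), device = "toy"),
    n_per_class = 150, classifier = "lstm", L = 32, seed = 31,
    lstm_config = small_lstm_cfg(31))
  expect_gte(run$report$average_accuracy, 0.99)

  bayes <- classification_experiment(lib,
    data.frame(label = c("shallow", "deep"), device = "toy"),
    n_per_class = 150, classifier = "bayes", seed = 31)
  expect_lt(abs(run$report$average_accuracy - bayes$report$average_accuracy), 0.05)
  expect_equal(sum(run$report$confusion), nrow(run$split$test$X))
})

test_that("label-shuffled training collapses the LSTM to chance accuracy", {
  lib <- toy_library()
  es <- simulate_event_set(lib, data.frame(label = c("shallow", "deep"),
                                           device = "toy"),
                           n_per_class = 120, seed = 32)
  enc <- encode_event_set(es, L = 32)
  set.seed(33)
  enc$labels <- sample(enc$labels)
  sp <- split_dataset(enc, seed = 34)
  model <- train_sequence_classifier(sp$train, sp$validation, small_lstm_cfg(35))
  acc <- evaluate_classifier(classify(model, sp$test)$labels,
                             sp$test$labels)$average_accuracy
  expect_lt(abs(acc - 0.5), 0.15)
})

test_that("LSTM training is deterministic under a fixed seed and checks lengths", {
  lib <- toy_library()
  es <- simulate_event_set(lib, data.frame(label = c("shallow", "deep"),
                                           device = "toy"),
                           n_per_class = 60, seed = 36)
  enc <- encode_event_set(es, L = 32)
  sp <- split_dataset(enc, seed = 37, min_per_class = 20)
  cfg <- small_lstm_cfg(38); cfg$epochs <- 5L
  m1 <- train_sequence_classifier(sp$train, sp$validation, cfg)
  m2 <- train_sequence_classifier(sp$train, sp$validation, cfg)
  expect_identical(classify(m1, sp$test)$labels, classify(m2, sp$test)$labels)
  bad <- encode_event_set(es, L = 16)
  expect_error(classify(m1, bad), "does not match")
})
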