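# LSTM sequence classifier over encoded event waveforms.
#
# Architecture: single-layer LSTM over the L-point normalized waveform,
# mean-over-time pooling of the hidden states, concatenation of the two
# scalar features, four fully connected ReLU layers, and a softmax output.
# Written directly in base-R matrix operations (batched BPTT + Adam); the
# network is small enough that BLAS-backed matrix products train it in
# seconds to minutes on one CPU core.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Sequence-classifier configuration
#'
#' @param lstm_hidden LSTM hidden width.
#' @param fc_widths Widths of the four fully connected layers.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param patience Early-stopping patience (epochs without validation
#'   accuracy improvement).
#' @param seed RNG seed for initialisation and batch shuffling.
#' @return A `sequence_classifier_config` list.
#' @export
sequence_classifier_config <- function(lstm_hidden = 64L,
                                       fc_widths = c(64L, 32L, 16L, 8L),
                                       epochs = 100L, batch_size = 64L,
                                       learning_rate = 1e-3, patience = 10L,
                                       seed = 1L) {
  stopifnot(length(fc_widths) == 4L, lstm_hidden >= 1L, epochs >= 1L)
  structure(list(lstm_hidden = as.integer(lstm_hidden),
                 fc_widths = as.integer(fc_widths),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "sequence_classifier_config")
}

init_lstm_params <- function(H, fc_widths, n_classes) {
  glorot <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
  b <- rep(0, 4 * H)
  b[(H + 1L):(2L * H)] <- 1  # forget-gate bias starts open
  p <- list(W = glorot(4L * H, 1L + H), b = b)
  dims <- c(H + 2L, fc_widths, n_classes)
  for (k in seq_len(length(dims) - 1L)) {
    p[[paste0("Wf", k)]] <- glorot(dims[k], dims[k + 1L])
    p[[paste0("bf", k)]] <- rep(0, dims[k + 1L])
  }
  p
}

# Forward pass over a batch. X: B x L waveforms, S: B x 2 standardized
# scalar features. Returns logits and (optionally) the cache for BPTT.
lstm_forward <- function(p, X, S, H, keep_cache = FALSE) {
  B <- nrow(X); L <- ncol(X)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  pool <- matrix(0, B, H)
  cache <- if (keep_cache) vector("list", L) else NULL
  Wt <- t(p$W)
  for (t in seq_len(L)) {
    inp <- cbind(X[, t], h)
    a <- inp %*% Wt + matrix(p$b, B, 4L * H, byrow = TRUE)
    i <- sigmoid(a[, 1:H, drop = FALSE])
    f <- sigmoid(a[, (H + 1L):(2L * H), drop = FALSE])
    o <- sigmoid(a[, (2L * H + 1L):(3L * H), drop = FALSE])
    g <- tanh(a[, (3L * H + 1L):(4L * H), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    if (keep_cache)
      cache[[t]] <- list(x = X[, t], h_prev = h, c_prev = cc,
                         i = i, f = f, o = o, g = g, tc = tc)
    h <- h_new; cc <- c_new
    pool <- pool + h
  }
  pool <- pool / L
  z <- cbind(pool, S)
  acts <- list(z)
  nfc <- 5L
  for (k in seq_len(nfc)) {
    z <- z %*% p[[paste0("Wf", k)]] + matrix(p[[paste0("bf", k)]], nrow(z),
                                             length(p[[paste0("bf", k)]]), byrow = TRUE)
    if (k < nfc) z <- pmax(z, 0)
    acts[[k + 1L]] <- z
  }
  list(logits = z, acts = acts, cache = cache, pool = pool)
}

lstm_backward <- function(p, fwd, X, S, Y, H) {
  B <- nrow(X); L <- ncol(X)
  prob <- exp(fwd$logits - apply(fwd$logits, 1L, max))
  prob <- prob / rowSums(prob)
  grads <- list()
  dz <- (prob - Y) / B
  nfc <- 5L
  for (k in nfc:1) {
    a_in <- fwd$acts[[k]]
    grads[[paste0("Wf", k)]] <- t(a_in) %*% dz
    grads[[paste0("bf", k)]] <- colSums(dz)
    dz <- dz %*% t(p[[paste0("Wf", k)]])
    if (k > 1L) dz <- dz * (fwd$acts[[k]] > 0)
  }
  dpool <- dz[, 1:H, drop = FALSE] / L
  dW <- matrix(0, 4L * H, 1L + H); db <- rep(0, 4L * H)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  Wh <- p$W[, -1L, drop = FALSE]  # 4H x H block acting on h_prev
  for (t in L:1) {
    cc <- fwd$cache[[t]]
    dh <- dpool + dh_next
    do <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    da <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                do * cc$o * (1 - cc$o), dg * (1 - cc$g^2))
    inp <- cbind(cc$x, cc$h_prev)
    dW <- dW + t(da) %*% inp
    db <- db + colSums(da)
    dh_next <- da %*% Wh
    dc_next <- dc * cc$f
  }
  grads$W <- dW; grads$b <- db
  list(grads = grads,
       loss = -mean(log(pmax(rowSums(prob * Y), 1e-300))))
}

adam_step <- function(p, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^t)
    vh <- state$v[[nm]] / (1 - beta2^t)
    p[[nm]] <- p[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(p = p, state = state)
}

std_features <- function(S, center, scale) {
  sweep(sweep(S, 2L, center), 2L, scale, "/")
}

#' Train the LSTM sequence classifier
#'
#' Trains the LSTM / pooling / four-FC-layer / softmax network on encoded
#' events by cross-entropy with Adam, early-stopping on validation
#' accuracy. Scalar features are standardized using training-set moments
#' and appended to the pooled LSTM representation before the fully
#' connected stack, so the network sees both the raw waveform and the
#' extracted features.
#'
#' @param train,validation Labelled `encoded_events` objects sharing a
#'   class set.
#' @param config A [sequence_classifier_config()].
#' @return An `lstm_classifier` model (parameters, class list, config,
#'   feature standardisation, training history).
#' @export
train_sequence_classifier <- function(train, validation,
                                      config = sequence_classifier_config()) {
  stopifnot(inherits(train, "encoded_events"), !is.null(train$labels),
            inherits(validation, "encoded_events"), !is.null(validation$labels))
  classes <- levels(train$labels)
  if (length(classes) < 2L) stop("need at least 2 classes")
  if (!identical(levels(validation$labels), classes))
    stop("train and validation class sets differ")
  set.seed(config$seed)
  H <- config$lstm_hidden
  p <- init_lstm_params(H, config$fc_widths, length(classes))
  state <- list(m = lapply(p, function(z) z * 0), v = lapply(p, function(z) z * 0))
  ctr <- colMeans(train$features)
  scl <- pmax(apply(train$features, 2L, stats::sd), 1e-8)
  Str <- std_features(train$features, ctr, scl)
  Sva <- std_features(validation$features, ctr, scl)
  n <- nrow(train$X)
  Ytr <- 1 * (matrix(as.character(train$labels), n, length(classes)) ==
                matrix(classes, n, length(classes), byrow = TRUE))
  best <- list(acc = -Inf, p = p, epoch = 0L)
  wait <- 0L; step <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0), val_acc = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      fwd <- lstm_forward(p, train$X[idx, , drop = FALSE], Str[idx, , drop = FALSE],
                          H, keep_cache = TRUE)
      bwd <- lstm_backward(p, fwd, train$X[idx, , drop = FALSE],
                           Str[idx, , drop = FALSE], Ytr[idx, , drop = FALSE], H)
      if (!is.finite(bwd$loss))
        stop(sprintf("non-finite loss at epoch %d (lr %.2g); training aborted",
                     epoch, config$learning_rate))
      step <- step + 1L
      upd <- adam_step(p, bwd$grads, state, config$learning_rate, step)
      p <- upd$p; state <- upd$state
      losses <- c(losses, bwd$loss)
    }
    val_logits <- lstm_forward(p, validation$X, Sva, H)$logits
    val_pred <- classes[apply(val_logits, 1L, which.max)]
    val_acc <- mean(val_pred == as.character(validation$labels))
    history <- rbind(history, data.frame(epoch = epoch, loss = mean(losses),
                                         val_acc = val_acc))
    if (val_acc > best$acc + 1e-9) {
      best <- list(acc = val_acc, p = p, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  structure(list(params = best$p, classes = classes, config = config,
                 feature_center = ctr, feature_scale = scl,
                 L = train$L, history = history,
                 best_val_acc = best$acc, best_epoch = best$epoch),
            class = "lstm_classifier")
}

#' @export
classify.lstm_classifier <- function(model, encoded) {
  stopifnot(inherits(encoded, "encoded_events"))
  if (nrow(encoded$X) == 0L) return(empty_prediction(model$classes))
  if (ncol(encoded$X) != model$L)
    stop(sprintf("encoding length %d does not match the model's %d",
                 ncol(encoded$X), model$L))
  S <- std_features(encoded$features, model$feature_center, model$feature_scale)
  logits <- lstm_forward(model$params, encoded$X, S, model$config$lstm_hidden)$logits
  finish_prediction(logits, model$classes)
}

#' @export
print.lstm_classifier <- function(x, ...) {
  cat(sprintf("<lstm_classifier> H = %d, classes %s; best val acc %.2f%% (epoch %d)\n",
              x$config$lstm_hidden, paste(x$classes, collapse = "/"),
              100 * x$best_val_acc, x$best_epoch))
  invisible(x)
}
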