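#' Kernel-density fit with mode calling
#'
#' Gaussian-kernel density estimate of a scalar blockade feature with the
#' bandwidth defaulting to Silverman's rule, plus located modes. Mode
#' locations are grid argmaxima refined by a parabolic fit through the
#' three neighbouring grid points; modes are ranked by density and reported
#' sorted by location.
#'
#' @param values Numeric sample (n >= 30).
#' @param bandwidth Optional kernel bandwidth (same units as `values`);
#'   default `stats::bw.nrd0` (Silverman).
#' @param n_grid Grid resolution.
#' @param min_rel_density Modes below this fraction of the global maximum
#'   density are suppressed (noise shoulders).
#' @return An object of class `density_fit`: `grid`, `density`,
#'   `bandwidth`, `modes` (data frame `location`, `density`, sorted by
#'   location), `method = "kde_normal"`, `n`.
#' @export
kde_fit <- function(values, bandwidth = NULL, n_grid = 2048L, min_rel_density = 0.1) {
  values <- values[is.finite(values)]
  if (length(values) < 30L) stop("kde_fit needs at least 30 values")
  bw <- if (is.null(bandwidth)) stats::bw.nrd0(values) else bandwidth
  d <- stats::density(values, bw = bw, kernel = "gaussian", n = n_grid)
  y <- d$y; x <- d$x
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  is_max <- is_max[y[is_max] >= min_rel_density * max(y)]
  if (length(is_max) == 0L) is_max <- which.max(y)
  loc <- vapply(is_max, function(i) {
    if (i <= 1L || i >= length(y)) return(x[i])
    # parabola through (x[i-1..i+1], y[i-1..i+1]); vertex offset in grid units
    denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
    if (denom >= 0) return(x[i])
    x[i] + 0.5 * (y[i - 1L] - y[i + 1L]) / denom * (x[i] - x[i - 1L])
  }, numeric(1))
  modes <- data.frame(location = loc, density = y[is_max])
  modes <- modes[order(-modes$density, modes$location), , drop = FALSE]
  modes <- modes[order(modes$location), , drop = FALSE]
  rownames(modes) <- NULL
  structure(list(grid = x, density = y, bandwidth = bw, modes = modes,
                 method = "kde_normal", components = NULL, n = length(values)),
            class = "density_fit")
}

#' @export
print.density_fit <- function(x, ...) {
  cat(sprintf("<density_fit> %s, n = %d\n", x$method, x$n))
  if (!is.null(x$modes)) {
    cat("modes:\n"); print(x$modes)
  }
  if (!is.null(x$components)) {
    cat("components:\n"); print(x$components)
  }
  invisible(x)
}

#' Primary mode of a sample
#'
#' Convenience wrapper: the highest-density KDE mode location.
#'
#' @inheritParams kde_fit
#' @return Scalar mode location.
#' @export
kde_mode <- function(values, bandwidth = NULL) {
  f <- kde_fit(values, bandwidth)
  f$modes$location[which.max(f$modes$density)]
}

# One EM run for a k-component univariate Gaussian mixture.
em_gauss_once <- function(x, k, w, mu, s2, max_iter = 500L, tol = 1e-8) {
  n <- length(x)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j)
      log(w[j]) + stats::dnorm(x, mu[j], sqrt(s2[j]), log = TRUE), numeric(n))
    m <- apply(logd, 1L, max)
    p <- exp(logd - m)
    rs <- rowSums(p)
    ll <- sum(m + log(rs))
    g <- p / rs
    nk <- colSums(g)
    if (any(nk < 1e-8)) return(NULL)   # empty component
    w <- nk / n
    mu <- colSums(g * x) / nk
    s2 <- colSums(g * (x - rep(mu, each = n))^2) / nk
    if (any(s2 < 1e-12)) return(NULL)  # degenerate component
    if (is.finite(ll_old) && ll - ll_old < tol * abs(ll)) break
    ll_old <- ll
  }
  list(weight = w, mean = mu, sd = sqrt(s2), loglik = ll, iter = iter)
}

#' Gaussian-mixture fit by expectation-maximisation
#'
#' Fits a k-component univariate Gaussian mixture, taking the best of
#' `restarts` random initialisations by log-likelihood. Initial means are
#' drawn from the sample quantiles with jitter; runs that collapse a
#' component (weight or variance to zero) are discarded and re-drawn.
#' Components are reported sorted by mean.
#'
#' @param values Numeric sample (n >= 50).
#' @param k Number of components.
#' @param restarts Number of EM restarts.
#' @param seed Optional RNG seed for the restart draws.
#' @return A `density_fit` with `method = "gaussian_mixture"`,
#'   `components` (data frame `weight`, `mean`, `sd`), `loglik`, `bic`.
#' @export
fit_gaussian_mixture <- function(values, k = 2L, restarts = 10L, seed = NULL) {
  x <- values[is.finite(values)]
  if (length(x) < 50L) stop("fit_gaussian_mixture needs at least 50 values")
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  best <- NULL
  tries <- 0L
  while (tries < restarts * 3L && (is.null(best) || tries < restarts)) {
    tries <- tries + 1L
    q <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
    mu0 <- q + stats::rnorm(k, 0, stats::sd(x) / 4)
    fit <- em_gauss_once(x, k, w = rep(1 / k, k), mu = mu0,
                         s2 = rep(stats::var(x) / k^2, k))
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("EM failed to converge without degenerate components")
  ord <- order(best$mean)
  comp <- data.frame(weight = best$weight[ord], mean = best$mean[ord],
                     sd = best$sd[ord])
  npar <- 3L * k - 1L
  grid <- seq(min(x), max(x), length.out = 1024L)
  dens <- rowSums(vapply(seq_len(k), function(j)
    comp$weight[j] * stats::dnorm(grid, comp$mean[j], comp$sd[j]),
    numeric(length(grid))))
  structure(list(grid = grid, density = dens, bandwidth = NA_real_,
                 modes = data.frame(location = comp$mean,
                                    density = blockade_mix_density(comp, comp$mean)),
                 method = "gaussian_mixture", components = comp,
                 loglik = best$loglik, bic = npar * log(n) - 2 * best$loglik,
                 n = n),
            class = "density_fit")
}

blockade_mix_density <- function(comp, x) {
  m <- vapply(seq_len(nrow(comp)), function(j)
    comp$weight[j] * stats::dnorm(x, comp$mean[j], comp$sd[j]),
    numeric(length(x)))
  rowSums(matrix(m, nrow = length(x)))
}

#' Two-sample z-test on blockade populations
#'
#' Unequal-variance (Welch-style) z statistic
#' \eqn{z = (\bar a - \bar b) / \sqrt{s_a^2/n_1 + s_b^2/n_2}} with a
#' two-sided p-value from the standard normal. Used to confirm that two
#' analytes' blockade populations are statistically separated.
#'
#' @param a,b Numeric samples, each of size >= 30.
#' @return A list of class `ztest_result`: `statistic`, `p_value`, `n1`,
#'   `n2`.
#' @export
two_sample_ztest <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 30L || length(b) < 30L) stop("z-test needs n >= 30 per sample")
  va <- stats::var(a); vb <- stats::var(b)
  se <- sqrt(va / length(a) + vb / length(b))
  if (se == 0) stop("both samples have zero variance")
  z <- (mean(a) - mean(b)) / se
  structure(list(statistic = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 n1 = length(a), n2 = length(b)),
            class = "ztest_result")
}

#' @export
print.ztest_result <- function(x, ...) {
  cat(sprintf("<ztest> z = %.3f, p = %.3g (n1 = %d, n2 = %d)\n",
              x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Dwell-time versus blockade heatmap
#'
#' 2-D histogram of events over dwell time and blockade (relative by
#' default), the standard scatter summary of a nanopore measurement. The
#' dwell axis can be binned on a log scale.
#'
#' @param events Event data frame with `dwell_s` and the blockade column.
#' @param blockade_col `"rel_blockade"` or `"dI_nA"`.
#' @param n_bins Bins per axis (length-2 vector or scalar).
#' @param log_dwell Bin dwell on log10 scale (default TRUE).
#' @return A list of class `dwell_heatmap`: `counts` (matrix, dwell bins x
#'   blockade bins), `dwell_breaks`, `blockade_breaks`, `log_dwell`,
#'   `blockade_col`. `sum(counts)` equals the number of events.
#' @export
dwell_blockade_heatmap <- function(events, blockade_col = "rel_blockade",
                                   n_bins = c(40L, 40L), log_dwell = TRUE) {
  stopifnot(is.data.frame(events), nrow(events) >= 1L,
            blockade_col %in% names(events))
  if (length(n_bins) == 1L) n_bins <- rep(n_bins, 2L)
  dw <- if (log_dwell) log10(events$dwell_s) else events$dwell_s
  bl <- events[[blockade_col]]
  pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r + diff(r) * c(-1e-9, 1e-9)
  db <- seq(pad(range(dw))[1], pad(range(dw))[2], length.out = n_bins[1] + 1L)
  bb <- seq(pad(range(bl))[1], pad(range(bl))[2], length.out = n_bins[2] + 1L)
  counts <- table(cut(dw, db, include.lowest = TRUE),
                  cut(bl, bb, include.lowest = TRUE))
  structure(list(counts = matrix(as.integer(counts), n_bins[1], n_bins[2]),
                 dwell_breaks = db, blockade_breaks = bb,
                 log_dwell = log_dwell, blockade_col = blockade_col),
            class = "dwell_heatmap")
}
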