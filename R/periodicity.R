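#' Periodogram at Fourier frequencies
#'
#' For an evenly sampled series of N+1 points y_0 .. y_N, the periodogram
#' \deqn{I(\omega) = \frac{1}{N}\left|\sum_{j=0}^{N} e^{-i\omega j} y_j\right|^2}
#' evaluated at the Fourier frequencies \eqn{\omega_k = 2\pi k / N},
#' k = 1 .. q with q = floor((N-1)/2). Note the frequency denominator is
#' N (the number of intervals), not N+1, and the series mean is not
#' removed: the k = 0 ordinate is simply excluded from the test set.
#'
#' @param y numeric series with at least 5 points (N >= 4 so q >= 1).
#' @param demean subtract the series mean first (default FALSE).
#' @return an object of class `periodogram` with `frequencies`,
#'   `intensities`, `n` (the N above) and `q`.
#' @export
periodogram <- function(y, demean = FALSE) {
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("series must be finite", call. = FALSE)
  N <- length(y) - 1
  if (N < 4) stop("series too short: need at least 5 points", call. = FALSE)
  if (demean) y <- y - mean(y)
  q <- (N - 1) %/% 2
  k <- seq_len(q)
  omega <- 2 * pi * k / N
  # |sum_j exp(-i w j) y_j|^2 / N, vectorised over frequencies
  ph <- outer(omega, 0:N)
  re <- cos(ph) %*% y
  im <- sin(ph) %*% y
  structure(list(frequencies = omega,
                 intensities = as.numeric(re^2 + im^2) / N,
                 n = N, q = q),
            class = "periodogram")
}

#' Fisher's g statistic of a periodogram
#'
#' \eqn{g = \max_i I(\omega_i) / \sum_{i=1}^q I(\omega_i)} over the q
#' test frequencies; g lies in `[1/q, 1]`. Ties at the maximum are broken
#' toward the lowest frequency.
#'
#' @param pg a [periodogram()].
#' @return an object of class `fisher_g_result` with `g`,
#'   `peak_frequency`, `q` (and `p_value = NA` until
#'   [fisher_g_pvalue()] is applied).
#' @export
fisher_g <- function(pg) {
  stopifnot(inherits(pg, "periodogram"))
  s <- sum(pg$intensities)
  if (s <= 0)
    stop("degenerate input: all periodogram ordinates are zero, g undefined",
         call. = FALSE)
  i <- which.max(pg$intensities)        # first maximum = lowest frequency
  structure(list(g = pg$intensities[i] / s,
                 peak_frequency = pg$frequencies[i],
                 q = pg$q, p_value = NA_real_),
            class = "fisher_g_result")
}

#' Exact null p-value of Fisher's g
#'
#' Under the Gaussian white-noise null, the exact tail probability of the
#' g statistic is
#' \deqn{P(g \ge x) = \sum_{j=1}^{p} (-1)^{j-1} \binom{q}{j} (1 - jx)^{q-1},}
#' where p is the largest integer strictly less than 1/x (capped at q).
#' Computed with log-binomial coefficients and clamped to `[0, 1]` against
#' cancellation in the alternating sum.
#'
#' @param x observed g, in `[1/q, 1]`.
#' @param q number of test frequencies (>= 1).
#' @return the p-value.
#' @export
fisher_g_pvalue <- function(x, q) {
  if (q < 1) stop("q must be >= 1", call. = FALSE)
  if (x < 1 / q - 1e-12 || x > 1 + 1e-12)
    stop("x must lie in [1/q, 1]", call. = FALSE)
  x <- min(max(x, 1 / q), 1)
  if (x == 1) return(0)
  inv <- 1 / x
  p <- if (abs(inv - round(inv)) < 1e-12) round(inv) - 1 else floor(inv)
  p <- min(p, q)
  j <- seq_len(p)
  terms <- exp(lchoose(q, j) + (q - 1) * log1p(-j * x))
  min(1, max(0, sum((-1)^(j - 1) * terms)))
}

#' Fisher's test for hidden periodicity in an entropy series
#'
#' Composition of [periodogram()], [fisher_g()] and [fisher_g_pvalue()]
#' on an evenly sampled series: detects a periodic component against the
#' white-noise null (amplitude beta = 0 in the cosine signal model).
#'
#' @param series an `entropy_series` or a numeric vector.
#' @param demean passed to [periodogram()].
#' @return a `fisher_g_result` with `g`, `peak_frequency`, `q`,
#'   `p_value`.
#' @export
test_entropy_series <- function(series, demean = FALSE) {
  y <- if (inherits(series, "entropy_series")) series$values else series
  if (length(y) > 0 && diff(range(y)) == 0)
    stop("degenerate input: constant series has no periodic component to test",
         call. = FALSE)
  pg <- periodogram(y, demean = demean)
  res <- fisher_g(pg)
  res$p_value <- fisher_g_pvalue(res$g, res$q)
  res
}

#' @export
print.fisher_g_result <- function(x, ...) {
  cat(sprintf("Fisher's g = %.4f (q = %d, peak at %.4f rad/sample)",
              x$g, x$q, x$peak_frequency))
  if (!is.na(x$p_value)) cat(sprintf(", exact p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}

#' Mean of per-replica p-values
#'
#' Arithmetic mean of a set of p-values, used as a descriptive summary
#' per temperature (no multiplicity correction is applied; the p-values
#' are read as continuous parameters).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return their arithmetic mean.
#' @export
mean_pvalue <- function(p) {
  if (length(p) == 0) stop("empty p-value set", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  mean(p)
}
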