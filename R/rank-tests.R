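#' Grouped samples for rank tests
#'
#' Labelled groups of scalar values (one group per temperature).
#'
#' @param groups named list of non-empty numeric vectors, k >= 2.
#' @return an object of class `grouped_samples` with `groups`, `k`,
#'   `n_i`, `N_total`.
#' @export
grouped_samples <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) == 0))
    stop("every group must be non-empty", call. = FALSE)
  if (any(!vapply(groups, function(g) all(is.finite(g)), TRUE)))
    stop("all values must be finite", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- as.character(seq_along(groups))
  structure(list(groups = groups, k = length(groups),
                 n_i = vapply(groups, length, 1L),
                 N_total = sum(vapply(groups, length, 1L))),
            class = "grouped_samples")
}

# mid-ranks over the pooled sample plus per-group rank sums
rank_summary <- function(samples) {
  pooled <- unlist(samples$groups, use.names = FALSE)
  rk <- rank(pooled)                    # mid-ranks for ties
  idx <- rep(seq_len(samples$k), samples$n_i)
  rs <- as.numeric(tapply(rk, idx, sum))
  list(ranks = rk, rs = rs, S_r = sum(rk^2))
}

#' Kruskal-Wallis H statistic
#'
#' Rank-based comparison of k group medians:
#' \deqn{H = \frac{12}{N(N+1)} \sum_i^k \frac{rs_i^2}{n_i} - 3(N+1),}
#' with rs_i the group rank sums over the pooled mid-ranks. By default no
#' tie correction is applied (the uncorrected statistic above); set
#' `tie_correction = TRUE` to divide by the usual
#' \eqn{1 - \sum(t^3 - t)/(N^3 - N)}. H is returned as a continuous
#' parameter; no significance threshold is imposed.
#'
#' @param samples a [grouped_samples()] (or a named list of numerics).
#' @param tie_correction apply the tie correction factor (default FALSE).
#' @return list with `H`, `rs`, `n_i`, `N`, `k`, `S_r`.
#' @export
kruskal_wallis <- function(samples, tie_correction = FALSE) {
  if (!inherits(samples, "grouped_samples")) samples <- grouped_samples(samples)
  rsum <- rank_summary(samples)
  N <- samples$N_total
  H <- 12 / (N * (N + 1)) * sum(rsum$rs^2 / samples$n_i) - 3 * (N + 1)
  if (tie_correction) {
    t <- table(unlist(samples$groups, use.names = FALSE))
    corr <- 1 - sum(t^3 - t) / (N^3 - N)
    if (corr > 0) H <- H / corr
  }
  list(H = H, rs = stats::setNames(rsum$rs, names(samples$groups)),
       n_i = samples$n_i, N = N, k = samples$k, S_r = rsum$S_r)
}

#' Conover-Iman multi-comparison criterion
#'
#' After Kruskal-Wallis, each pair of groups is compared through the
#' difference of mean ranks: the left-hand side is
#' \eqn{|rs_i/n_i - rs_j/n_j|} and the pair differs at level alpha when
#' it exceeds
#' \deqn{t_{1-\alpha/2}\sqrt{\frac{(S_r - C)}{N-1}\cdot\frac{N-1-H}{N-k}
#'   \left(\frac{1}{n_i}+\frac{1}{n_j}\right)},}
#' with \eqn{S_r} the sum of squared ranks, \eqn{C = 0.25\,N(N+1)^2}, and
#' the Student-t quantile on N - k degrees of freedom. Both sides are
#' returned so the caller can vary alpha without re-ranking; the
#' significance decision is the caller's.
#'
#' @param samples a [grouped_samples()] (or named list of numerics).
#' @param alpha level for the t-quantile (default 0.05).
#' @return list with the symmetric `lhs` matrix of mean-rank differences,
#'   the `threshold` matrix (right-hand side per pair), `exceeds`
#'   (lhs > threshold), plus `H`, `S_r`, `C`, `df`, `t_quantile`.
#' @export
conover_iman <- function(samples, alpha = 0.05) {
  if (!inherits(samples, "grouped_samples")) samples <- grouped_samples(samples)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  kw <- kruskal_wallis(samples)
  N <- kw$N; k <- kw$k
  C <- 0.25 * N * (N + 1)^2
  mean_ranks <- kw$rs / kw$n_i
  lhs <- abs(outer(mean_ranks, mean_ranks, `-`))
  tq <- stats::qt(1 - alpha / 2, df = N - k)
  s2 <- (kw$S_r - C) / (N - 1)
  fac <- s2 * (N - 1 - kw$H) / (N - k)
  inv_n <- outer(1 / kw$n_i, 1 / kw$n_i, `+`)
  threshold <- tq * sqrt(pmax(0, fac * inv_n))
  dim(threshold) <- dim(inv_n)          # pmax drops dim attributes
  labs <- names(samples$groups)
  dimnames(lhs) <- dimnames(threshold) <- list(labs, labs)
  diag(threshold) <- 0
  list(lhs = lhs, threshold = threshold, exceeds = lhs > threshold & lhs > 0,
       H = kw$H, S_r = kw$S_r, C = C, df = N - k, t_quantile = tq,
       alpha = alpha)
}

#' Group per-replica summaries by temperature
#'
#' Collects one scalar summary per replica (e.g. time-mean RMSD, RMS
#' end-to-end over a window) into temperature-labelled groups ready for
#' [kruskal_wallis()] / [conover_iman()].
#'
#' @param summaries data.frame with a `temperature` column and the
#'   summary column named by `value`.
#' @param value name of the summary column (default `"value"`).
#' @return a [grouped_samples()].
#' @export
group_by_temperature <- function(summaries, value = "value") {
  if (!is.data.frame(summaries) || !"temperature" %in% names(summaries))
    stop("summaries must be a data.frame with a 'temperature' column",
         call. = FALSE)
  if (!value %in% names(summaries))
    stop("unknown summary column: ", value, call. = FALSE)
  groups <- split(summaries[[value]], summaries$temperature)
  # preserve first-appearance order of the labels
  groups <- groups[unique(as.character(summaries$temperature))]
  if (length(groups) < 2)
    stop("need at least 2 temperature groups", call. = FALSE)
  grouped_samples(groups)
}
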