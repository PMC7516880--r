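#' Gas constant used for conformational entropy
#'
#' R0 = 8.314 J K^-1 mol^-1; entropy values are reported in
#' J K^-1 mol^-1 throughout.
#' @export
GAS_CONSTANT <- 8.314

# bin index of x into n_bins bins with the given edges; right-closed so the
# upper domain boundary lands in the last bin, lower boundary in the first.
bin_index <- function(x, edges) {
  n <- length(edges) - 1
  ix <- findInterval(x, edges, rightmost.closed = TRUE)
  ix[ix < 1] <- 1
  ix[ix > n] <- n
  ix
}

#' Ramachandran-style angle histogram
#'
#' Pools (phi_i, psi_i) angle pairs over a frame range and bins them on a
#' fixed 2-D grid: phi on `[0, pi]`, psi on `(-pi, pi]`, 50 bins per axis
#' by default. Bead i contributes the pair (phi at bead i+1, psi over
#' beads i..i+3), i.e. the phi and psi matrices are paired column-wise on
#' their shared interior beads. NA angles (degenerate geometry) are
#' dropped.
#'
#' @param angles an [backbone_angles()] `angle_series`.
#' @param frames integer frame indices; default all frames.
#' @param n_bins bins per axis (default 50).
#' @return an object of class `ramachandran_histogram` with fields `prob`
#'   (n_bins x n_bins, sums to 1), `phi_edges`, `psi_edges`, `counts`,
#'   `n_samples`.
#' @export
ramachandran_histogram <- function(angles, frames = NULL, n_bins = 50) {
  stopifnot(inherits(angles, "angle_series"))
  phi <- angles$phi; psi <- angles$psi
  if (!is.null(frames)) {
    phi <- phi[frames, , drop = FALSE]
    psi <- psi[frames, , drop = FALSE]
  }
  if (length(phi) == 0) stop("empty frame range", call. = FALSE)
  npairs <- ncol(psi)                         # interior beads with both angles
  p <- as.numeric(phi[, seq_len(npairs), drop = FALSE])
  s <- as.numeric(psi)
  keep <- is.finite(p) & is.finite(s)
  p <- p[keep]; s <- s[keep]
  if (length(p) == 0) stop("no finite angle pairs in range", call. = FALSE)
  phi_edges <- seq(0, pi, length.out = n_bins + 1)
  psi_edges <- seq(-pi, pi, length.out = n_bins + 1)
  ix <- bin_index(p, phi_edges)
  iy <- bin_index(s, psi_edges)
  counts <- matrix(tabulate((iy - 1) * n_bins + ix, nbins = n_bins * n_bins),
                   nrow = n_bins)
  structure(list(prob = counts / sum(counts), counts = counts,
                 phi_edges = phi_edges, psi_edges = psi_edges,
                 n_samples = length(p)),
            class = "ramachandran_histogram")
}

#' Conformational entropy of an angle histogram
#'
#' Shannon entropy of the empirical angle-pair distribution scaled by the
#' gas constant: \eqn{S = -R_0 \sum_i p_i \ln p_i}, in J K^-1 mol^-1.
#' Empty bins contribute zero. S ranges from 0 (a single occupied bin) to
#' \eqn{R_0 \ln B} (uniform occupancy of all B bins). The estimate depends
#' on the bin grid, so it is only comparable across histograms built on
#' the same grid.
#'
#' @param hist a [ramachandran_histogram()], or any numeric vector/matrix
#'   of probabilities summing to 1.
#' @param R0 gas constant (default [GAS_CONSTANT]).
#' @return entropy in J K^-1 mol^-1.
#' @export
conformational_entropy <- function(hist, R0 = GAS_CONSTANT) {
  p <- if (inherits(hist, "ramachandran_histogram")) hist$prob else hist
  p <- as.numeric(p)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("histogram must be normalized (non-negative, sums to 1)", call. = FALSE)
  p <- p[p > 0]
  -R0 * sum(p * log(p))
}

#' Entropy time series of a trajectory
#'
#' At every `stride`-th frame, the conformational entropy of that single
#' frame's angle-pair histogram across beads (default: joint 2-D
#' histogram; `method = "marginal"` instead sums the entropies of the two
#' 1-D marginal histograms, i.e. treats phi and psi as independent). The
#' series is evenly sampled, as the periodicity test downstream assumes.
#'
#' @param traj a [calpha_trajectory()].
#' @param stride sample every `stride`-th frame (>= 1).
#' @param n_bins bins per angular axis (default 50).
#' @param method `"joint"` (default) or `"marginal"`.
#' @param R0 gas constant.
#' @return an object of class `entropy_series` with fields `times` (ns),
#'   `values` (J K^-1 mol^-1), `scope = "replica"`.
#' @export
entropy_series <- function(traj, stride = 1, n_bins = 50,
                           method = c("joint", "marginal"),
                           R0 = GAS_CONSTANT) {
  stopifnot(inherits(traj, "calpha_trajectory"))
  method <- match.arg(method)
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  ang <- backbone_angles(traj)
  frames <- seq(1, n_frames(traj), by = stride)
  phi_edges <- seq(0, pi, length.out = n_bins + 1)
  psi_edges <- seq(-pi, pi, length.out = n_bins + 1)
  npairs <- ncol(ang$psi)
  vals <- vapply(frames, function(f) {
    p <- ang$phi[f, seq_len(npairs)]
    s <- ang$psi[f, ]
    keep <- is.finite(p) & is.finite(s)
    ix <- bin_index(p[keep], phi_edges)
    iy <- bin_index(s[keep], psi_edges)
    if (method == "joint") {
      cnt <- tabulate((iy - 1) * n_bins + ix, nbins = n_bins * n_bins)
      conformational_entropy(cnt / sum(cnt), R0 = R0)
    } else {
      cx <- tabulate(ix, nbins = n_bins); cy <- tabulate(iy, nbins = n_bins)
      conformational_entropy(cx / sum(cx), R0 = R0) +
        conformational_entropy(cy / sum(cy), R0 = R0)
    }
  }, numeric(1))
  structure(list(times = (frames - 1) * traj$frame_dt, values = vals,
                 scope = "replica", R0 = R0),
            class = "entropy_series")
}

#' Pointwise mean entropy across replicas
#'
#' Arithmetic mean of several replica entropy series on a shared time
#' grid; one value per time point.
#'
#' @param series_list list of `entropy_series` with identical `times`.
#' @return an `entropy_series` with `scope = "ensemble-mean"`.
#' @export
ensemble_mean_entropy <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  t0 <- series_list[[1]]$times
  for (s in series_list) {
    stopifnot(inherits(s, "entropy_series"))
    if (length(s$times) != length(t0) || any(abs(s$times - t0) > 1e-9))
      stop("entropy series have mismatched time grids", call. = FALSE)
  }
  m <- colMeans(do.call(rbind, lapply(series_list, `[[`, "values")))
  structure(list(times = t0, values = m, scope = "ensemble-mean",
                 R0 = series_list[[1]]$R0),
            class = "entropy_series")
}

#' Normalized histogram of a scalar signal
#'
#' Bins values on the given edges (or on the value range if none given)
#' and normalizes. When several distributions are to be compared with KL
#' measures they must share edges: use [shared_edges()] over the pooled
#' values.
#'
#' @param values numeric, all finite.
#' @param n_bins number of bins (default 50); ignored when `edges` given.
#' @param edges optional strictly increasing breakpoints.
#' @return an object of class `scalar_distribution` with `prob`, `counts`,
#'   `edges`, `n_samples`.
#' @export
scalar_histogram <- function(values, n_bins = 50, edges = NULL) {
  if (length(values) < 1 || !all(is.finite(values)))
    stop("values must be non-empty and finite", call. = FALSE)
  if (is.null(edges)) {
    rng <- range(values)
    if (diff(rng) == 0) {
      warning("zero-width value range; returning a single-bin distribution")
      edges <- c(rng[1] - 0.5, rng[1] + 0.5)
    } else {
      edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    }
  }
  if (any(diff(edges) <= 0))
    stop("edges must be strictly increasing", call. = FALSE)
  counts <- tabulate(bin_index(values, edges), nbins = length(edges) - 1)
  structure(list(prob = counts / sum(counts), counts = counts,
                 edges = edges, n_samples = length(values)),
            class = "scalar_distribution")
}

#' Common histogram edges for a comparison set
#'
#' Equal-width edges spanning the pooled min-max of all value sets, so
#' every compared distribution lives on the same grid.
#'
#' @param value_list list of numeric vectors.
#' @param n_bins number of bins.
#' @return numeric vector of `n_bins + 1` edges.
#' @export
shared_edges <- function(value_list, n_bins = 50) {
  rng <- range(unlist(value_list))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  seq(rng[1], rng[2], length.out = n_bins + 1)
}

# extract (prob, counts) from a scalar_distribution or bare numeric vector;
# bare vectors carry no sample size, so their probabilities double as counts
# for smoothing purposes.
as_dist <- function(x) {
  if (inherits(x, "scalar_distribution"))
    list(prob = x$prob, counts = x$counts, edges = x$edges)
  else if (is.numeric(x)) {
    if (any(x < 0) || abs(sum(x) - 1) > 1e-8)
      stop("probability vector must be non-negative and sum to 1", call. = FALSE)
    list(prob = x, counts = x, edges = NULL)
  } else stop("expected a scalar_distribution or probability vector", call. = FALSE)
}

check_same_support <- function(dp, dq) {
  if (length(dp$prob) != length(dq$prob))
    stop("distributions have different numbers of bins", call. = FALSE)
  if (!is.null(dp$edges) && !is.null(dq$edges) &&
      (length(dp$edges) != length(dq$edges) ||
       any(abs(dp$edges - dq$edges) > 1e-9)))
    stop("distributions do not share bin edges", call. = FALSE)
}

smooth_pair <- function(dp, dq, smooth) {
  need <- any(dp$prob == 0) || any(dq$prob == 0)
  apply_it <- switch(smooth, always = TRUE, never = FALSE, auto = need)
  if (!apply_it) {
    if (need)
      stop("zero bins present with smooth = \"never\"; KL undefined", call. = FALSE)
    return(list(p = dp$prob, q = dq$prob))
  }
  # one pseudo-count per bin, then renormalize (Laplace smoothing)
  list(p = (dp$counts + 1) / sum(dp$counts + 1),
       q = (dq$counts + 1) / sum(dq$counts + 1))
}

#' Kullback-Leibler divergence between two histograms
#'
#' \eqn{KL(p, q) = \sum_i p_i \ln(p_i / q_i)} in nats, with q the
#' reference distribution. When either histogram has empty bins the
#' divergence is undefined as printed; the default `smooth = "auto"`
#' applies additive (one pseudo-count per bin) smoothing to both
#' histograms in that case, and leaves fully-positive inputs untouched.
#'
#' @param p,q [scalar_histogram()] objects on shared edges, or bare
#'   probability vectors of equal length.
#' @param smooth `"auto"` (default), `"always"`, or `"never"`.
#' @return divergence in nats (>= 0 after smoothing; 0 iff p = q).
#' @export
kl_divergence <- function(p, q, smooth = c("auto", "always", "never")) {
  smooth <- match.arg(smooth)
  dp <- as_dist(p); dq <- as_dist(q)
  check_same_support(dp, dq)
  s <- smooth_pair(dp, dq, smooth)
  keep <- s$p > 0
  sum(s$p[keep] * log(s$p[keep] / s$q[keep]))
}

#' Symmetric Kullback-Leibler distance
#'
#' \eqn{(KL(p, q) + KL(q, p)) / 2}; symmetric in its arguments.
#'
#' @inheritParams kl_divergence
#' @return distance in nats.
#' @export
kl_distance <- function(p, q, smooth = c("auto", "always", "never")) {
  smooth <- match.arg(smooth)
  (kl_divergence(p, q, smooth) + kl_divergence(q, p, smooth)) / 2
}

#' Pairwise KL divergence and distance matrices
#'
#' For a labelled set of distributions on shared edges, the divergence
#' matrix has the *reference* distribution on rows: entry (r, c) is
#' \eqn{KL(p = c\mathrm{-th}, q = r\mathrm{-th})}, matching summary
#' tables labelled "temperature of the reference probability" by row. The
#' distance matrix is symmetric; both have zero diagonals.
#'
#' @param distributions named list of [scalar_histogram()] objects (or
#'   probability vectors of equal length).
#' @param smooth passed to [kl_divergence()].
#' @return list with matrices `divergence` and `distance`.
#' @export
kl_matrix <- function(distributions, smooth = c("auto", "always", "never")) {
  smooth <- match.arg(smooth)
  k <- length(distributions)
  if (k < 2) stop("need at least 2 distributions", call. = FALSE)
  labs <- names(distributions)
  if (is.null(labs)) labs <- as.character(seq_len(k))
  div <- matrix(0, k, k, dimnames = list(labs, labs))  # rows = reference
  for (r in seq_len(k)) for (cc in seq_len(k)) {
    if (r != cc)
      div[r, cc] <- kl_divergence(distributions[[cc]], distributions[[r]],
                                  smooth = smooth)
  }
  dist <- (div + t(div)) / 2
  list(divergence = div, distance = dist)
}

#' Bivariate histogram of two signals
#'
#' Joint normalized histogram of paired signals, used for visual
#' inspection of tail co-movement between replicas (copula-style model
#' fitting is out of scope; only the histogram is produced).
#'
#' @param x,y numeric vectors of equal length.
#' @param n_bins bins per axis (default 50).
#' @return list with `prob` (n_bins x n_bins, sums to 1), `x_edges`,
#'   `y_edges`, `n_samples`.
#' @export
bivariate_histogram <- function(x, y, n_bins = 50) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("values must be finite", call. = FALSE)
  ex <- shared_edges(list(x), n_bins)
  ey <- shared_edges(list(y), n_bins)
  ix <- bin_index(x, ex); iy <- bin_index(y, ey)
  counts <- matrix(tabulate((iy - 1) * n_bins + ix, nbins = n_bins * n_bins),
                   nrow = n_bins)
  list(prob = counts / sum(counts), x_edges = ex, y_edges = ey,
       n_samples = length(x))
}
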