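make_angles <- function(n_frames = 3, n_beads = 12, seed = 1) {
  set.seed(seed)
  backbone_angles(calpha_trajectory(
    array(rnorm(n_frames * n_beads * 3, sd = 2),
          dim = c(n_frames, n_beads, 3))))
}

test_that("angle histogram is normalized and matches brute-force binning", {
  ang <- make_angles()
  h <- ramachandran_histogram(ang, n_bins = 50)
  expect_equal(sum(h$prob), 1, tolerance = 1e-12)
  expect_true(all(h$prob >= 0))
  expect_equal(dim(h$prob), c(50, 50))

  # brute force: assign each pair to its bin one by one
  npairs <- ncol(ang$psi)
  phi <- as.numeric(ang$phi[, seq_len(npairs)])
  psi <- as.numeric(ang$psi)
  brute <- matrix(0, 50, 50)
  pe <- h$phi_edges; se <- h$psi_edges
  for (i in seq_along(phi)) {
    ix <- min(50, max(1, findInterval(phi[i], pe, rightmost.closed = TRUE)))
    iy <- min(50, max(1, findInterval(psi[i], se, rightmost.closed = TRUE)))
    brute[ix, iy] <- brute[ix, iy] + 1
  }
  expect_equal(h$counts, brute)
})

test_that("identical angle pairs collapse the histogram to one bin", {
  # ideal helix: every interior bead has the same (phi, psi) pair
  cfg <- ensemble_config(temperatures = "300K", replicas_per_temperature = 1,
                         n_residues = 20, n_frames = 3,
                         chain_model = "rigid_helix_noise",
                         model_params = list(noise_sd = 0), seed = 2)
  ang <- backbone_angles(generate_chain_trajectory(cfg, "300K", 1))
  h <- ramachandran_histogram(ang)
  expect_equal(sum(h$prob > 0), 1)
  expect_equal(max(h$prob), 1)
})

test_that("conformational entropy matches closed forms and bounds", {
  expect_equal(conformational_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(conformational_entropy(c(0.5, 0.5)), 8.314 * log(2))
  p <- rep(1 / 2500, 2500)
  expect_equal(conformational_entropy(p), 8.314 * log(2500))
  # permutation invariance and bounds on a random histogram
  set.seed(4)
  q <- runif(100); q <- q / sum(q)
  s <- conformational_entropy(q)
  expect_equal(conformational_entropy(sample(q)), s, tolerance = 1e-12)
  expect_gte(s, 0)
  expect_lte(s, 8.314 * log(100))
  expect_error(conformational_entropy(c(0.5, 0.4)), "normalized")
})

test_that("entropy series composes per-frame histograms and honors stride", {
  cfg <- ensemble_config(temperatures = "300K", replicas_per_temperature = 1,
                         n_residues = 60, n_frames = 10, seed = 6)
  tr <- generate_chain_trajectory(cfg, "300K", 1)
  es <- entropy_series(tr, stride = 1, n_bins = 20)
  expect_length(es$values, 10)
  expect_length(entropy_series(tr, stride = 3, n_bins = 20)$values, 4)

  ang <- backbone_angles(tr)
  direct <- vapply(1:10, function(f) {
    conformational_entropy(ramachandran_histogram(ang, frames = f,
                                                  n_bins = 20))
  }, numeric(1))
  expect_equal(es$values, direct, tolerance = 1e-12)

  # a rigid trajectory yields a constant series
  rigid <- calpha_trajectory(array(rep(tr$coords[1, , ], each = 4),
                                   dim = c(4, 60, 3)))
  expect_equal(diff(range(entropy_series(rigid, n_bins = 20)$values)), 0)
})

test_that("ensemble mean entropy averages pointwise and checks grids", {
  mk <- function(v) structure(list(times = 0:2, values = v, scope = "replica",
                                   R0 = 8.314), class = "entropy_series")
  expect_equal(ensemble_mean_entropy(list(mk(c(4, 4, 4)), mk(c(6, 6, 6))))$values,
               c(5, 5, 5))
  expect_equal(ensemble_mean_entropy(list(mk(1:3)))$values, 1:3)
  set.seed(10)
  mats <- replicate(9, runif(3), simplify = FALSE)
  got <- ensemble_mean_entropy(lapply(mats, mk))$values
  expect_equal(got, colMeans(do.call(rbind, mats)), tolerance = 1e-12)
  bad <- structure(list(times = 0:3, values = rep(1, 4), scope = "replica",
                        R0 = 8.314), class = "entropy_series")
  expect_error(ensemble_mean_entropy(list(mk(1:3), bad)), "time grids")
})

test_that("scalar histograms normalize and match brute-force binning", {
  expect_warning(h0 <- scalar_histogram(rep(2, 5)), "zero-width")
  expect_equal(h0$prob, 1)
  set.seed(12)
  v <- rnorm(200)
  h <- scalar_histogram(v, n_bins = 17)
  expect_equal(sum(h$prob), 1, tolerance = 1e-12)
  brute <- numeric(17)
  for (x in v) {
    i <- min(17, max(1, findInterval(x, h$edges, rightmost.closed = TRUE)))
    brute[i] <- brute[i] + 1
  }
  expect_equal(h$counts, brute)
})

test_that("KL divergence and distance match hand-evaluated values", {
  p <- c(0.5, 0.5); q <- c(0.9, 0.1)
  expect_equal(kl_divergence(p, q), log(5) - 0.5 * log(9), tolerance = 1e-12)
  expect_equal(kl_divergence(p, q), 0.5108, tolerance = 1e-4)
  expect_equal(kl_distance(p, q), (0.51083 + 0.36807) / 2, tolerance = 1e-4)
  expect_equal(kl_divergence(p, p), 0)
  expect_equal(kl_distance(p, q), kl_distance(q, p))
  expect_equal(kl_distance(p, p), 0)
})

test_that("KL is non-negative on smoothed pairs and zero only at equality", {
  set.seed(13)
  for (i in 1:25) {
    a <- scalar_histogram(rnorm(40), edges = seq(-4, 4, length.out = 21))
    b <- scalar_histogram(rnorm(40, mean = 0.5),
                          edges = seq(-4, 4, length.out = 21))
    d <- kl_divergence(a, b)
    expect_gte(d, 0)
    expect_equal(kl_divergence(a, a), 0)
  }
  # smoothing keeps zero-bin comparisons finite
  a <- scalar_histogram(c(1, 1, 2), edges = 0:4)
  b <- scalar_histogram(c(3, 3, 4), edges = 0:4)
  expect_true(is.finite(kl_divergence(a, b)))
  expect_error(kl_divergence(a, b, smooth = "never"), "zero bins")
  expect_error(kl_divergence(c(0.5, 0.5), c(0.5, 0.3, 0.2)), "bins")
})

test_that("KL matrix follows the reference-on-rows orientation", {
  set.seed(14)
  ds <- list(a = scalar_histogram(rnorm(30), edges = seq(-4, 4, length.out = 11)),
             b = scalar_histogram(rnorm(30, 1), edges = seq(-4, 4, length.out = 11)),
             c = scalar_histogram(rnorm(30, -1), edges = seq(-4, 4, length.out = 11)))
  m <- kl_matrix(ds)
  expect_equal(diag(m$divergence), c(a = 0, b = 0, c = 0))
  expect_equal(m$distance, t(m$distance))
  for (r in 1:3) for (cc in 1:3) {
    if (r != cc) {
      expect_equal(m$divergence[r, cc],
                   kl_divergence(ds[[cc]], ds[[r]]), tolerance = 1e-12)
      expect_equal(m$distance[r, cc],
                   kl_distance(ds[[r]], ds[[cc]]), tolerance = 1e-12)
    }
  }
  same <- list(x = ds$a, y = ds$a)
  expect_true(all(kl_matrix(same)$divergence == 0))
})

test_that("bivariate histogram normalizes and confines x = y to the diagonal", {
  set.seed(15)
  x <- rnorm(300)
  h <- bivariate_histogram(x, x, n_bins = 10)
  expect_equal(sum(h$prob), 1, tolerance = 1e-12)
  expect_equal(sum(diag(h$prob)), 1, tolerance = 1e-12)
  y <- rnorm(300)
  h2 <- bivariate_histogram(x, y, n_bins = 10)
  ix <- pmin(10, pmax(1, findInterval(x, h2$x_edges, rightmost.closed = TRUE)))
  iy <- pmin(10, pmax(1, findInterval(y, h2$y_edges, rightmost.closed = TRUE)))
  brute <- unname(table(factor(ix, 1:10), factor(iy, 1:10))) / 300
  expect_equal(h2$prob, matrix(as.numeric(brute), 10), tolerance = 1e-12)
  expect_error(bivariate_histogram(1:3, 1:4), "equal length")
})
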