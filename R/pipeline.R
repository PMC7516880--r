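#' Configure an analysis run
#'
#' Holds the knobs of the full pipeline: the time windows, the Flory
#' parameters (tau and the chain-size parameter N, which has no default
#' and must be set explicitly), histogram and entropy settings, the
#' post-hoc level and the output directory.
#'
#' @param n_bonds chain-size parameter N for the size exponent (required).
#' @param windows list of `c(start_ns, end_ns)` pairs, half-open
#'   `[start, end)`, non-overlapping; default `list(c(0, 30), c(70, 100))`.
#' @param tau bond length in Angstrom (default 3.8).
#' @param n_bins histogram bins (per axis for angles, total for scalar
#'   signals; default 50).
#' @param entropy_stride frame stride of the entropy series (default 1).
#' @param smooth KL smoothing rule, see [kl_divergence()].
#' @param alpha level for the Conover-Iman threshold (default 0.05).
#' @param seed integer seed recorded in the manifest.
#' @param output_dir where tables are written.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(n_bonds,
                            windows = list(c(0, 30), c(70, 100)),
                            tau = 3.8, n_bins = 50, entropy_stride = 1,
                            smooth = "auto", alpha = 0.05, seed = 1L,
                            output_dir = "results") {
  if (missing(n_bonds)) stop("n_bonds must be set explicitly", call. = FALSE)
  for (w in windows) {
    if (length(w) != 2 || w[1] >= w[2])
      stop("each window must be c(start, end) with start < end", call. = FALSE)
  }
  if (length(windows) > 1) {
    m <- do.call(rbind, windows)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[-1, 1] < m[-nrow(m), 2]))
      stop("windows must not overlap", call. = FALSE)
  }
  structure(list(n_bonds = as.integer(n_bonds), windows = windows, tau = tau,
                 n_bins = n_bins, entropy_stride = entropy_stride,
                 smooth = smooth, alpha = alpha, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "analysis_config")
}

window_label <- function(w) sprintf("%g-%gns", w[1], w[2])

# frame indices whose times fall in [start, end) ns
window_frames <- function(traj, w) {
  t <- (seq_len(n_frames(traj)) - 1) * traj$frame_dt
  which(t >= w[1] & t < w[2])
}

# write a labelled square matrix as CSV with a label column
write_matrix_csv <- function(m, path, label = "temperature") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- label
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# per-window, per-replica scalar summaries and entropy analyses
analyze_window <- function(ensemble, config, w) {
  labs <- unique(vapply(ensemble, `[[`, "", "temperature"))
  rows <- lapply(ensemble, function(traj) {
    fr <- window_frames(traj, w)
    if (length(fr) == 0)
      stop("window ", window_label(w), " selects no frames", call. = FALSE)
    e2e <- end_to_end_series(traj)
    r_rms <- rms_end_to_end(e2e, fr)
    sub <- calpha_trajectory(traj$coords[fr, , , drop = FALSE],
                             temperature = traj$temperature,
                             replica = traj$replica,
                             frame_dt = traj$frame_dt,
                             bond_length = traj$bond_length,
                             window = window_label(w))
    rmsd <- rmsd_series(sub, reference = 1, alignment = "centroid")
    es <- entropy_series(sub, stride = config$entropy_stride,
                         n_bins = config$n_bins)
    fis <- tryCatch(test_entropy_series(es),
                    error = function(e) list(p_value = NA_real_, g = NA_real_))
    list(temperature = traj$temperature, replica = traj$replica,
         r_rms = r_rms,
         mu = flory_exponent(r_rms, config$tau, config$n_bonds)$mu,
         mean_rmsd = mean(rmsd), rmsd = rmsd, entropy = es,
         fisher_p = fis$p_value, fisher_g = fis$g)
  })
  per_replica <- data.frame(
    temperature = vapply(rows, `[[`, "", "temperature"),
    replica = vapply(rows, function(r) as.integer(r$replica), 1L),
    r_rms = vapply(rows, `[[`, 1, "r_rms"),
    mu = vapply(rows, `[[`, 1, "mu"),
    mean_rmsd = vapply(rows, `[[`, 1, "mean_rmsd"),
    fisher_p = vapply(rows, `[[`, 1, "fisher_p"),
    fisher_g = vapply(rows, `[[`, 1, "fisher_g"))

  # temperature-level summary: RMS over pooled replicas, and its mu
  summary_tbl <- do.call(rbind, lapply(labs, function(tp) {
    sel <- per_replica$temperature == tp
    pooled_rms <- sqrt(mean(per_replica$r_rms[sel]^2))
    data.frame(temperature = tp, r_rms = pooled_rms,
               mu = flory_exponent(pooled_rms, config$tau, config$n_bonds)$mu)
  }))

  kl_of <- function(col) {
    vals <- split(per_replica[[col]], per_replica$temperature)[labs]
    edges <- shared_edges(vals, config$n_bins)
    dists <- lapply(vals, scalar_histogram, edges = edges)
    kl_matrix(dists, smooth = config$smooth)
  }

  # ensemble-mean entropy per temperature, Fisher test on the mean series
  mean_fisher <- vapply(labs, function(tp) {
    sel <- vapply(rows, function(r) r$temperature == tp, TRUE)
    ms <- ensemble_mean_entropy(lapply(rows[sel], `[[`, "entropy"))
    tryCatch(test_entropy_series(ms)$p_value, error = function(e) NA_real_)
  }, numeric(1))

  # pooled per-frame RMSD values per temperature (signal-level KL)
  rmsd_signals <- lapply(labs, function(tp) {
    sel <- vapply(rows, function(r) r$temperature == tp, TRUE)
    unlist(lapply(rows[sel], `[[`, "rmsd"))
  })
  names(rmsd_signals) <- labs
  sig_edges <- shared_edges(rmsd_signals, config$n_bins)
  kl_rmsd_signal <- kl_matrix(lapply(rmsd_signals, scalar_histogram,
                                     edges = sig_edges),
                              smooth = config$smooth)

  list(window = window_label(w),
       per_replica = per_replica,
       summary = summary_tbl,
       kw_r = kruskal_wallis(group_by_temperature(per_replica, "r_rms")),
       kw_mu = kruskal_wallis(group_by_temperature(per_replica, "mu")),
       kw_rmsd = kruskal_wallis(group_by_temperature(per_replica, "mean_rmsd")),
       conover_rmsd = conover_iman(group_by_temperature(per_replica, "mean_rmsd"),
                                   alpha = config$alpha),
       kl_r = kl_of("r_rms"),
       kl_rmsd = kl_of("mean_rmsd"),
       kl_rmsd_signal = kl_rmsd_signal,
       mean_entropy_fisher_p = stats::setNames(mean_fisher, labs))
}

#' Run the full analysis pipeline
#'
#' Orchestrates the study design over a trajectory ensemble: per time
#' window it computes the RMS end-to-end summary and size-exponent table,
#' per-replica entropy series with Fisher's periodicity test (per-replica
#' table with a mean row, plus the test on the ensemble-mean series),
#' Kruskal-Wallis H for the end-to-end, size-exponent and RMSD summaries,
#' the Conover-Iman pairwise matrix for mean RMSD, and Kullback-Leibler
#' divergence/distance matrices across temperatures. All tables are
#' written as CSV under `config$output_dir` and listed in a JSON
#' manifest. Deterministic given the ensemble and config.
#'
#' @param config an [analysis_config()].
#' @param ensemble a named list of [calpha_trajectory()] objects (e.g.
#'   from [generate_ensemble()]), or a directory of multi-model PDB files
#'   read with [read_calpha_trajectory()].
#' @return an object of class `run_manifest`: list with `files`,
#'   `results` (the per-window result lists), `config`.
#' @export
run_pipeline <- function(config, ensemble) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(ensemble)) ensemble <- read_ensemble_dir(ensemble)
  stopifnot(is.list(ensemble), length(ensemble) >= 1)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  results <- list()
  for (w in config$windows) {
    res <- analyze_window(ensemble, config, w)
    wl <- gsub("[^0-9A-Za-z]+", "_", res$window)
    out <- function(name) file.path(config$output_dir,
                                    sprintf("%s_%s.csv", name, wl))
    utils::write.csv(res$per_replica, out("per_replica"), row.names = FALSE)
    utils::write.csv(res$summary, out("summary"), row.names = FALSE)
    # Fisher per-replica table: rows = replica, columns = temperature, mean row
    pv <- stats::reshape(res$per_replica[c("temperature", "replica", "fisher_p")],
                         idvar = "replica", timevar = "temperature",
                         direction = "wide")
    names(pv) <- sub("^fisher_p\\.", "", names(pv))
    pv$replica <- as.character(pv$replica)
    pv <- rbind(pv, c(replica = "mean",
                      as.list(vapply(pv[-1], mean, 1))))
    utils::write.csv(pv, out("fisher_pvalues"), row.names = FALSE)
    utils::write.csv(data.frame(temperature = names(res$mean_entropy_fisher_p),
                                p_value = res$mean_entropy_fisher_p),
                     out("fisher_mean_entropy"), row.names = FALSE)
    kw <- data.frame(statistic = c("H_r_rms", "H_mu", "H_mean_rmsd"),
                     value = c(res$kw_r$H, res$kw_mu$H, res$kw_rmsd$H))
    utils::write.csv(kw, out("kruskal_wallis"), row.names = FALSE)
    files <- c(files,
               out("per_replica"), out("summary"), out("fisher_pvalues"),
               out("fisher_mean_entropy"), out("kruskal_wallis"),
               write_matrix_csv(res$conover_rmsd$lhs, out("conover_lhs")),
               write_matrix_csv(res$kl_r$divergence, out("kl_divergence_r")),
               write_matrix_csv(res$kl_r$distance, out("kl_distance_r")),
               write_matrix_csv(res$kl_rmsd$divergence, out("kl_divergence_rmsd")),
               write_matrix_csv(res$kl_rmsd$distance, out("kl_distance_rmsd")),
               write_matrix_csv(res$kl_rmsd_signal$distance,
                                out("kl_distance_rmsd_signal")))
    results[[res$window]] <- res
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("chaindyn")),
    seed = config$seed,
    n_bonds = config$n_bonds, tau = config$tau, n_bins = config$n_bins,
    entropy_stride = config$entropy_stride, smooth = config$smooth,
    alpha = config$alpha,
    windows = lapply(config$windows, function(w) list(start_ns = w[1],
                                                      end_ns = w[2])),
    files = files)
  mpath <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("pipeline outputs missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(files = c(files, mpath), results = results,
                 config = config),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Pipeline run: %d windows, %d output files under %s\n",
              length(x$results), length(x$files), x$config$output_dir))
  invisible(x)
}

#' Reference summary tables from a published albumin MD study
#'
#' Published per-temperature summaries for human serum albumin (579
#' residues, two analysis windows, 0-30 ns and 70-100 ns, five
#' temperatures 300-312 K, nine replicas each): the RMS end-to-end
#' distances, the size exponents derived from them, and the per-replica
#' Fisher-test p-values for the entropy series. These serve as worked
#' inputs for the size-exponent and p-value-aggregation operations; the
#' underlying trajectories are not deposited.
#'
#' @return list of data.frames: `rms_end_to_end`, `size_exponent`,
#'   `fisher_pvalues_0_30ns`, `fisher_pvalues_70_100ns`.
#' @export
albumin_reference <- function() {
  dir <- system.file("extdata", "albumin", package = "chaindyn")
  rd <- function(f) utils::read.csv(file.path(dir, f), check.names = FALSE)
  list(rms_end_to_end = rd("rms_end_to_end.csv"),
       size_exponent = rd("size_exponent.csv"),
       fisher_pvalues_0_30ns = rd("fisher_pvalues_0_30ns.csv"),
       fisher_pvalues_70_100ns = rd("fisher_pvalues_70_100ns.csv"))
}
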