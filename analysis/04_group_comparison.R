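#!/usr/bin/env Rscript
# Cross-temperature comparison: Kruskal-Wallis H for the per-replica RMS
# end-to-end, size-exponent and mean-RMSD summaries, the Conover-Iman
# pairwise criterion for mean RMSD, and Kullback-Leibler divergence and
# distance matrices across temperatures. Runs the orchestrated pipeline so
# every table family lands under results/pipeline/.

source("analysis/00_config.R")

ens <- generate_ensemble(study_config)
cfg <- analysis_config(n_bonds = study_n_bonds, windows = study_windows,
                       tau = study_config$bond_length, n_bins = 50,
                       alpha = 0.05, seed = study_seed,
                       output_dir = file.path(results_dir, "pipeline"))
man <- run_pipeline(cfg, ens)
message("pipeline wrote ", length(man$files), " files under ",
        cfg$output_dir)

for (wl in names(man$results)) {
  res <- man$results[[wl]]
  message(sprintf("%s: H(r_rms) = %.2f, H(mu) = %.2f, H(mean RMSD) = %.2f",
                  wl, res$kw_r$H, res$kw_mu$H, res$kw_rmsd$H))
  ci <- res$conover_rmsd
  message(sprintf("%s: Conover-Iman threshold (alpha = %.2f) = %.2f; pairs above it:",
                  wl, ci$alpha, ci$threshold[1, 2]))
  above <- which(ci$exceeds, arr.ind = TRUE)
  if (nrow(above) == 0) {
    message("  none")
  } else {
    above <- above[above[, 1] < above[, 2], , drop = FALSE]
    for (i in seq_len(nrow(above)))
      message(sprintf("  %s vs %s (|mean-rank diff| = %.2f)",
                      rownames(ci$lhs)[above[i, 1]],
                      colnames(ci$lhs)[above[i, 2]],
                      ci$lhs[above[i, 1], above[i, 2]]))
  }
  message(wl, ": KL distance matrix for per-replica RMS end-to-end:")
  print(round(res$kl_r$distance, 3))
}
message("with sub-percent injected shifts the rank tests sit near their ",
        "null, mirroring the small H values the albumin summaries report")
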