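#!/usr/bin/env Rscript
# Conformational-entropy analysis: per-frame Ramachandran-histogram entropy
# series for every replica and window, Fisher's exact g-test per series,
# per-temperature mean p-values, and the test on the ensemble-mean series.
# A cosine-signal power check shows the test machinery detecting a true
# oscillation at the study's series length.

source("analysis/00_config.R")

ens <- generate_ensemble(study_config)
labs <- study_config$temperatures

for (w in study_windows) {
  wl <- sprintf("%g-%gns", w[1], w[2])
  per <- list(); mean_p <- numeric(0)
  for (tp in labs) {
    series <- list()
    for (r in seq_len(study_config$replicas_per_temperature)) {
      tr <- ens[[paste0(tp, "_r", r)]]
      t_ns <- (seq_len(dim(tr$coords)[1]) - 1) * tr$frame_dt
      fr <- which(t_ns >= w[1] & t_ns < w[2])
      sub <- calpha_trajectory(tr$coords[fr, , , drop = FALSE],
                               temperature = tp, replica = r,
                               frame_dt = tr$frame_dt)
      es <- entropy_series(sub, stride = 1, n_bins = 50)
      series[[r]] <- es
      fis <- test_entropy_series(es)
      fis_dm <- test_entropy_series(es, demean = TRUE)
      per[[length(per) + 1]] <- data.frame(window = wl, temperature = tp,
                                           replica = r, g = fis$g,
                                           p_value = fis$p_value,
                                           p_value_demeaned = fis_dm$p_value)
    }
    mean_p[tp] <- tryCatch(test_entropy_series(ensemble_mean_entropy(series))$p_value,
                           error = function(e) NA_real_)
  }
  per <- do.call(rbind, per)
  utils::write.csv(per, file.path(results_dir,
                                  sprintf("entropy_fisher_%s.csv",
                                          gsub("[^0-9A-Za-z]", "_", wl))),
                   row.names = FALSE)
  agg <- stats::aggregate(cbind(p_value, p_value_demeaned) ~ temperature,
                          per, mean)
  message(wl, ": mean per-replica Fisher p-value by temperature ",
          "(literal formula / mean-removed)")
  print(agg, row.names = FALSE, digits = 3)
  message(wl, ": p-value of the ensemble-mean entropy series")
  print(round(mean_p, 3))
}
message("under the literal formula the large constant offset of the entropy ",
        "series (~R0 ln B) injects a uniform intensity floor of mean^2/N at ",
        "every test frequency (the frequency set is not orthogonal to a ",
        "constant), flattening g toward 1/q and the p-values toward 1; with ",
        "the mean removed the p-values spread over (0, 1) as expected for ",
        "aperiodic series")

# -- power check on the explicit cosine signal model --------------------------
# 30-point series (one window at 1 ns sampling): a cosine of amplitude
# comparable to the noise is detected, pure noise is not.
p_osc <- test_entropy_series(generate_entropy_signal(
  signal_model_params(beta = 1.5, omega = 2 * pi * 5 / 29, alpha = 0.4,
                      noise_sd = 0.5, n_points = 30, seed = study_seed)))
p_null <- test_entropy_series(generate_entropy_signal(
  signal_model_params(beta = 0, noise_sd = 0.5, n_points = 30,
                      seed = study_seed)))
message(sprintf("cosine signal model, 30 points: p = %.4g with beta = 1.5, p = %.3f with beta = 0",
                p_osc$p_value, p_null$p_value))
jsonlite::write_json(list(beta_1.5 = p_osc$p_value, beta_0 = p_null$p_value),
                     file.path(results_dir, "fisher_power_check.json"),
                     auto_unbox = TRUE, digits = NA)
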