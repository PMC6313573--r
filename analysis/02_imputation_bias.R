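#!/usr/bin/env Rscript
# Evaluate the bootstrap-EM multiple imputation against DL/2 and DL/sqrt(2)
# substitution on a complete two-substance panel whose target substance is
# artificially censored at ~82% and ~88% while the correlated helper
# substance stays observed: AME and RMSE on the censored cells, whose truth
# is known.

source(file.path("analysis", "_common.R"))
out <- results_dir("tables")

cfg <- scenario_config(n_units = 200, n_substances = 2,
                       substance_correlation = 0.9, censoring_target = 0,
                       seed = MASTER_SEED)
w <- simulate_water_panel(cfg)
truth <- w$latent
wide <- reshape(as.data.frame(truth)[, c("obs_id", "substance", "value")],
                idvar = "obs_id", timevar = "substance", direction = "wide")

rows <- list()
for (q in c(0.82, 0.88)) {
  thr <- quantile(wide$value.S1, q)
  cen <- artificial_censor(truth, thr, substances = "S1")
  ests <- list(
    imputation = em_bootstrap_impute(cen, m = 8, seed = MASTER_SEED + 1L),
    half_dl = substitute_censored(cen, "half_dl"),
    dl_over_sqrt2 = substitute_censored(cen, "dl_over_sqrt2"))
  for (nm in names(ests)) {
    ev <- evaluate_imputation(truth, ests[[nm]])
    rows[[length(rows) + 1]] <- data.frame(
      censoring = sprintf("%.0f%%", 100 * attr(cen, "censoring_rate")),
      method = nm, ame_ngL = ev$ame * 1e6, rmse_ngL = ev$rmse * 1e6,
      n_cells = ev$n_cells)
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out, "imputation_bias.csv"), row.names = FALSE)

message("imputation bias table (ng/L):")
print(tab, row.names = FALSE)
best <- tapply(tab$ame_ngL, tab$censoring, function(v) v[1] == min(v))
message("imputation has the lowest AME at every censoring level: ",
        all(best))
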