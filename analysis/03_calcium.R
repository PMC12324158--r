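#!/usr/bin/env Rscript
# Delta-F/F0 analysis of the simulated membrane Ca2+-sensor recordings:
# frame-wise background subtraction, baseline normalization against the
# pre-glutamate period, and per-cell peak / AUC metrics. The WT-like
# condition carries the larger transients (true peak 0.80 vs 0.45).

library(nanocouple)

tab_dir <- "results/tables"
dir.create(tab_dir, recursive = TRUE, showWarnings = FALSE)
ca <- read.csv("results/data/calcium_traces.csv")

metrics <- do.call(rbind, lapply(split(ca, ca[c("cell", "condition")]),
  function(tr) {
    if (nrow(tr) == 0) return(NULL)
    corrected <- background_subtract(tr$F, tr$F_bg)
    dff <- delta_f_over_f0(corrected, tr$time_s, c(0, tr$stim_onset_s[1]))
    pa <- peak_and_auc(dff, response_window = c(tr$stim_onset_s[1], 60),
                       smooth_s = 1.25)
    data.frame(condition = tr$condition[1], cell = tr$cell[1],
               F0 = dff$F0, peak_dff = pa$peak, auc_s = pa$auc,
               true_peak_dff = tr$true_peak_dff[1])
  }))
rownames(metrics) <- NULL
write.csv(metrics, file.path(tab_dir, "calcium_metrics.csv"),
          row.names = FALSE)

for (cond in unique(metrics$condition)) {
  m <- metrics[metrics$condition == cond, ]
  message(sprintf("%-6s peak dF/F0: %.3f +/- %.3f (truth %.2f), AUC %.2f s",
                  cond, mean(m$peak_dff), sd(m$peak_dff) / sqrt(nrow(m)),
                  m$true_peak_dff[1], mean(m$auc_s)))
}
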