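#!/usr/bin/env Rscript
# Generate the full synthetic two-condition dataset ("WT" vs "V618G") that
# the downstream analysis scripts consume: two-color localization tables,
# glutamate-evoked sweeps at 7 holding potentials, Ca2+-sensor traces, PLA
# image pairs, and an immunoblot band table. Everything is written under
# results/data/ and is reproducible from the single seed below.

library(nanocouple)

seed <- 20260901
data_dir <- "results/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

conditions <- list(
  WT    = list(ratio = 0.4,  n_hetero = 60, n_homo_red = 15, sd = 40,
               peak_dff = 0.80, puncta = 10:13),
  V618G = list(ratio = 0.05, n_hetero = 40, n_homo_red = 30, sd = 25,
               peak_dff = 0.45, puncta = 2:5))

message("== SMLM localization tables ==")
for (i in seq_along(conditions)) {
  cond <- names(conditions)[i]; p <- conditions[[i]]
  cfg <- point_sim_config(
    field_size = c(12000, 12000),
    n_homo_red = p$n_homo_red, n_homo_green = 15, n_hetero = p$n_hetero,
    molecules_per_cluster = list(lambda = 60, floor = 40),
    cluster_sd = p$sd, hetero_fraction_red = 0.5,
    background_density = 1, seed = seed + i)
  tab <- simulate_localizations(cfg)
  write_localizations(tab, file.path(data_dir,
                                     paste0("locs_", cond, ".csv")))
  message(sprintf("  %s: %d localizations, %d true clusters", cond,
                  nrow(tab), nrow(attr(tab, "truth"))))
}

message("== whole-cell sweeps (6 cells x 7 voltages per condition) ==")
for (i in seq_along(conditions)) {
  cond <- names(conditions)[i]; ratio <- conditions[[i]]$ratio
  for (cell in 1:6) {
    cell_seed <- seed + 100 * i + cell
    scale <- withr::with_seed(cell_seed, runif(1, 0.7, 1.3))
    for (v in seq(-80, 40, 20)) {
      a_in <- 1200 * scale * (0.4 + 0.6 * abs(v + 80) / 120)
      q_in <- a_in * 0.25^2 / (0.02 + 0.25)
      a_out <- ratio * q_in / (0.6^2 / (0.1 + 0.6))
      cfg <- trace_sim_config(
        dt = 1e-3, duration = 8, stim_onset = 1, stim_duration = 1,
        inward_amplitude = a_in, inward_rise = 0.02, inward_decay = 0.25,
        outward_amplitude = a_out, outward_delay = 1.5,
        outward_rise = 0.1, outward_decay = 0.6,
        noise_sd = 0.5, voltage_mV = v, seed = cell_seed + v + 200)
      sim <- simulate_current_trace(cfg)
      sim$trace$cell <- sprintf("%s_cell%d", cond, cell)
      write_current_trace(
        sim$trace,
        file.path(data_dir, sprintf("sweep_%s_c%02d_%+04d.csv",
                                    cond, cell, v)),
        extra = list(condition = cond,
                     true_Q_in_pC = sim$true_Q_in_pC,
                     true_Q_out_pC = sim$true_Q_out_pC,
                     true_ratio = ratio))
    }
  }
}
message("  84 sweeps written")

message("== Ca2+-sensor traces (5 cells per condition) ==")
ca <- NULL
for (i in seq_along(conditions)) {
  cond <- names(conditions)[i]
  for (cell in 1:5) {
    tr <- simulate_fluorescence_trace(
      f0 = 100, peak_dff = conditions[[i]]$peak_dff, stim_onset = 10,
      bg = 20, noise_sd = 1, seed = seed + 300 + 10 * i + cell)
    ca <- rbind(ca, data.frame(condition = cond, cell = cell,
                               time_s = tr$time, F = tr$F, F_bg = tr$F_bg,
                               stim_onset_s = tr$stim_onset,
                               true_peak_dff = tr$true_peak_dff))
  }
}
write.csv(ca, file.path(data_dir, "calcium_traces.csv"), row.names = FALSE)

message("== PLA image pairs (2 fields x 3 cells per condition) ==")
for (i in seq_along(conditions)) {
  cond <- names(conditions)[i]
  for (img_i in 1:2) {
    counts <- withr::with_seed(seed + 400 + 10 * i + img_i,
                               sample(conditions[[i]]$puncta, 3, TRUE))
    sim <- simulate_cell_image(3, counts,
                               seed = seed + 500 + 10 * i + img_i)
    write_cell_image(sim, data_dir,
                     prefix = sprintf("pla_%s_f%d", cond, img_i))
  }
}

message("== immunoblot band intensities ==")
write.csv(data.frame(lane = 1:6,
                     condition = rep(c("WT", "V618G"), each = 3),
                     target = c(1.00, 1.10, 0.95, 1.90, 2.10, 2.00),
                     loading = c(1.00, 1.05, 0.98, 1.02, 1.00, 0.97)),
          file.path(data_dir, "blot_bands.csv"), row.names = FALSE)

message("done; data under ", data_dir)
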