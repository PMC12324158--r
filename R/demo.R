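#' End-to-end synthetic rehearsal of the WT vs V618G comparison
#'
#' Regenerates, from one seed, a complete two-condition synthetic study and
#' runs every pipeline stage on it:
#'
#' * a "WT-like" condition: strongly coupled sweeps (true Q_out/Q_in = 0.4),
#'   an SMLM scene rich in large heteroclusters (spread 40 nm);
#' * a "V618G-like" condition: nearly uncoupled sweeps (true ratio 0.05), a
#'   scene with fewer, smaller heteroclusters (spread 25 nm) and more
#'   red homoclusters.
#'
#' Stages: localization simulation, radius sweep (20/40/60 nm, count 10)
#' with composition and area analysis, K-S comparison of heterocluster
#' areas, cross-channel NND, charge/coupling analysis of simulated sweeps,
#' delta-F/F0 metrics, PLA image segmentation + puncta density, TIRF
#' intensities and blot densitometry ratios. All outputs are CSV/JSON under
#' `out_dir`; two runs with the same seed are byte-identical.
#'
#' @param seed integer master seed; all stage seeds derive from it.
#' @param out_dir output directory (created).
#' @param n_cells_ephys cells per condition for the sweep analysis.
#' @return Invisibly, a list with the key result objects (`coupling`,
#'   `ks_hetero_areas`, `composition`, `pla`, `summary_path`).
#' @export
run_demo <- function(seed, out_dir, n_cells_ephys = 6) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("demo stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  conditions <- list(
    WT = list(ratio = 0.4, n_hetero = 60, n_homo_red = 15, sd = 40,
              peak_dff = 0.8, puncta = 10:13),
    V618G = list(ratio = 0.05, n_hetero = 40, n_homo_red = 30, sd = 25,
                 peak_dff = 0.45, puncta = 2:5))

  ## --- SMLM scenes, radius sweep, K-S on heterocluster areas -------------
  sweeps <- list(); scenes <- list()
  stage("smlm", {
    for (i in seq_along(conditions)) {
      cond <- names(conditions)[i]
      p <- conditions[[i]]
      cfg <- point_sim_config(
        field_size = c(12000, 12000),
        n_homo_red = p$n_homo_red, n_homo_green = 15, n_hetero = p$n_hetero,
        molecules_per_cluster = list(lambda = 60, floor = 40),
        cluster_sd = p$sd, hetero_fraction_red = 0.5,
        background_density = 1, seed = seed + i)
      scenes[[cond]] <- simulate_localizations(cfg)
      write_localizations(scenes[[cond]],
                          file.path(out_dir, paste0("locs_", cond, ".csv")))
      sweeps[[cond]] <- radius_sweep(scenes[[cond]], c(20, 40, 60), 10)
      utils::write.csv(sweeps[[cond]]$summary,
                       file.path(out_dir, paste0("cluster_summary_", cond,
                                                 ".csv")),
                       row.names = FALSE)
      utils::write.csv(sweeps[[cond]]$results$r40$areas$table,
                       file.path(out_dir, paste0("cluster_areas_r40_", cond,
                                                 ".csv")),
                       row.names = FALSE)
    }
  })

  ks_res <- stage("ks", {
    het_area <- lapply(sweeps, function(s) {
      tab <- s$results$r40$areas$table
      tab$area_nm2[tab$composition == "hetero" & !tab$degenerate]
    })
    ks <- ks_two_sample(het_area$WT, het_area$V618G)
    utils::write.csv(data.frame(comparison = "hetero_area_r40_WT_vs_V618G",
                                D = ks$D, p = ks$p, n1 = ks$n1, n2 = ks$n2),
                     file.path(out_dir, "ks_hetero_areas.csv"),
                     row.names = FALSE)
    ks
  })

  stage("nnd", {
    nnd_rows <- do.call(rbind, lapply(names(scenes), function(cond) {
      do.call(rbind, lapply(list(c("red", "green"), c("green", "red")),
        function(dir) {
          r <- cross_channel_nnd(scenes[[cond]], dir[1], dir[2])
          s <- nnd_distribution(r, bin_width = 5)
          data.frame(condition = cond, direction = r$direction,
                     n = s$n, modal_bin_lo = s$modal_bin[1],
                     modal_bin_hi = s$modal_bin[2],
                     fraction_within_50nm = s$fraction_within)
        }))
    }))
    utils::write.csv(nnd_rows, file.path(out_dir, "nnd_summary.csv"),
                     row.names = FALSE)
  })

  ## --- ephys: per-cell sweeps at 7 voltages ------------------------------
  voltages <- seq(-80, 40, by = 20)
  coupling <- stage("ephys", {
    rows <- NULL
    for (i in seq_along(conditions)) {
      cond <- names(conditions)[i]
      ratio <- conditions[[i]]$ratio
      for (cell in seq_len(n_cells_ephys)) {
        cell_seed <- seed + 100 * i + cell
        scale <- local_seed(cell_seed, stats::runif(1, 0.7, 1.3))
        for (v in voltages) {
          a_in <- 1200 * scale * (0.4 + 0.6 * abs(v + 80) / 120)
          q_in <- biexp_charge(a_in, 0.02, 0.25)
          # outward amplitude chosen so true Q_out/Q_in equals the target
          a_out <- ratio * q_in / biexp_charge(1, 0.1, 0.6)
          cfg <- trace_sim_config(
            dt = 1e-3, duration = 8, stim_onset = 1, stim_duration = 1,
            inward_amplitude = a_in, inward_rise = 0.02, inward_decay = 0.25,
            outward_amplitude = a_out, outward_delay = 1.5,
            outward_rise = 0.1, outward_decay = 0.6,
            noise_sd = 0.5, voltage_mV = v,
            seed = cell_seed + v + 200)
          sim <- simulate_current_trace(cfg)
          sim$trace$cell <- paste0(cond, "_cell", cell)
          row <- analyze_sweep(sim$trace, window = c(1, 7))
          row$condition <- cond
          row$true_ratio <- ratio
          rows <- rbind(rows, row)
        }
      }
    }
    utils::write.csv(rows, file.path(out_dir, "ephys_per_sweep.csv"),
                     row.names = FALSE)
    agg <- do.call(rbind, lapply(names(conditions), function(cond) {
      cc <- coupling_curve(rows[rows$condition == cond, ])
      cbind(condition = cond, cc$aggregate)
    }))
    utils::write.csv(agg, file.path(out_dir, "coupling_curves.csv"),
                     row.names = FALSE)
    agg
  })

  ## --- calcium ------------------------------------------------------------
  stage("calcium", {
    ca <- do.call(rbind, lapply(seq_along(conditions), function(i) {
      cond <- names(conditions)[i]
      do.call(rbind, lapply(1:5, function(cell) {
        tr <- simulate_fluorescence_trace(
          f0 = 100, peak_dff = conditions[[i]]$peak_dff,
          stim_onset = 10, bg = 20, noise_sd = 1,
          seed = seed + 300 + 10 * i + cell)
        corrected <- background_subtract(tr$F, tr$F_bg)
        dff <- delta_f_over_f0(corrected, tr$time, c(0, tr$stim_onset))
        pa <- peak_and_auc(dff, response_window = c(tr$stim_onset, 60))
        data.frame(condition = cond, cell = cell, peak_dff = pa$peak,
                   auc_s = pa$auc, true_peak_dff = tr$true_peak_dff)
      }))
    }))
    utils::write.csv(ca, file.path(out_dir, "calcium_metrics.csv"),
                     row.names = FALSE)
  })

  ## --- PLA images ---------------------------------------------------------
  pla <- stage("pla", {
    rows <- do.call(rbind, lapply(seq_along(conditions), function(i) {
      cond <- names(conditions)[i]
      do.call(rbind, lapply(1:2, function(img_i) {
        sim <- simulate_cell_image(
          n_cells = 3,
          puncta_per_cell = local_seed(seed + 400 + 10 * i + img_i,
            sample(conditions[[i]]$puncta, 3, replace = TRUE)),
          seed = seed + 500 + 10 * i + img_i)
        masks <- segment_cells(sim$nuclear, expansion_um = 2,
                               pixel_size_um = sim$pixel_size_um)
        det <- detect_puncta(sim$puncta, masks, sim$pixel_size_um)
        dens <- puncta_density(det, masks$areas)
        cbind(condition = cond, image = img_i, dens)
      }))
    }))
    utils::write.csv(rows, file.path(out_dir, "pla_density.csv"),
                     row.names = FALSE)
    rows
  })

  ## --- TIRF + blot --------------------------------------------------------
  stage("tirf_blot", {
    tirf <- do.call(rbind, lapply(seq_along(conditions), function(i) {
      cond <- names(conditions)[i]
      level <- if (cond == "WT") 800 else 2000  # V618G: higher membrane level
      local_seed(seed + 600 + i, {
        img <- matrix(100 + stats::rnorm(128 * 128, sd = 5), 128, 128)
        mask <- matrix(0L, 128, 128); mask[40:90, 40:90] <- 1L
        img[mask == 1L] <- img[mask == 1L] + level
        bg <- matrix(FALSE, 128, 128); bg[1:20, 1:20] <- TRUE
        cbind(condition = cond,
              tirf_intensity(img, bg, mask, exposure_ms = 50))
      })
    }))
    tirf <- normalize_to_reference(tirf, "normalized_intensity", "WT")
    utils::write.csv(tirf, file.path(out_dir, "tirf_intensity.csv"),
                     row.names = FALSE)

    bands <- data.frame(lane = 1:6,
                        condition = rep(c("WT", "V618G"), each = 3),
                        target = c(1.00, 1.10, 0.95, 1.9, 2.1, 2.0),
                        loading = c(1.00, 1.05, 0.98, 1.02, 1.00, 0.97))
    utils::write.csv(densitometry_ratio(bands, "WT"),
                     file.path(out_dir, "blot_ratios.csv"),
                     row.names = FALSE)
  })

  ## --- summary ------------------------------------------------------------
  summary_path <- file.path(out_dir, "summary.json")
  comp <- lapply(sweeps, function(s)
    setNames(s$results$r40$distribution$percentage,
             s$results$r40$distribution$composition))
  jsonlite::write_json(list(
    seed = seed,
    coupling_ratio_mean = lapply(split(coupling$mean, coupling$condition),
                                 mean),
    ks_hetero_area_r40 = list(D = ks_res$D, p = ks_res$p),
    composition_pct_r40 = comp), summary_path, auto_unbox = TRUE, digits = NA)

  invisible(list(coupling = coupling, ks_hetero_areas = ks_res,
                 composition = comp, pla = pla, summary_path = summary_path))
}
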