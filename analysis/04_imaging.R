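#!/usr/bin/env Rscript
# Image-based quantification: PLA puncta density per cell (nuclear
# segmentation -> cytoplasm expansion -> LoG spot detection -> count/area),
# TIRF membrane-abundance intensities normalized to exposure and to the WT
# group, and immunoblot densitometry ratios. The PLA density should drop
# sharply in the V618G-like condition (fewer puncta per cell by design).

library(nanocouple)

data_dir <- "results/data"
tab_dir <- "results/tables"
dir.create(tab_dir, recursive = TRUE, showWarnings = FALSE)

## --- PLA ------------------------------------------------------------------
pla <- NULL
for (f in list.files(data_dir, pattern = "^pla_.*_nuclear\\.tif$")) {
  prefix <- sub("_nuclear\\.tif$", "", f)
  cond <- sub("^pla_([^_]+)_.*$", "\\1", prefix)
  truth <- jsonlite::read_json(file.path(data_dir,
                                         paste0(prefix, "_truth.json")),
                               simplifyVector = TRUE)
  nuclear <- read_image_16bit(file.path(data_dir, f))
  puncta <- read_image_16bit(file.path(data_dir,
                                       paste0(prefix, "_puncta.tif")))
  masks <- segment_cells(nuclear, expansion_um = 2,
                         pixel_size_um = truth$pixel_size_um)
  det <- detect_puncta(puncta, masks, truth$pixel_size_um)
  dens <- puncta_density(det, masks$areas)
  pla <- rbind(pla, cbind(condition = cond, field = prefix, dens))
}
write.csv(pla, file.path(tab_dir, "pla_density.csv"), row.names = FALSE)
for (cond in unique(pla$condition)) {
  m <- pla[pla$condition == cond, ]
  message(sprintf("%-6s PLA: %.1f puncta/cell, %.4f puncta/um^2 (n = %d cells)",
                  cond, mean(m$puncta_count), mean(m$puncta_density),
                  nrow(m)))
}

## --- TIRF -----------------------------------------------------------------
tirf <- NULL
for (cond in c("WT", "V618G")) {
  level <- if (cond == "WT") 800 else 2000   # V618G: higher membrane level
  tirf <- rbind(tirf, withr::with_seed(if (cond == "WT") 61 else 62, {
    img <- matrix(100 + rnorm(128 * 128, sd = 5), 128, 128)
    mask <- matrix(0L, 128, 128); mask[40:90, 40:90] <- 1L
    img[mask == 1L] <- img[mask == 1L] + level
    bg <- matrix(FALSE, 128, 128); bg[1:20, 1:20] <- TRUE
    cbind(condition = cond, tirf_intensity(img, bg, mask, exposure_ms = 50))
  }))
}
tirf <- normalize_to_reference(tirf, "normalized_intensity", "WT")
write.csv(tirf, file.path(tab_dir, "tirf_intensity.csv"), row.names = FALSE)
message(sprintf("TIRF V618G/WT membrane abundance: %.2fx",
                tirf$normalized_intensity_normalized[tirf$condition ==
                                                       "V618G"]))

## --- blot -----------------------------------------------------------------
bands <- read.csv(file.path(data_dir, "blot_bands.csv"))
blot <- densitometry_ratio(bands, "WT")
write.csv(blot, file.path(tab_dir, "blot_ratios.csv"), row.names = FALSE)
message(sprintf("blot V618G/WT (loading-normalized): %.2f",
                mean(blot$normalized_to_ref[blot$condition == "V618G"])))
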