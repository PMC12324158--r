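test_that("blank nuclear images give zero cells with a warning", {
  img <- matrix(100, 64, 64)
  expect_warning(res <- segment_cells(img + matrix(rnorm(64 * 64), 64),
                                      expansion_um = 2, pixel_size_um = 0.1),
                 "no nuclei")
  expect_equal(nrow(res$areas), 0)
  expect_true(all(res$labels == 0))
})

test_that("segmentation recovers disjoint synthetic cells and their areas", {
  sim <- simulate_cell_image(n_cells = 3, puncta_per_cell = 0,
                             cell_radius_um = 5, nucleus_radius_um = 3,
                             seed = 21)
  # nucleus (3 um) + 2 um expansion reproduces the 5 um cell disk
  res <- segment_cells(sim$nuclear, expansion_um = 2, pixel_size_um = 0.1)
  expect_equal(nrow(res$areas), 3)
  expect_true(all(abs(res$areas$area_um2 - pi * 25) / (pi * 25) < 0.05))
})

test_that("masks of close nuclei partition the contested pixels", {
  # two nuclei closer than twice the expansion radius
  img <- matrix(100, 128, 128)
  d2a <- outer((1:128 - 50)^2, (1:128 - 64)^2, "+")
  d2b <- outer((1:128 - 78)^2, (1:128 - 64)^2, "+")
  img[d2a <= 10^2] <- 20000
  img[d2b <= 10^2] <- 20000
  res <- segment_cells(img, expansion_um = 3, pixel_size_um = 0.1,
                       min_nucleus_area_um2 = 1)
  expect_equal(nrow(res$areas), 2)
  # no overlap by construction (single label matrix); union preserved:
  # every pixel within the expansion distance of a nucleus is labeled
  expect_equal(sum(res$labels > 0) * 0.1^2, sum(res$areas$area_um2))
  expect_gt(sum(res$labels == 1), 0)
  expect_gt(sum(res$labels == 2), 0)
})

test_that("puncta detection is exact on clean synthetic cells", {
  sim <- simulate_cell_image(n_cells = 1, puncta_per_cell = 8,
                             puncta_amplitude = 2000, noise_sd = 200,  # SNR 10
                             seed = 33)
  masks <- segment_cells(sim$nuclear, expansion_um = 2, pixel_size_um = 0.1)
  det <- detect_puncta(sim$puncta, masks, pixel_size_um = 0.1)
  expect_equal(nrow(det), 8)
})

test_that("blank cells give zero puncta and off-mask spots are not counted", {
  sim <- simulate_cell_image(n_cells = 1, puncta_per_cell = 0, seed = 5)
  masks <- segment_cells(sim$nuclear, expansion_um = 2, pixel_size_um = 0.1)
  expect_equal(nrow(detect_puncta(sim$puncta, masks, 0.1)), 0)
  # paint spots far outside the mask: they must not be counted
  img <- sim$puncta
  spot <- function(m, cy, cx) {
    ax <- -6:6
    g <- 3000 * exp(-outer(ax^2, ax^2, "+") / (2 * 2^2))
    m[cy + ax, cx + ax] <- m[cy + ax, cx + ax] + g
    m
  }
  corner_ok <- all(masks$labels[1:20, 1:20] == 0)
  expect_true(corner_ok)
  img <- spot(img, 10, 10)
  expect_equal(nrow(detect_puncta(img, masks, 0.1)), 0)
})

test_that("saturated images are flagged", {
  sim <- simulate_cell_image(n_cells = 1, puncta_per_cell = 1,
                             puncta_amplitude = 1e6, seed = 2)
  masks <- segment_cells(sim$nuclear, expansion_um = 2, pixel_size_um = 0.1)
  expect_warning(detect_puncta(sim$puncta, masks, 0.1), "saturated")
})

test_that("puncta density is count/area with unit correctness", {
  areas <- data.frame(cell = 1:2, area_um2 = c(100, 50))
  counts <- data.frame(cell = 1:2, puncta_count = c(5, 0))
  out <- puncta_density(counts, areas)
  expect_equal(out$puncta_density, c(0.05, 0))
  # a zero-area cell is excluded with a warning
  areas2 <- rbind(areas, data.frame(cell = 3, area_um2 = 0))
  expect_warning(out2 <- puncta_density(counts, areas2), "zero-area")
  expect_equal(nrow(out2), 2)
  # halving the pixel size quadruples pixel counts but fixes the um^2 area:
  # density in um^-2 is unchanged for the same physical cell
  px_area_coarse <- 400 * 0.2^2
  px_area_fine <- 1600 * 0.1^2
  expect_equal(5 / px_area_coarse, 5 / px_area_fine)
})

test_that("TIRF intensity normalizes by exposure and background", {
  img <- matrix(0, 32, 32)
  mask <- matrix(FALSE, 32, 32); mask[10:19, 10:19] <- TRUE
  bg <- matrix(FALSE, 32, 32); bg[1:5, 1:5] <- TRUE
  # image equal to background everywhere -> 0
  flat <- matrix(7, 32, 32)
  expect_equal(tirf_intensity(flat, bg, mask, 10)$normalized_intensity, 0)
  # uniform value v over n pixels, bg 0, exposure 10 -> n*v/10
  img[mask] <- 12
  res <- tirf_intensity(img, bg, mask, 10)
  expect_equal(res$normalized_intensity, 100 * 12 / 10)
  # proportional exposures agree exactly
  r5 <- tirf_intensity(img, bg, mask, 5)
  r50 <- tirf_intensity(img * 10, bg, mask, 50)
  expect_equal(r5$normalized_intensity, r50$normalized_intensity,
               tolerance = 1e-12)
  # background overlapping the mask is an error
  bad_bg <- mask
  expect_error(tirf_intensity(img, bad_bg, mask, 10), "overlap")
})

test_that("densitometry ratios normalize to the reference condition", {
  bands <- data.frame(lane = 1:4, condition = c("WT", "WT", "mut", "mut"),
                      target = c(1, 1, 2, 2), loading = c(1, 1, 1, 1))
  out <- densitometry_ratio(bands, "WT")
  expect_equal(out$normalized_to_ref, c(1, 1, 2, 2))
  # gain change on all lanes leaves normalized values unchanged
  bands2 <- bands; bands2$target <- bands2$target * 2
  bands2$loading <- bands2$loading * 2
  expect_equal(densitometry_ratio(bands2, "WT")$normalized_to_ref,
               out$normalized_to_ref)
  expect_error(densitometry_ratio(transform(bands, loading = 0), "WT"),
               "> 0")
  expect_error(densitometry_ratio(bands, "absent"), "reference")
})
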