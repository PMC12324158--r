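#' Simulate a two-channel cell image with countable puncta
#'
#' Renders a PLA-style field: round cells with bright nuclei in one channel
#' and diffraction-limited puncta (small Gaussian spots) strictly inside the
#' cells in the other channel, on a constant background with Gaussian read
#' noise. Cells are placed without overlap by rejection sampling; puncta
#' within a cell keep a minimum mutual separation so that every rendered spot
#' is resolvable and countable, and stay well inside the cell edge.
#'
#' @param n_cells number of cells.
#' @param puncta_per_cell integer vector of length `n_cells` (recycled if
#'   length 1): puncta count per cell.
#' @param cell_radius_um cell radius in um.
#' @param nucleus_radius_um nucleus radius in um.
#' @param pixel_size_um pixel size in um (must be > 0).
#' @param image_size_px image width/height in pixels (length-2).
#' @param puncta_sigma_um Gaussian sigma of a rendered punctum (um).
#' @param puncta_amplitude peak intensity of a punctum above background.
#' @param nucleus_intensity nucleus plateau intensity above background.
#' @param background constant offset in both channels.
#' @param noise_sd Gaussian read-noise SD; punctum SNR is
#'   `puncta_amplitude / noise_sd`.
#' @param min_separation_um minimum center-to-center distance between puncta
#'   of the same cell.
#' @param seed integer seed.
#' @return A list with integer matrices `nuclear` and `puncta` (16-bit range,
#'   row = y), `pixel_size_um`, and `truth`: `cells` (center, radius, area in
#'   um^2, puncta count) and `puncta` (cell id and positions in um).
#' @export
simulate_cell_image <- function(n_cells, puncta_per_cell = 0,
                                cell_radius_um = 5, nucleus_radius_um = 3,
                                pixel_size_um = 0.1,
                                image_size_px = c(256, 256),
                                puncta_sigma_um = 0.2,
                                puncta_amplitude = 3000,
                                nucleus_intensity = 20000,
                                background = 100, noise_sd = 20,
                                min_separation_um = 1,
                                seed = 1L) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  stopifnot(n_cells >= 0, length(image_size_px) == 2)
  puncta_per_cell <- rep_len(as.integer(puncta_per_cell), max(n_cells, 1))
  if (n_cells == 0) puncta_per_cell <- integer(0)

  W <- image_size_px[1] * pixel_size_um
  H <- image_size_px[2] * pixel_size_um

  local_seed(seed, {
    # non-overlapping cell placement; restart the whole configuration if a
    # sequential draw paints itself into a corner
    centers <- matrix(numeric(0), ncol = 2)
    for (attempt in 1:50) {
      centers <- matrix(numeric(0), ncol = 2)
      failed <- FALSE
      for (k in seq_len(n_cells)) {
        ok <- FALSE
        for (try in 1:500) {
          cx <- stats::runif(1, cell_radius_um, W - cell_radius_um)
          cy <- stats::runif(1, cell_radius_um, H - cell_radius_um)
          if (nrow(centers) == 0 ||
              all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
                  2 * cell_radius_um + 0.5)) {
            centers <- rbind(centers, c(cx, cy)); ok <- TRUE; break
          }
        }
        if (!ok) { failed <- TRUE; break }
      }
      if (!failed) break
    }
    if (failed) stop("could not place ", n_cells,
                     " non-overlapping cells after bounded retries")

    nx <- image_size_px[1]; ny <- image_size_px[2]
    # pixel center coordinates in um
    px <- (seq_len(nx) - 0.5) * pixel_size_um
    py <- (seq_len(ny) - 0.5) * pixel_size_um
    nuclear <- matrix(background, nrow = ny, ncol = nx)
    puncta_img <- matrix(background, nrow = ny, ncol = nx)

    cells <- NULL; spots <- NULL
    for (k in seq_len(n_cells)) {
      cx <- centers[k, 1]; cy <- centers[k, 2]
      d2 <- outer((py - cy)^2, (px - cx)^2, "+")
      nuclear[d2 <= nucleus_radius_um^2] <-
        background + nucleus_intensity
      # place puncta: inside cell with an edge margin, minimum separation
      np <- puncta_per_cell[k]
      pos <- matrix(numeric(0), ncol = 2)
      margin <- max(3 * puncta_sigma_um, 0.5)
      for (j in seq_len(np)) {
        placed <- FALSE
        for (try in 1:5000) {
          r <- (cell_radius_um - margin) * sqrt(stats::runif(1))
          th <- stats::runif(1, 0, 2 * pi)
          sx <- cx + r * cos(th); sy <- cy + r * sin(th)
          if (nrow(pos) == 0 ||
              all(sqrt((pos[, 1] - sx)^2 + (pos[, 2] - sy)^2) >=
                  min_separation_um)) {
            pos <- rbind(pos, c(sx, sy)); placed <- TRUE; break
          }
        }
        if (!placed) stop("could not place ", np, " puncta in cell ", k,
                          " with the requested minimum separation")
      }
      if (np > 0) {
        for (j in seq_len(np)) {
          gx <- exp(-(px - pos[j, 1])^2 / (2 * puncta_sigma_um^2))
          gy <- exp(-(py - pos[j, 2])^2 / (2 * puncta_sigma_um^2))
          puncta_img <- puncta_img + puncta_amplitude * outer(gy, gx)
        }
        spots <- rbind(spots, data.frame(cell = k, x_um = pos[, 1],
                                         y_um = pos[, 2]))
      }
      cells <- rbind(cells, data.frame(
        cell = k, center_x_um = cx, center_y_um = cy,
        radius_um = cell_radius_um,
        area_um2 = pi * cell_radius_um^2,
        puncta_count = np))
    }

    if (noise_sd > 0) {
      nuclear <- nuclear + matrix(stats::rnorm(nx * ny, sd = noise_sd), ny, nx)
      puncta_img <- puncta_img +
        matrix(stats::rnorm(nx * ny, sd = noise_sd), ny, nx)
    }
    clip16 <- function(m) matrix(as.integer(pmin(pmax(round(m), 0), 65535)),
                                 nrow = nrow(m))
    list(nuclear = clip16(nuclear), puncta = clip16(puncta_img),
         pixel_size_um = pixel_size_um,
         truth = list(
           cells = cells %||% data.frame(cell = integer(0),
                                         center_x_um = numeric(0),
                                         center_y_um = numeric(0),
                                         radius_um = numeric(0),
                                         area_um2 = numeric(0),
                                         puncta_count = integer(0)),
           puncta = spots %||% data.frame(cell = integer(0),
                                          x_um = numeric(0),
                                          y_um = numeric(0))))
  })
}

#' Write a simulated cell image pair to 16-bit TIFFs plus ground-truth JSON
#'
#' @param sim result of [simulate_cell_image()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_cell_image <- function(sim, dir, prefix = "cells") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    nuclear = file.path(dir, paste0(prefix, "_nuclear.tif")),
    puncta = file.path(dir, paste0(prefix, "_puncta.tif")),
    truth = file.path(dir, paste0(prefix, "_truth.json")))
  tiff::writeTIFF(sim$nuclear / 65535, paths$nuclear, bits.per.sample = 16)
  tiff::writeTIFF(sim$puncta / 65535, paths$puncta, bits.per.sample = 16)
  jsonlite::write_json(list(pixel_size_um = sim$pixel_size_um,
                            cells = sim$truth$cells, puncta = sim$truth$puncta),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a 16-bit single-plane TIFF as an integer matrix
#'
#' @param path TIFF file path.
#' @return Integer matrix in the 0..65535 range (row = y).
#' @export
read_image_16bit <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  storage.mode(img) <- "integer"
  img
}
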