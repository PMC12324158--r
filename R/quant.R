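#' Segment cells from a nuclear-stain image
#'
#' Nuclei are found by global Otsu thresholding and connected-component
#' labeling with a minimum-size filter; the cytoplasmic area of each cell is
#' then estimated by expanding every nucleus by a fixed radius, with
#' contested pixels (within reach of several nuclei) assigned to the nearest
#' nucleus (ties to the lowest label), so the cell masks always form a
#' partition.
#'
#' @param nuclear_image numeric/integer matrix (row = y).
#' @param expansion_um expansion radius from the nucleus boundary, um.
#' @param pixel_size_um pixel size in um (> 0).
#' @param min_nucleus_area_um2 nuclei smaller than this are discarded.
#' @return A list of class `cell_mask`: `labels` (integer matrix, 0 =
#'   background), `areas` (`data.frame` with `cell, area_um2`),
#'   `pixel_size_um`, `expansion_um`. Zero nuclei yields an empty result
#'   with a warning.
#' @export
segment_cells <- function(nuclear_image, expansion_um, pixel_size_um,
                          min_nucleus_area_um2 = 20) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  img <- nuclear_image / max(nuclear_image, 1)
  thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  nucmask <- img > thr
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(nucmask)))
  # minimum-size filter
  min_px <- min_nucleus_area_um2 / pixel_size_um^2
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= min_px)
  if (length(keep) == 0) {
    warning("no nuclei found")
    return(structure(list(labels = matrix(0L, nrow(nuclear_image),
                                          ncol(nuclear_image)),
                          areas = data.frame(cell = integer(0),
                                             area_um2 = numeric(0)),
                          pixel_size_um = pixel_size_um,
                          expansion_um = expansion_um),
                     class = "cell_mask"))
  }
  # relabel kept nuclei 1..k in original label order
  relab <- integer(length(sizes)); relab[keep] <- seq_along(keep)
  pos <- labels > 0
  labels[pos] <- relab[labels[pos]]

  # per-nucleus Euclidean distance maps; nearest-nucleus assignment within
  # the expansion radius (distance from outside pixels to the nucleus)
  k <- length(keep)
  exp_px <- expansion_um / pixel_size_um
  dist_stack <- array(Inf, dim = c(nrow(labels), ncol(labels), k))
  for (i in seq_len(k)) {
    # distmap: distance of foreground pixels to background; complement gives
    # distance of every pixel to nucleus i (0 inside the nucleus)
    dist_stack[, , i] <-
      EBImage::imageData(EBImage::distmap(EBImage::Image(labels != i)))
  }
  dmin <- apply(dist_stack, c(1, 2), min)
  amin <- apply(dist_stack, c(1, 2), which.min)  # ties -> lowest label
  cellmask <- matrix(0L, nrow(labels), ncol(labels))
  inside <- dmin <= exp_px
  cellmask[inside] <- as.integer(amin[inside])
  areas <- data.frame(cell = seq_len(k),
                      area_um2 = as.numeric(tabulate(cellmask[cellmask > 0],
                                                     nbins = k)) *
                        pixel_size_um^2)
  structure(list(labels = cellmask, areas = areas,
                 pixel_size_um = pixel_size_um, expansion_um = expansion_um),
            class = "cell_mask")
}

log_kernel <- function(sigma_px) {
  # scale-normalized negative Laplacian-of-Gaussian (bright blobs -> positive)
  half <- max(3L, ceiling(3 * sigma_px))
  ax <- seq(-half, half)
  g <- outer(ax, ax, function(x, y) exp(-(x^2 + y^2) / (2 * sigma_px^2)))
  g <- g / sum(g)
  lap <- outer(ax, ax, function(x, y)
    (x^2 + y^2 - 2 * sigma_px^2) / sigma_px^4 *
      exp(-(x^2 + y^2) / (2 * sigma_px^2)))
  lap <- lap - mean(lap)          # zero response to constant background
  -sigma_px^2 * lap / sum(g > 0)  # scale-normalized, sign-flipped
}

#' Detect diffraction-limited puncta inside cell masks
#'
#' Scale-space Laplacian-of-Gaussian spot detection: the image is filtered
#' with scale-normalized LoG kernels over a sigma range, local maxima of the
#' response above `threshold_k` robust noise SDs (median absolute deviation
#' of the response) are kept, detections are merged across scales (nearest
#' detections within one sigma keep the strongest response), and only
#' detections falling on a nonzero mask label are counted. Saturated images
#' are flagged with a warning.
#'
#' @param pla_image numeric/integer matrix (row = y), congruent with the mask.
#' @param mask a [segment_cells()] result or an integer label matrix.
#' @param pixel_size_um pixel size in um.
#' @param min_sigma_um,max_sigma_um detection scale range (Gaussian sigma,
#'   um); PLA puncta are diffraction-limited, default 0.2-1.0 um.
#' @param n_scales number of logarithmically spaced scales.
#' @param threshold_k detection threshold in robust noise SDs of the
#'   filtered response.
#' @return `data.frame` with one row per punctum: `cell, x_px, y_px, x_um,
#'   y_um, sigma_um, response`.
#' @export
detect_puncta <- function(pla_image, mask, pixel_size_um,
                          min_sigma_um = 0.2, max_sigma_um = 1.0,
                          n_scales = 4, threshold_k = 6) {
  labels <- if (inherits(mask, "cell_mask")) mask$labels else mask
  if (!all(dim(pla_image) == dim(labels)))
    stop("image and mask must be congruent")
  if (any(pla_image >= 65535))
    warning("saturated pixels present; intensities may be clipped")
  sigmas_um <- exp(seq(log(min_sigma_um), log(max_sigma_um),
                       length.out = n_scales))
  img <- EBImage::Image(pla_image)
  det <- NULL
  for (s_um in sigmas_um) {
    s_px <- s_um / pixel_size_um
    resp <- EBImage::imageData(EBImage::filter2(img, log_kernel(s_px)))
    # robust noise scale of the response, floored so that numerically flat
    # (noise-free) images do not fire on FFT ripple
    noise <- max(stats::mad(resp), 1e-6 * max(abs(resp)), 1e-12)
    thr <- threshold_k * noise
    # strict 8-neighbor local maxima above threshold, away from the border
    nr <- nrow(resp); nc <- ncol(resp)
    core <- resp[2:(nr - 1), 2:(nc - 1)]
    ismax <- core > thr
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ismax <- ismax & (core > resp[2:(nr - 1) + di, 2:(nc - 1) + dj])
    }
    hits <- which(ismax, arr.ind = TRUE)
    if (nrow(hits) > 0) {
      det <- rbind(det, data.frame(y_px = hits[, 1] + 1, x_px = hits[, 2] + 1,
                                   sigma_um = s_um,
                                   response = core[ismax]))
    }
  }
  empty <- data.frame(cell = integer(0), x_px = integer(0), y_px = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      sigma_um = numeric(0), response = numeric(0))
  if (is.null(det)) return(empty)

  # merge across scales: keep strongest response among detections closer
  # than the larger sigma of the pair
  det <- det[order(-det$response), ]
  keep <- rep(TRUE, nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!keep[i]) next
    if (i == nrow(det)) break
    j <- (i + 1):nrow(det)
    d_px <- sqrt((det$x_px[j] - det$x_px[i])^2 +
                 (det$y_px[j] - det$y_px[i])^2)
    merge_r <- pmax(det$sigma_um[j], det$sigma_um[i]) / pixel_size_um + 1
    keep[j][d_px <= merge_r] <- FALSE
  }
  det <- det[keep, , drop = FALSE]

  det$cell <- labels[cbind(det$y_px, det$x_px)]
  det <- det[det$cell > 0, , drop = FALSE]
  if (nrow(det) == 0) return(empty)
  det$x_um <- (det$x_px - 0.5) * pixel_size_um
  det$y_um <- (det$y_px - 0.5) * pixel_size_um
  rownames(det) <- NULL
  det[, c("cell", "x_px", "y_px", "x_um", "y_um", "sigma_um", "response")]
}

#' Per-cell puncta density
#'
#' Density is count / area (um^-2) per cell, the PLA readout normalized to
#' individual cell area; zero-area cells are excluded with a warning.
#'
#' @param counts `data.frame` with `cell, puncta_count`, or a detection table
#'   from [detect_puncta()] (counted per cell).
#' @param areas `data.frame` with `cell, area_um2` (e.g. from
#'   [segment_cells()]).
#' @return `data.frame` with `cell, area_um2, puncta_count, puncta_density`.
#' @export
puncta_density <- function(counts, areas) {
  if (!"puncta_count" %in% names(counts)) {
    counts <- as.data.frame(table(factor(counts$cell,
                                         levels = areas$cell)))
    names(counts) <- c("cell", "puncta_count")
    counts$cell <- as.integer(as.character(counts$cell))
  }
  out <- merge(areas, counts, by = "cell", all.x = TRUE)
  out$puncta_count[is.na(out$puncta_count)] <- 0L
  bad <- out$area_um2 <= 0
  if (any(bad)) {
    warning("excluded ", sum(bad), " zero-area cell(s)")
    out <- out[!bad, , drop = FALSE]
  }
  out$puncta_density <- out$puncta_count / out$area_um2
  rownames(out) <- NULL
  out
}

#' Exposure-normalized TIRF intensity per cell
#'
#' Background-subtracted integrated density over the cell mask divided by
#' the exposure time: `sum(pixel - bg_mean) / exposure_ms`, so values from
#' acquisitions at different exposures (5-100 ms) are comparable. The
#' background region must not overlap the mask.
#'
#' @param image numeric/integer matrix.
#' @param bg_region logical matrix marking background pixels.
#' @param mask logical matrix (one cell) or integer label matrix (per-cell
#'   results).
#' @param exposure_ms exposure time in ms (> 0).
#' @return `data.frame` with `cell, integrated_density, bg_mean, exposure_ms,
#'   normalized_intensity` (a.u./ms).
#' @export
tirf_intensity <- function(image, bg_region, mask, exposure_ms) {
  if (exposure_ms <= 0) stop("exposure_ms must be > 0")
  labels <- if (is.logical(mask)) ifelse(mask, 1L, 0L) else mask
  if (!all(dim(image) == dim(labels)) || !all(dim(image) == dim(bg_region)))
    stop("image, mask and bg_region must be congruent")
  if (any(bg_region & labels > 0))
    stop("background region overlaps the cell mask")
  if (!any(bg_region)) stop("empty background region")
  bg_mean <- mean(image[bg_region])
  ids <- sort(unique(labels[labels > 0]))
  do.call(rbind, lapply(ids, function(id) {
    v <- image[labels == id] - bg_mean
    data.frame(cell = id, integrated_density = sum(v), bg_mean = bg_mean,
               exposure_ms = exposure_ms,
               normalized_intensity = sum(v) / exposure_ms)
  }))
}

#' Normalize per-cell values to a reference condition
#'
#' Divides a value column by the mean of the reference condition (e.g. TIRF
#' intensities normalized to the wild-type group mean).
#'
#' @param df `data.frame` with a `condition` column.
#' @param value_col name of the value column.
#' @param reference_condition condition whose mean defines 1.0.
#' @return The input with an added `<value_col>_normalized` column.
#' @export
normalize_to_reference <- function(df, value_col, reference_condition) {
  ref <- df[[value_col]][df$condition == reference_condition]
  if (length(ref) == 0)
    stop("no rows for reference condition '", reference_condition, "'")
  df[[paste0(value_col, "_normalized")]] <- df[[value_col]] / mean(ref)
  df
}

#' Immunoblot densitometry ratios normalized to a reference condition
#'
#' Per lane, the target-band intensity divided by the loading-control band
#' (tubulin for total lysate, ATP1A1 for membrane fractions); the ratio is
#' then normalized to the mean ratio of the reference (wild-type) lanes.
#'
#' @param bands `data.frame` with columns `lane, condition, target, loading`.
#' @param reference_condition condition normalized to 1.0 on average.
#' @return The input with added `ratio` and `normalized_to_ref` columns.
#' @export
densitometry_ratio <- function(bands, reference_condition) {
  stopifnot(all(c("lane", "condition", "target", "loading") %in% names(bands)))
  if (any(bands$loading <= 0)) stop("loading-band intensities must be > 0")
  bands$ratio <- bands$target / bands$loading
  ref <- bands$ratio[bands$condition == reference_condition]
  if (length(ref) == 0)
    stop("no lanes for reference condition '", reference_condition, "'")
  bands$normalized_to_ref <- bands$ratio / mean(ref)
  bands
}
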