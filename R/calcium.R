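#' Frame-wise background subtraction of a fluorescence series
#'
#' Subtracts a background-ROI series from the cell-ROI series frame by frame
#' (the ImageJ "BG subtraction from ROI" operation).
#'
#' @param F cell-ROI fluorescence series (a.u.).
#' @param F_bg background-ROI series, same length.
#' @return `F - F_bg`.
#' @export
background_subtract <- function(F, F_bg) {
  if (length(F) != length(F_bg))
    stop("F and F_bg must have the same length")
  F - F_bg
}

#' Compute a delta-F/F0 series
#'
#' `F0` is the mean of the corrected series over the baseline window (the
#' pre-stimulus period); `dff(t) = (F(t) - F0) / F0`. A non-positive `F0`
#' signals a bad background subtraction and is an error. Negative dff values
#' (bleaching/undershoot) are retained.
#'
#' @param corrected background-subtracted fluorescence series.
#' @param time time in s, same length.
#' @param baseline_window length-2 window in s; by convention everything
#'   before stimulus onset.
#' @return A list with `dff` (series), `F0`, `time`, `baseline_window`.
#' @export
delta_f_over_f0 <- function(corrected, time, baseline_window) {
  stopifnot(length(corrected) == length(time))
  idx <- window_idx(time, baseline_window)
  F0 <- mean(corrected[idx])
  if (!is.finite(F0) || F0 <= 0)
    stop("baseline F0 must be > 0 (got ", signif(F0, 4),
         "); check background subtraction")
  list(dff = (corrected - F0) / F0, F0 = F0, time = time,
       baseline_window = baseline_window)
}

#' Peak and area under the curve of a delta-F/F0 response
#'
#' Peak is the maximum dff within the response window; AUC is the
#' trapezoidal integral of dff over the window (units s). Per-cell
#' normalization of AUC across voltages is done by [normalize_auc()].
#'
#' @param dff delta-F/F0 series (or the list from [delta_f_over_f0()]).
#' @param time time in s (ignored if `dff` is a list carrying its own time).
#' @param response_window length-2 window in s.
#' @param smooth_s moving-average width in s applied before peak picking
#'   (0 = raw maximum). Raw maxima are upward-biased on noisy traces; a width
#'   of ~1.25 s (5 frames at 4 Hz), short against the transient decay,
#'   removes that bias while attenuating the true peak by under 1%. The AUC
#'   is always computed on the raw series.
#' @return A list with `peak` (dimensionless) and `auc` (s).
#' @export
peak_and_auc <- function(dff, time = NULL, response_window, smooth_s = 0) {
  if (is.list(dff)) { time <- dff$time; dff <- dff$dff }
  stopifnot(length(dff) == length(time))
  idx <- window_idx(time, response_window)
  peak_series <- dff
  if (smooth_s > 0) {
    dt <- time[2] - time[1]
    k <- max(1L, as.integer(2 * floor(smooth_s / dt / 2) + 1))  # odd
    if (k > 1)
      peak_series <- as.numeric(stats::filter(dff, rep(1 / k, k), sides = 2))
  }
  list(peak = max(peak_series[idx], na.rm = TRUE),
       auc = pracma::trapz(time[idx], dff[idx]))
}

#' Per-cell normalized AUC across voltages
#'
#' Normalizes each cell's AUC values to that cell's maximum-magnitude AUC
#' across voltages (mirroring the I-V normalization); set
#' `reference = "none"` for absolute AUC.
#'
#' @param results `data.frame` with columns `cell, voltage_mV, auc`.
#' @param reference `"per_cell_max"` (default) or `"none"`.
#' @return The input with an added `auc_normalized` column and a
#'   `normalization` attribute.
#' @export
normalize_auc <- function(results, reference = c("per_cell_max", "none")) {
  reference <- match.arg(reference)
  stopifnot(all(c("cell", "voltage_mV", "auc") %in% names(results)))
  if (reference == "none") {
    results$auc_normalized <- results$auc
  } else {
    results$auc_normalized <- stats::ave(results$auc, results$cell,
                                         FUN = function(a) a / max(abs(a)))
  }
  attr(results, "normalization") <- reference
  results
}
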