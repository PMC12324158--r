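#' Construct a whole-cell current trace
#'
#' Container for one glutamate-evoked sweep. Inward current is negative
#' (standard patch-clamp convention); time must be uniformly sampled (checked
#' to 1 ppm) and the baseline window must precede the stimulus onset.
#'
#' @param time time in s, strictly increasing and uniform.
#' @param current current in pA.
#' @param voltage_mV holding potential in mV.
#' @param stim_onset,stim_duration stimulus window in s.
#' @param baseline_window length-2 window (s) used for baseline estimation;
#'   defaults to everything before `stim_onset`.
#' @param cell optional cell identifier.
#' @return A list of class `current_trace`.
#' @export
current_trace <- function(time, current, voltage_mV = NA_real_,
                          stim_onset, stim_duration,
                          baseline_window = c(min(time), stim_onset),
                          cell = NA_character_) {
  stopifnot(length(time) == length(current), length(time) >= 2)
  dts <- diff(time)
  if (any(dts <= 0)) stop("time must be strictly increasing")
  if (max(dts) - min(dts) > 1e-6 * mean(dts))
    stop("time must be uniformly sampled (within 1 ppm)")
  if (baseline_window[2] > stim_onset + 1e-12)
    stop("baseline_window must precede stim_onset")
  structure(list(time = as.numeric(time), current = as.numeric(current),
                 voltage_mV = voltage_mV, stim_onset = stim_onset,
                 stim_duration = stim_duration,
                 baseline_window = as.numeric(baseline_window),
                 cell = cell),
            class = "current_trace")
}

window_idx <- function(time, window) {
  idx <- which(time >= window[1] - 1e-12 & time <= window[2] + 1e-12)
  if (length(idx) == 0) stop("window [", window[1], ", ", window[2],
                             "] s lies outside the trace")
  idx
}

#' Baseline-correct a current trace
#'
#' Subtracts the pre-stimulus baseline so the mean current over the baseline
#' window is zero. The default is a constant offset (mean of the baseline
#' window); `mode = "linear"` fits and subtracts a linear drift estimated on
#' the baseline window instead.
#'
#' @param trace a [current_trace()].
#' @param mode `"constant"` (default) or `"linear"`.
#' @return The corrected `current_trace`.
#' @export
baseline_correct <- function(trace, mode = c("constant", "linear")) {
  stopifnot(inherits(trace, "current_trace"))
  mode <- match.arg(mode)
  idx <- window_idx(trace$time, trace$baseline_window)
  if (mode == "constant") {
    trace$current <- trace$current - mean(trace$current[idx])
  } else {
    fit <- stats::lm.fit(cbind(1, trace$time[idx]),
                         trace$current[idx])
    trace$current <- trace$current -
      (fit$coefficients[1] + fit$coefficients[2] * trace$time)
  }
  trace
}

#' Split a sweep into inward and outward charge
#'
#' Separates the baseline-corrected current by instantaneous sign (not by
#' time segmentation) and integrates each part by the trapezoidal rule over
#' the analysis window:
#' \deqn{Q_{in} = |\int \min(I, 0)\,dt|, \quad Q_{out} = \int \max(I, 0)\,dt,}
#' in pC (pA s). The coupling ratio is `Q_out / Q_in`, the study's
#' functional-coupling statistic; when `Q_in = 0` the ratio is flagged
#' undefined rather than propagating NaN. Peaks are the extrema of the
#' current within the window.
#'
#' @param trace a baseline-corrected [current_trace()].
#' @param window length-2 analysis window in s; default `stim_onset` to
#'   `stim_onset + 5` (the outward BK component outlasts the 1-s glutamate
#'   pulse, so the window must capture its decay).
#' @return A list of class `charge_result`: `Q_in_pC`, `Q_out_pC`,
#'   `coupling_ratio`, `ratio_defined`, `peak_in_pA` (<= 0), `peak_out_pA`
#'   (>= 0), `window`, `voltage_mV`, `cell`.
#' @export
split_charges <- function(trace,
                          window = trace$stim_onset + c(0, 5)) {
  stopifnot(inherits(trace, "current_trace"))
  window <- c(max(window[1], min(trace$time)),
              min(window[2], max(trace$time)))
  idx <- window_idx(trace$time, window)
  t <- trace$time[idx]; I <- trace$current[idx]
  q_in <- abs(pracma::trapz(t, pmin(I, 0)))
  q_out <- pracma::trapz(t, pmax(I, 0))
  defined <- q_in > 0
  structure(list(Q_in_pC = q_in, Q_out_pC = q_out,
                 coupling_ratio = if (defined) q_out / q_in else NA_real_,
                 ratio_defined = defined,
                 peak_in_pA = min(c(I, 0)), peak_out_pA = max(c(I, 0)),
                 window = window, voltage_mV = trace$voltage_mV,
                 cell = trace$cell),
            class = "charge_result")
}

#' One-row tidy summary of a sweep's charge analysis
#'
#' Convenience wrapper: baseline-corrects, splits charges and returns a tidy
#' row, the unit consumed by [iv_curve()], [qv_curve()] and
#' [coupling_curve()].
#'
#' @param trace a [current_trace()].
#' @param window analysis window passed to [split_charges()].
#' @param baseline_mode passed to [baseline_correct()].
#' @return A one-row `data.frame` with columns
#'   `cell, voltage_mV, peak_in_pA, peak_out_pA, Q_in_pC, Q_out_pC,
#'   coupling_ratio, ratio_defined`.
#' @export
analyze_sweep <- function(trace, window = trace$stim_onset + c(0, 5),
                          baseline_mode = "constant") {
  res <- split_charges(baseline_correct(trace, baseline_mode), window)
  data.frame(cell = res$cell, voltage_mV = res$voltage_mV,
             peak_in_pA = res$peak_in_pA, peak_out_pA = res$peak_out_pA,
             Q_in_pC = res$Q_in_pC, Q_out_pC = res$Q_out_pC,
             coupling_ratio = res$coupling_ratio,
             ratio_defined = res$ratio_defined,
             stringsAsFactors = FALSE)
}

sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0

curve_aggregate <- function(per_cell, value_col) {
  voltages <- sort(unique(per_cell$voltage_mV))
  agg <- do.call(rbind, lapply(voltages, function(v) {
    vals <- per_cell[[value_col]][per_cell$voltage_mV == v]
    vals <- vals[!is.na(vals)]
    data.frame(voltage_mV = v, mean = mean(vals), sem = sem(vals),
               n = length(vals))
  }))
  agg
}

normalize_per_cell <- function(results, value_col, out_col) {
  cells <- unique(results$cell)
  keep <- vector("list", length(cells))
  dropped <- character(0)
  for (i in seq_along(cells)) {
    rows <- results[results$cell == cells[i], ]
    ref <- max(abs(rows[[value_col]]), na.rm = TRUE)
    if (!is.finite(ref) || ref == 0) {
      dropped <- c(dropped, as.character(cells[i]))
      next
    }
    rows[[out_col]] <- rows[[value_col]] / ref
    keep[[i]] <- rows
  }
  if (length(dropped) > 0)
    warning("excluded all-zero cell(s): ", paste(dropped, collapse = ", "))
  do.call(rbind, keep)
}

#' Normalized current-voltage (I-V) relationship
#'
#' Per cell, the peak inward current at each voltage is normalized to that
#' cell's maximum |peak| across voltages (so the normalization reference is
#' the per-cell maximum magnitude, recorded in the output); cells with no
#' nonzero peak are excluded with a warning. Aggregate is mean +/- SEM per
#' voltage with n = cells.
#'
#' @param results tidy per-sweep rows from [analyze_sweep()] (>= 1 cell,
#'   >= 2 voltages per cell).
#' @return A list of class `curve_set`: `per_cell`, `aggregate`
#'   (`voltage_mV, mean, sem, n`) and `normalization`.
#' @export
iv_curve <- function(results) {
  check_curve_input(results)
  per_cell <- normalize_per_cell(results, "peak_in_pA", "value")
  structure(list(per_cell = per_cell,
                 aggregate = curve_aggregate(per_cell, "value"),
                 normalization = "per-cell max |peak_in_pA|"),
            class = "curve_set")
}

#' Normalized charge-voltage (Q-V) relationship
#'
#' As [iv_curve()], computed on the inward charge `Q_in_pC` (always >= 0 by
#' construction, independent of sign convention).
#'
#' @inheritParams iv_curve
#' @return A `curve_set` as in [iv_curve()].
#' @export
qv_curve <- function(results) {
  check_curve_input(results)
  per_cell <- normalize_per_cell(results, "Q_in_pC", "value")
  structure(list(per_cell = per_cell,
                 aggregate = curve_aggregate(per_cell, "value"),
                 normalization = "per-cell max Q_in_pC"),
            class = "curve_set")
}

#' Coupling-ratio (Q_out/Q_in) versus voltage
#'
#' Aggregates raw, un-normalized coupling ratios per voltage (mean +/- SEM,
#' n = cells with a defined ratio); sweeps with undefined ratios (Q_in = 0)
#' are dropped per voltage and their count reported.
#'
#' @inheritParams iv_curve
#' @return A list of class `curve_set` with `per_cell`, `aggregate`
#'   (`voltage_mV, mean, sem, n, n_undefined`).
#' @export
coupling_curve <- function(results) {
  check_curve_input(results)
  per_cell <- results
  per_cell$value <- per_cell$coupling_ratio
  voltages <- sort(unique(per_cell$voltage_mV))
  agg <- do.call(rbind, lapply(voltages, function(v) {
    rows <- per_cell[per_cell$voltage_mV == v, ]
    ok <- rows$ratio_defined & !is.na(rows$value)
    data.frame(voltage_mV = v, mean = mean(rows$value[ok]),
               sem = sem(rows$value[ok]), n = sum(ok),
               n_undefined = sum(!ok))
  }))
  structure(list(per_cell = per_cell, aggregate = agg,
                 normalization = "none (raw Q_out/Q_in)"),
            class = "curve_set")
}

check_curve_input <- function(results) {
  need <- c("cell", "voltage_mV")
  missing <- setdiff(need, names(results))
  if (length(missing) > 0)
    stop("missing columns: ", paste(missing, collapse = ", "))
  if (nrow(results) == 0) stop("no sweeps provided")
  nv <- tapply(results$voltage_mV, results$cell,
               function(v) length(unique(v)))
  if (all(nv < 2)) stop("need >= 2 voltages per cell")
  invisible(TRUE)
}

#' Read / write a current sweep as CSV plus JSON metadata
#'
#' The CSV holds `time_s,current_pA`; the JSON sidecar holds the holding
#' potential, stimulus window and optional cell id (and, for simulated
#' sweeps, ground-truth charges).
#'
#' @param csv_path path to the sweep CSV.
#' @param json_path path to the metadata JSON; defaults to the CSV path with
#'   a `.json` extension.
#' @return A [current_trace()]; ground-truth fields, when present, are kept
#'   in the `meta` attribute.
#' @export
read_current_trace <- function(csv_path,
                               json_path = sub("\\.csv$", ".json", csv_path)) {
  d <- utils::read.csv(csv_path)
  if (!all(c("time_s", "current_pA") %in% names(d)))
    stop("sweep CSV must have columns time_s,current_pA")
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  tr <- current_trace(d$time_s, d$current_pA,
                      voltage_mV = meta$voltage_mV %||% NA_real_,
                      stim_onset = meta$stim_onset_s,
                      stim_duration = meta$stim_duration_s,
                      cell = meta$cell %||% NA_character_)
  attr(tr, "meta") <- meta
  tr
}

#' @rdname read_current_trace
#' @param trace a [current_trace()] to write.
#' @param extra named list merged into the JSON metadata (e.g. ground-truth
#'   charges).
#' @export
write_current_trace <- function(trace, csv_path,
                                json_path = sub("\\.csv$", ".json", csv_path),
                                extra = list()) {
  utils::write.csv(data.frame(time_s = trace$time,
                              current_pA = trace$current),
                   csv_path, row.names = FALSE)
  meta <- c(list(voltage_mV = trace$voltage_mV,
                 stim_onset_s = trace$stim_onset,
                 stim_duration_s = trace$stim_duration,
                 cell = trace$cell), extra)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}
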