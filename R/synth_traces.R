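#' Configuration for the glutamate-evoked current simulator
#'
#' Phenomenological model of a whole-cell sweep: a fast inward (NMDAR-like)
#' component followed by a delayed, slower outward (BK-like) component, both
#' from the same double-exponential family
#' \deqn{g(t) = (1 - e^{-t/\tau_{rise}}) e^{-t/\tau_{decay}}, t \ge 0,}
#' so each component's charge has the closed form
#' \eqn{A \tau_{decay}^2 / (\tau_{rise} + \tau_{decay})} (pA s = pC), used as
#' the ground-truth oracle. The inward component is applied with negative
#' sign (standard patch-clamp convention: inward current negative).
#'
#' @param dt sample interval in s (default 1e-4 s, i.e. 10 kHz).
#' @param duration sweep length in s.
#' @param stim_onset,stim_duration glutamate application window in s
#'   (default a 1-s pulse starting at 1 s).
#' @param inward_amplitude amplitude scale of the inward component, pA
#'   (reported positive, applied negative).
#' @param inward_rise,inward_decay inward time constants in s (`rise = 0`
#'   gives a single exponential).
#' @param outward_amplitude,outward_delay,outward_rise,outward_decay outward
#'   component: amplitude (pA), onset delay after `stim_onset` (s) and time
#'   constants (s).
#' @param noise_sd Gaussian current noise SD in pA.
#' @param voltage_mV holding potential metadata.
#' @param seed integer seed.
#' @return A validated list of class `trace_sim_config`.
#' @export
trace_sim_config <- function(dt = 1e-4, duration = 10,
                             stim_onset = 1, stim_duration = 1,
                             inward_amplitude = 1000,
                             inward_rise = 0.05, inward_decay = 0.5,
                             outward_amplitude = 400,
                             outward_delay = 0.3,
                             outward_rise = 0.3, outward_decay = 1.5,
                             noise_sd = 2, voltage_mV = 40, seed = 1L) {
  if (dt <= 0) stop("dt must be > 0")
  if (stim_onset < 0 || stim_onset + stim_duration > duration)
    stop("stimulus window must lie inside [0, duration]")
  if (inward_decay <= 0 || outward_decay <= 0)
    stop("decay time constants must be > 0")
  if (inward_rise < 0 || outward_rise < 0) stop("rise constants must be >= 0")
  if (inward_amplitude < 0 || outward_amplitude < 0)
    stop("amplitudes are magnitudes and must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (outward_delay < 0) stop("outward_delay must be >= 0")
  structure(as.list(environment()), class = "trace_sim_config")
}

biexp_shape <- function(t, onset, rise, decay) {
  # response begins strictly after onset so the onset sample itself still
  # belongs to the baseline
  u <- t - onset
  s <- numeric(length(t))
  i <- u > 0
  if (rise > 0) s[i] <- (1 - exp(-u[i] / rise)) * exp(-u[i] / decay)
  else s[i] <- exp(-u[i] / decay)
  s
}

biexp_charge <- function(amplitude, rise, decay) {
  # closed form of A * integral_0^inf (1 - e^(-t/r)) e^(-t/d) dt = A d^2/(r+d)
  amplitude * decay^2 / (rise + decay)
}

#' Simulate a glutamate-evoked current sweep with known component charges
#'
#' @param cfg a [trace_sim_config()].
#' @return A list with `trace` (a [current_trace()]), `true_Q_in_pC` and
#'   `true_Q_out_pC`, the closed-form charges of each component alone. With
#'   `noise_sd = 0` and temporally disjoint components the measured charge
#'   split equals the true charges up to trapezoidal-integration error.
#' @export
simulate_current_trace <- function(cfg) {
  stopifnot(inherits(cfg, "trace_sim_config"))
  local_seed(cfg$seed, {
    time <- seq(0, cfg$duration, by = cfg$dt)
    inward <- cfg$inward_amplitude *
      biexp_shape(time, cfg$stim_onset, cfg$inward_rise, cfg$inward_decay)
    outward <- cfg$outward_amplitude *
      biexp_shape(time, cfg$stim_onset + cfg$outward_delay,
                  cfg$outward_rise, cfg$outward_decay)
    noise <- if (cfg$noise_sd > 0) stats::rnorm(length(time), sd = cfg$noise_sd)
             else 0
    current <- -inward + outward + noise
    trace <- current_trace(time, current, voltage_mV = cfg$voltage_mV,
                           stim_onset = cfg$stim_onset,
                           stim_duration = cfg$stim_duration,
                           baseline_window = c(0, cfg$stim_onset))
    list(trace = trace,
         true_Q_in_pC = biexp_charge(cfg$inward_amplitude, cfg$inward_rise,
                                     cfg$inward_decay),
         true_Q_out_pC = biexp_charge(cfg$outward_amplitude, cfg$outward_rise,
                                      cfg$outward_decay))
  })
}

#' Simulate a delta-F/F0-style fluorescence transient
#'
#' The emitted series is `F(t) = f0 * (1 + peak_dff * s(t)) + bg + noise`
#' together with a background ROI series `F_bg = bg + noise`, where the
#' response shape `s(t)` peaks at exactly 1, so the ground-truth peak
#' delta-F/F0 equals `peak_dff`. Shapes: `"biexp"` (rise/decay transient,
#' peak-normalized analytically) or `"triangle"` (symmetric triangle of the
#' given base, whose delta-F/F0 area is exactly `peak_dff * base / 2`).
#'
#' @param f0 baseline fluorescence (a.u.), must be > 0.
#' @param peak_dff ground-truth peak delta-F/F0 (dimensionless).
#' @param dt sample interval in s (default 0.25 s, 4-Hz acquisition).
#' @param duration recording length in s.
#' @param stim_onset response onset in s.
#' @param shape `"biexp"` or `"triangle"`.
#' @param rise,decay time constants (s) for the biexp shape.
#' @param base triangle base width (s) for the triangle shape.
#' @param bg constant background level added to both series (a.u.).
#' @param noise_sd Gaussian noise SD (a.u.), applied independently to F and
#'   the background ROI.
#' @param seed integer seed.
#' @return A list with `time`, `F`, `F_bg`, `stim_onset`, and ground truth
#'   `true_peak_dff` and `true_auc` (s; integral of delta-F/F0 over the full
#'   response support).
#' @export
simulate_fluorescence_trace <- function(f0, peak_dff, dt = 0.25, duration = 60,
                                        stim_onset = 10, shape = "biexp",
                                        rise = 1, decay = 8, base = 10,
                                        bg = 0, noise_sd = 0, seed = 1L) {
  if (f0 <= 0) stop("f0 must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  shape <- match.arg(shape, c("biexp", "triangle"))
  local_seed(seed, {
    time <- seq(0, duration, by = dt)
    if (shape == "biexp") {
      stopifnot(rise > 0, decay > 0)
      # peak of (1-e^(-u/r))e^(-u/d) is at u* = r log(1 + d/r)
      ustar <- rise * log(1 + decay / rise)
      smax <- (1 - exp(-ustar / rise)) * exp(-ustar / decay)
      s <- biexp_shape(time, stim_onset, rise, decay) / smax
      true_auc <- peak_dff * (decay^2 / (rise + decay)) / smax
    } else {
      stopifnot(base > 0)
      u <- time - stim_onset
      s <- pmax(0, 1 - abs(u - base / 2) / (base / 2))
      true_auc <- peak_dff * base / 2
    }
    F_sig <- f0 * (1 + peak_dff * s) + bg
    if (noise_sd > 0) {
      F_sig <- F_sig + stats::rnorm(length(time), sd = noise_sd)
      F_bg <- bg + stats::rnorm(length(time), sd = noise_sd)
    } else {
      F_bg <- rep(bg, length(time))
    }
    list(time = time, F = F_sig, F_bg = F_bg, stim_onset = stim_onset,
         true_peak_dff = peak_dff, true_auc = true_auc)
  })
}
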