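#' Measure an eEPSC component amplitude from a sweep
#'
#' AMPAR amplitudes are read as the peak of the baseline-subtracted current
#' in a post-stimulus window at -70 mV; NMDAR amplitudes as the
#' baseline-subtracted current 35 ms after stimulation onset at +40 mV
#' (`method = "t35"`), where the fast AMPAR component has decayed, or as the
#' peak for pharmacologically isolated NMDAR currents. The baseline is the
#' mean current in the 10 ms before stimulation; reported amplitudes are
#' magnitudes (inward currents are negative in raw traces).
#'
#' At sampling rates of 10 kHz and above the 35-ms value uses the nearest
#' sample; below that it is linearly interpolated.
#'
#' @param trace A [sweep_trace()].
#' @param component `"AMPA"` or `"NMDA"`.
#' @param method `"peak"` or `"t35"`. `t35` is only valid at +40 mV;
#'   `peak` requires -70 mV (or negative holding) for AMPA. Set
#'   `check_holding = FALSE` to lift the consistency check (e.g. isolated
#'   NMDAR currents recorded at -70 mV in magnesium-free solution).
#' @param peak_window Post-stimulus search window for the peak, seconds
#'   (default `c(0, 0.1)`).
#' @param baseline_window Pre-stimulus baseline interval, seconds before
#'   onset (default 0.01).
#' @param t_offset Read-out latency for `t35`, seconds (default 0.035).
#' @param check_holding Enforce the method/holding pairing (default TRUE).
#' @return A list of class `epsc_measurement`: `component`, `method`,
#'   `amplitude` (pA, magnitude), `holding`, `stim_intensity`.
#' @export
measure_component <- function(trace, component = c("AMPA", "NMDA"),
                              method = c("peak", "t35"),
                              peak_window = c(0, 0.1), baseline_window = 0.01,
                              t_offset = 0.035, check_holding = TRUE) {
  stopifnot(inherits(trace, "sweep_trace"))
  component <- match.arg(component)
  method <- match.arg(method)
  if (check_holding) {
    if (method == "t35" && !(component == "NMDA" && trace$holding_potential > 0))
      stop_invalid("t35 read-out is defined for NMDA at +40 mV",
                   class = "habtrap_invalid_measurement")
    if (method == "peak" && component == "AMPA" && trace$holding_potential >= 0)
      stop_invalid("AMPA peak is read at negative holding (-70 mV)",
                   class = "habtrap_invalid_measurement")
  }
  tt <- trace$time; cur <- trace$current; on <- trace$stim_onset
  base_idx <- tt >= on - baseline_window & tt < on
  baseline <- if (any(base_idx)) mean(cur[base_idx]) else 0
  y <- cur - baseline
  amp <- if (method == "peak") {
    win <- tt >= on + peak_window[1L] & tt <= on + peak_window[2L]
    max(abs(y[win]))
  } else {
    t35 <- on + t_offset
    if (trace$sampling_rate >= 10000) {
      abs(y[which.min(abs(tt - t35))])
    } else {
      abs(stats::approx(tt, y, xout = t35)$y)
    }
  }
  structure(list(component = component, method = method, amplitude = amp,
                 holding = trace$holding_potential,
                 stim_intensity = trace$stim_intensity),
            class = "epsc_measurement")
}

#' NMDA/AMPA ratio at one stimulation intensity
#'
#' Ratio of the NMDAR amplitude (35 ms post-stimulus at +40 mV) to the
#' AMPAR peak (at -70 mV), each averaged across its sweeps (recordings
#' average three or more sweeps per condition, at 1.5 mA by convention).
#'
#' @param nmda_sweeps List of [sweep_trace()] at +40 mV.
#' @param ampa_sweeps List of [sweep_trace()] at -70 mV.
#' @param ... Passed to [measure_component()].
#' @return The dimensionless ratio.
#' @export
nmda_ampa_ratio <- function(nmda_sweeps, ampa_sweeps, ...) {
  if (inherits(nmda_sweeps, "sweep_trace")) nmda_sweeps <- list(nmda_sweeps)
  if (inherits(ampa_sweeps, "sweep_trace")) ampa_sweeps <- list(ampa_sweeps)
  nmda <- mean(vapply(nmda_sweeps, function(s)
    measure_component(s, "NMDA", "t35", ...)$amplitude, numeric(1L)))
  ampa <- mean(vapply(ampa_sweeps, function(s)
    measure_component(s, "AMPA", "peak", ...)$amplitude, numeric(1L)))
  if (ampa == 0)
    stop_invalid("AMPA amplitude is zero; ratio undefined",
                 class = "habtrap_undefined_ratio")
  nmda / ampa
}

#' Input-output curve and large-response prevalence
#'
#' Mean amplitude per stimulation intensity (the standard 0.25-1.50 mA
#' series in 0.25-mA steps) plus, when requested, the fraction of neurons
#' whose amplitude at the reference intensity strictly exceeds a threshold
#' (10 pA by default).
#'
#' @param measurements A data.frame with columns `neuron_id`,
#'   `intensity_mA`, `amplitude_pA` (one row per averaged measurement).
#' @param prevalence_threshold Threshold in pA for the prevalence statistic
#'   (default 10); set to `NULL` to skip.
#' @param reference_intensity Intensity (mA) at which prevalence is
#'   evaluated (default 1.5).
#' @return A list of class `io_curve`: `intensities`, `mean_amplitude`,
#'   `n`, and (unless skipped) `prevalence` with the fraction of neurons
#'   above threshold at the reference intensity.
#' @export
build_io_curve <- function(measurements, prevalence_threshold = 10,
                           reference_intensity = 1.5) {
  req <- c("neuron_id", "intensity_mA", "amplitude_pA")
  if (!all(req %in% names(measurements)))
    stop_invalid("measurements must have columns neuron_id, intensity_mA, amplitude_pA")
  if (!nrow(measurements)) stop_invalid("no measurements supplied")
  agg <- stats::aggregate(amplitude_pA ~ intensity_mA, data = measurements, mean)
  cnt <- stats::aggregate(amplitude_pA ~ intensity_mA, data = measurements, length)
  out <- list(intensities = agg$intensity_mA, mean_amplitude = agg$amplitude_pA,
              n = cnt$amplitude_pA)
  if (!is.null(prevalence_threshold)) {
    at_ref <- measurements[abs(measurements$intensity_mA - reference_intensity) < 1e-9, ]
    if (!nrow(at_ref))
      stop_invalid(sprintf("no measurements at the %g mA reference intensity",
                           reference_intensity))
    per_neuron <- tapply(at_ref$amplitude_pA, at_ref$neuron_id, mean)
    out$prevalence <- mean(per_neuron > prevalence_threshold)
    out$n_neurons <- length(per_neuron)
  }
  class(out) <- "io_curve"
  out
}

#' Washout series container
#'
#' Normalized test-pulse amplitudes across the baseline / wash-in / washout
#' epochs of a drug-washout experiment, with test pulses at a uniform
#' interval (10 s by default).
#'
#' @param pulse_times Pulse times (s), uniformly spaced.
#' @param normalized_amplitude Amplitude per pulse, as a fraction of the
#'   baseline mean.
#' @param epochs Named list of `c(start, end)` intervals (s):
#'   `baseline`, `wash_in`, `washout`.
#' @param drug,concentration Metadata: drug label and bath concentration
#'   (uM).
#' @return An object of class `washout_series`.
#' @export
washout_series <- function(pulse_times, normalized_amplitude, epochs,
                           drug = "none", concentration = 0) {
  if (length(pulse_times) != length(normalized_amplitude))
    stop_invalid("pulse_times and normalized_amplitude must have equal length")
  d <- diff(pulse_times)
  if (length(d) && (max(d) - min(d)) > 1e-6 * max(d))
    stop_invalid("pulse_times must be uniformly spaced")
  for (nm in c("baseline", "wash_in", "washout"))
    if (is.null(epochs[[nm]])) stop_invalid(paste0("epochs must include `", nm, "`"))
  structure(list(pulse_times = as.numeric(pulse_times),
                 normalized_amplitude = as.numeric(normalized_amplitude),
                 epochs = epochs, drug = drug, concentration = concentration),
            class = "washout_series")
}

#' Normalize raw washout amplitudes to the baseline epoch
#'
#' Every amplitude is divided by the mean amplitude of the baseline epoch,
#' so the baseline-epoch mean of the result is exactly 1. Idempotent: an
#' already-normalized series is returned unchanged.
#'
#' @param pulse_times Pulse times (s).
#' @param amplitudes Raw amplitudes (pA) per pulse.
#' @param epochs As in [washout_series()].
#' @param drug,concentration Metadata.
#' @return A [washout_series()].
#' @export
washout_normalize <- function(pulse_times, amplitudes, epochs,
                              drug = "none", concentration = 0) {
  b <- epochs$baseline
  if (is.null(b)) stop_invalid("epochs must include `baseline`")
  in_base <- pulse_times >= b[1L] & pulse_times < b[2L]
  if (!any(in_base)) stop_invalid("baseline epoch contains no pulses")
  base_mean <- mean(amplitudes[in_base])
  if (!is.finite(base_mean) || base_mean <= 0)
    stop_invalid("baseline mean must be positive",
                 class = "habtrap_normalization_error")
  washout_series(pulse_times, amplitudes / base_mean, epochs,
                 drug = drug, concentration = concentration)
}

#' Maximal blockade, late blockade and recovery of a washout series
#'
#' Blockade is evaluated in 10-min bins tiling from the wash-in onset:
#' `100 * (1 - mean normalized amplitude in bin)`. The maximal blockade is
#' the largest bin value (earliest bin on ties; because of trapping it may
#' occur after the wash-in period). The late blockade is read in the
#' 50-60 min bin and recovery is `max_blockade - blockade_50_60`.
#'
#' The 50-60 min window is counted from the wash-in onset by default (a
#' 10-min wash-in plus 50 min of washout puts it at the last bin of the
#' standard protocol); set `clock = "washout"` to count from washout onset
#' instead.
#'
#' @param series A [washout_series()].
#' @param bin_min Bin width in minutes (default 10).
#' @param late_window_min Late read-out window in minutes on the chosen
#'   clock (default `c(50, 60)`).
#' @param clock `"wash_in"` (default) or `"washout"`.
#' @return A list of class `blockade_recovery`: `max_blockade`,
#'   `blockade_50_60`, `recovery` (all %), `bin_blockade`, `bin_starts_min`.
#' @export
blockade_recovery <- function(series, bin_min = 10,
                              late_window_min = c(50, 60),
                              clock = c("wash_in", "washout")) {
  stopifnot(inherits(series, "washout_series"))
  clock <- match.arg(clock)
  t0 <- series$epochs$wash_in[1L]
  late0 <- if (clock == "wash_in") t0 else series$epochs$washout[1L]
  t_end <- max(series$pulse_times)
  if (t_end < late0 + late_window_min[2L] * 60 - 1e-6)
    stop_invalid("series too short for the requested late window")
  rel_min <- (series$pulse_times - t0) / 60
  starts <- seq(0, (t_end - t0) / 60 - bin_min + 1e-9, by = bin_min)
  bin_block <- vapply(starts, function(s0) {
    sel <- rel_min >= s0 & rel_min < s0 + bin_min
    100 * (1 - mean(series$normalized_amplitude[sel]))
  }, numeric(1L))
  max_blockade <- bin_block[which.max(bin_block)]  # which.max takes the earliest tie
  late_min <- (series$pulse_times - late0) / 60
  late_sel <- late_min >= late_window_min[1L] & late_min < late_window_min[2L]
  blockade_50_60 <- 100 * (1 - mean(series$normalized_amplitude[late_sel]))
  structure(list(max_blockade = max_blockade, blockade_50_60 = blockade_50_60,
                 recovery = max_blockade - blockade_50_60,
                 bin_blockade = bin_block, bin_starts_min = starts),
            class = "blockade_recovery")
}

#' Linear regression of recovery on maximal blockade
#'
#' Ordinary least squares of per-cell recovery against per-cell maximal
#' blockade via the closed-form normal equations, with
#' `R^2 = 1 - SS_res / SS_tot`. A negative slope reproduces the reverse
#' correlation between initial blockade depth and later recovery.
#'
#' @param max_blockade Numeric vector (x), one value per cell.
#' @param recovery Numeric vector (y), same length.
#' @return A list: `slope`, `intercept`, `r_squared`, `n`.
#' @export
blockade_recovery_regression <- function(max_blockade, recovery) {
  x <- as.numeric(max_blockade); y <- as.numeric(recovery)
  if (length(x) != length(y) || length(x) < 3L)
    stop_invalid("need at least 3 (max_blockade, recovery) pairs")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0)
    stop_invalid("zero variance in max_blockade; regression degenerate",
                 class = "habtrap_degenerate_regression")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = slope, intercept = intercept, r_squared = r2, n = length(x))
}
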