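#' Generate a tonic (Poisson) spike train
#'
#' Homogeneous Poisson process at the requested rate, thinned so that no
#' inter-spike interval falls below an absolute refractory period. This
#' emulates the tonic-firing mode of spontaneously active LHb neurons.
#'
#' @param rate Target firing rate in Hz (>= 0).
#' @param duration Recording duration in seconds (> 0).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param refractory Absolute refractory period in seconds (default 0.002).
#' @param t_start Window start in seconds (default 0).
#' @param unit_id Unit identifier.
#' @return A [spike_train()].
#' @export
gen_tonic_train <- function(rate, duration, seed, refractory = 0.002,
                            t_start = 0, unit_id = "tonic") {
  check_number(rate, "rate", lower = 0)
  check_number(duration, "duration", lower = 0, allow_equal_lower = FALSE)
  with_seed(seed, {
    if (rate == 0) {
      s <- numeric(0)
    } else {
      n <- stats::rpois(1L, rate * duration * 1.2 + 10)
      s <- sort(stats::runif(n, 0, duration))
      # thinning: drop spikes violating the refractory period, sequentially
      if (length(s) > 1L) {
        keep <- logical(length(s)); keep[1L] <- TRUE; last <- s[1L]
        for (i in 2L:length(s)) {
          if (s[i] - last >= refractory) { keep[i] <- TRUE; last <- s[i] }
        }
        s <- s[keep]
      }
      # subsample back to the target expected count after thinning overshoot
      target <- stats::rpois(1L, rate * duration)
      if (length(s) > target) s <- sort(sample(s, target))
    }
    spike_train(s + t_start, t_start, t_start + duration, unit_id = unit_id)
  })
}

#' Generate a burst-firing spike train
#'
#' Burst onsets follow a Poisson process at `bursts_per_min`; each burst has
#' `spikes_per_burst` spikes with geometrically lengthening intra-burst
#' intervals, ISI_k = `isi0 * isi_growth^k` (an initially high, progressively
#' declining instantaneous firing frequency). Optional tonic background
#' spikes are superposed at least 60 ms away from any burst so that burst
#' membership is unambiguous by construction.
#'
#' @param bursts_per_min Burst rate, bursts per minute (>= 0).
#' @param spikes_per_burst Spikes per burst (>= 2).
#' @param isi0 First intra-burst ISI in ms; must be <= 20 so generated
#'   bursts satisfy the detection onset criterion.
#' @param isi_growth Geometric ISI growth ratio (>= 1); the last intra-burst
#'   ISI `isi0 * isi_growth^(spikes_per_burst - 2)` must be <= 50 ms.
#' @param background_rate Tonic background rate in Hz (default 0).
#' @param duration Recording duration in seconds.
#' @param seed Integer seed.
#' @param t_start Window start in seconds (default 0).
#' @param unit_id Unit identifier.
#' @return A [spike_train()].
#' @export
gen_bursting_train <- function(bursts_per_min, spikes_per_burst = 5L,
                               isi0 = 8, isi_growth = 1.3,
                               background_rate = 0, duration = 60, seed = 1L,
                               t_start = 0, unit_id = "burst") {
  check_number(bursts_per_min, "bursts_per_min", lower = 0)
  check_number(spikes_per_burst, "spikes_per_burst", lower = 2)
  check_number(isi0, "isi0", lower = 0, allow_equal_lower = FALSE)
  check_number(isi_growth, "isi_growth", lower = 1)
  check_number(background_rate, "background_rate", lower = 0)
  check_number(duration, "duration", lower = 0, allow_equal_lower = FALSE)
  if (isi0 > 20)
    stop_invalid("`isi0` must be <= 20 ms so bursts satisfy the onset criterion")
  spikes_per_burst <- as.integer(spikes_per_burst)
  last_isi <- isi0 * isi_growth^(spikes_per_burst - 2L)
  if (last_isi > 50)
    stop_invalid("last intra-burst ISI exceeds 50 ms; reduce isi_growth or spikes_per_burst")
  isis_s <- isi0 * isi_growth^(seq_len(spikes_per_burst - 1L) - 1L) / 1000
  blen <- sum(isis_s)
  offsets <- c(0, cumsum(isis_s))

  with_seed(seed, {
    n_b <- stats::rpois(1L, bursts_per_min * duration / 60)
    onsets <- sort(stats::runif(n_b, 0, max(duration - blen, 0)))
    # enforce >60 ms separation between bursts so detection stays unambiguous
    if (n_b > 1L) {
      keep <- logical(n_b); keep[1L] <- TRUE; last <- onsets[1L]
      for (i in 2L:n_b) {
        if (onsets[i] - (last + blen) > 0.060) { keep[i] <- TRUE; last <- onsets[i] }
      }
      onsets <- onsets[keep]
    }
    spikes <- if (length(onsets)) as.numeric(outer(offsets, onsets, `+`)) else numeric(0)
    if (background_rate > 0) {
      # background ISIs are kept above the burst-extension criterion (60 ms
      # refractory) so background spikes can neither form nor join bursts
      bg <- gen_tonic_train(background_rate, duration, split_seed(seed, 7L),
                            refractory = 0.06)$spikes
      # keep background clear of bursts (>60 ms margin) so bursts stay intact
      if (length(onsets)) {
        near <- vapply(bg, function(t)
          any(t > onsets - 0.060 & t < onsets + blen + 0.060), logical(1L))
        bg <- bg[!near]
      }
      # and clear of each other's burst-onset criterion is not needed: the
      # background is already refractory-thinned Poisson
      spikes <- c(spikes, bg)
    }
    spikes <- sort(unique(spikes))
    spikes <- spikes[spikes >= 0 & spikes < duration]
    spike_train(spikes + t_start, t_start, t_start + duration, unit_id = unit_id)
  })
}

#' Generate a cohort of pre/post-injection session recordings
#'
#' Each unit receives a 10-min baseline epoch and a 30-min post-injection
#' epoch. Basal bursting spike frequency is drawn from a two-mode log-normal
#' mixture (the bimodal distribution seen across LHb units in vivo); a
#' fraction of units is "inhibited": from the injection time onwards their
#' burst rate is multiplied by `inhibition_factor`.
#'
#' @param n_units Number of units (0 returns an empty list).
#' @param frac_inhibited Fraction of units inhibited after injection, in
#'   `[0, 1]`.
#' @param inhibition_factor Multiplier on post-injection burst rate for
#'   inhibited units, in `[0, 1]` (0 = total suppression, 1 = no effect).
#' @param basal_mixture List `low_mode_Hz`, `high_mode_Hz`, `frac_high`,
#'   `sdlog`: the two modes (in bursting-spike-frequency Hz) of the basal
#'   mixture, the mixing fraction of the high mode, and the log-normal
#'   spread around each mode.
#' @param spikes_per_burst Spikes per burst used to convert a target
#'   bursting spike frequency into a burst rate (default 5).
#' @param inhibit_high_only When TRUE, inhibited units are drawn only from
#'   the high-mode population (the preferential suppression of
#'   high-bursting units).
#' @param baseline_dur,post_dur Epoch durations in seconds (defaults 600
#'   and 1800).
#' @param seed Integer seed.
#' @return A list of [session_recording()] objects with attributes
#'   `inhibited` (logical per unit) and `basal_freq` (Hz per unit).
#' @export
gen_session <- function(n_units, frac_inhibited = 0, inhibition_factor = 1,
                        basal_mixture = list(low_mode_Hz = 0.5,
                                             high_mode_Hz = 4,
                                             frac_high = 0.27,
                                             sdlog = 0.25),
                        spikes_per_burst = 5L, inhibit_high_only = FALSE,
                        baseline_dur = 600, post_dur = 1800, seed = 1L) {
  check_number(n_units, "n_units", lower = 0)
  check_number(frac_inhibited, "frac_inhibited", lower = 0, upper = 1)
  check_number(inhibition_factor, "inhibition_factor", lower = 0, upper = 1)
  check_number(basal_mixture$frac_high, "frac_high", lower = 0, upper = 1)
  if (post_dur < 1800)
    stop_invalid("post-injection epoch must cover at least 30 min")
  n_units <- as.integer(n_units)
  if (n_units == 0L) return(list())

  with_seed(seed, {
    high <- stats::runif(n_units) < basal_mixture$frac_high
    mode_hz <- ifelse(high, basal_mixture$high_mode_Hz, basal_mixture$low_mode_Hz)
    basal <- stats::rlnorm(n_units, meanlog = log(mode_hz),
                           sdlog = basal_mixture$sdlog)
    pool <- if (inhibit_high_only) which(high) else seq_len(n_units)
    n_inh <- round(frac_inhibited * n_units)
    inhibited <- rep(FALSE, n_units)
    if (n_inh > 0L && length(pool))
      inhibited[sample(pool, min(n_inh, length(pool)))] <- TRUE
    seeds <- vapply(seq_len(n_units), function(i) split_seed(seed, i), numeric(1L))
    NULL
  })

  sessions <- vector("list", n_units)
  injection_time <- baseline_dur
  for (i in seq_len(n_units)) {
    bpm_base <- basal[i] * 60 / spikes_per_burst
    bpm_post <- bpm_base * if (inhibited[i]) inhibition_factor else 1
    pre <- gen_bursting_train(bpm_base, spikes_per_burst = spikes_per_burst,
                              duration = baseline_dur, seed = seeds[i],
                              t_start = 0, unit_id = sprintf("u%03d", i))
    post <- gen_bursting_train(bpm_post, spikes_per_burst = spikes_per_burst,
                               duration = post_dur,
                               seed = split_seed(seeds[i], 2L),
                               t_start = baseline_dur,
                               unit_id = sprintf("u%03d", i))
    full <- spike_train(c(pre$spikes, post$spikes), 0, baseline_dur + post_dur,
                        unit_id = sprintf("u%03d", i))
    sessions[[i]] <- session_recording(
      full, injection_time,
      epochs = list(baseline = c(0, baseline_dur),
                    post = c(baseline_dur, baseline_dur + post_dur)))
  }
  attr(sessions, "inhibited") <- inhibited
  attr(sessions, "basal_freq") <- basal
  sessions
}

#' Synaptic waveform: normalized difference of exponentials
#'
#' Unit-peak difference-of-exponentials kinetic template,
#' `(exp(-t/tau_decay) - exp(-t/tau_rise))` scaled to peak 1, zero before
#' onset.
#'
#' @param t Time in seconds (vector), relative to recording start.
#' @param onset Waveform onset in seconds.
#' @param tau_rise,tau_decay Time constants in ms (`tau_decay > tau_rise`).
#' @return Numeric vector, same length as `t`, peak value 1.
#' @export
synaptic_waveform <- function(t, onset, tau_rise, tau_decay) {
  check_number(tau_rise, "tau_rise", lower = 0, allow_equal_lower = FALSE)
  check_number(tau_decay, "tau_decay", lower = 0, allow_equal_lower = FALSE)
  if (tau_decay <= tau_rise) stop_invalid("`tau_decay` must exceed `tau_rise`")
  tr <- tau_rise / 1000; td <- tau_decay / 1000
  tpk <- tr * td / (td - tr) * log(td / tr)
  norm <- exp(-tpk / td) - exp(-tpk / tr)
  x <- t - onset
  w <- ifelse(x >= 0, (exp(-x / td) - exp(-x / tr)) / norm, 0)
  w
}

#' eEPSC sweep container
#'
#' @param time Uniformly sampled time axis (s).
#' @param current Current trace (pA), same length as `time`.
#' @param holding_potential Holding potential (mV).
#' @param stim_onset Stimulation onset (s), within the time axis.
#' @param stim_intensity Stimulation intensity (mA).
#' @param sampling_rate Sampling rate (Hz); inferred from `time` if omitted.
#' @return An object of class `sweep_trace`.
#' @export
sweep_trace <- function(time, current, holding_potential, stim_onset,
                        stim_intensity = NA_real_, sampling_rate = NULL) {
  if (length(time) != length(current))
    stop_invalid("`time` and `current` must have equal length")
  dts <- diff(time)
  if (length(dts) && (max(dts) - min(dts)) > 1e-9 * max(abs(dts)))
    stop_invalid("time axis must be uniformly sampled")
  if (is.null(sampling_rate)) sampling_rate <- 1 / stats::median(dts)
  if (stim_onset < time[1L] || stim_onset > time[length(time)])
    stop_invalid("`stim_onset` must lie within the time axis")
  structure(list(time = time, current = current,
                 holding_potential = holding_potential,
                 stim_onset = stim_onset, stim_intensity = stim_intensity,
                 sampling_rate = sampling_rate),
            class = "sweep_trace")
}

#' Default eEPSC kinetic time constants (ms)
#'
#' AMPAR rise 0.5 / decay 3 ms and NMDAR rise 5 / decay 80 ms. LHb-specific
#' constants are not established; these are documented assumptions chosen so
#' the fast AMPAR component has decayed to a negligible residual 35 ms after
#' stimulation, where the NMDAR amplitude is read out.
#' @return Named list `tau_rise_a`, `tau_decay_a`, `tau_rise_n`, `tau_decay_n`.
#' @export
default_epsc_kinetics <- function() {
  list(tau_rise_a = 0.5, tau_decay_a = 3, tau_rise_n = 5, tau_decay_n = 80)
}

#' Generate a synthetic evoked-EPSC sweep
#'
#' Sum of a fast AMPAR and a slow NMDAR difference-of-exponentials component
#' plus Gaussian noise. Sign follows the holding potential: inward (negative)
#' at negative holding, outward (positive) at positive holding. Under
#' physiological magnesium (`mg_mode = "physiological"`) the NMDAR component
#' is suppressed at hyperpolarized potentials (multiplied by
#' `mg_suppression`, default 0); in magnesium-free mode it is left intact.
#'
#' @param holding Holding potential (mV).
#' @param ampa_amp,nmda_amp Component peak amplitudes (pA, magnitudes).
#' @param kinetics Time constants in ms; see [default_epsc_kinetics()].
#' @param noise_sd Gaussian noise SD (pA).
#' @param stim_onset Stimulation onset (s).
#' @param duration Sweep duration (s).
#' @param sampling_rate Sampling rate (Hz); must resolve the fastest rise
#'   time (at least two samples per `tau_rise`).
#' @param stim_intensity Stimulation intensity (mA), metadata only.
#' @param mg_mode `"physiological"` or `"free"` (no added Mg2+).
#' @param mg_suppression NMDAR suppression factor at negative holding under
#'   physiological Mg2+ (default 0).
#' @param seed Integer seed.
#' @return A [sweep_trace()].
#' @export
gen_epsc_sweep <- function(holding, ampa_amp, nmda_amp,
                           kinetics = default_epsc_kinetics(),
                           noise_sd = 0, stim_onset = 0.05, duration = 0.5,
                           sampling_rate = 20000, stim_intensity = 1.5,
                           mg_mode = c("physiological", "free"),
                           mg_suppression = 0, seed = 1L) {
  mg_mode <- match.arg(mg_mode)
  check_number(ampa_amp, "ampa_amp", lower = 0)
  check_number(nmda_amp, "nmda_amp", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  for (nm in names(kinetics)) check_number(kinetics[[nm]], nm, lower = 0,
                                           allow_equal_lower = FALSE)
  min_tau_s <- min(kinetics$tau_rise_a, kinetics$tau_rise_n) / 1000
  if (1 / sampling_rate > min_tau_s / 2)
    stop_invalid("sampling_rate too low to resolve the fastest rise time")
  tt <- seq(0, duration, by = 1 / sampling_rate)
  sgn <- if (holding < 0) -1 else 1
  nmda_eff <- nmda_amp
  if (mg_mode == "physiological" && holding < 0) nmda_eff <- nmda_amp * mg_suppression
  cur <- sgn * ampa_amp * synaptic_waveform(tt, stim_onset, kinetics$tau_rise_a,
                                            kinetics$tau_decay_a) +
         sgn * nmda_eff * synaptic_waveform(tt, stim_onset, kinetics$tau_rise_n,
                                            kinetics$tau_decay_n)
  if (noise_sd > 0)
    cur <- cur + with_seed(seed, stats::rnorm(length(tt), 0, noise_sd))
  sweep_trace(tt, cur, holding, stim_onset, stim_intensity, sampling_rate)
}

#' Fraction of the NMDAR waveform peak remaining at the 35-ms read-out
#'
#' The 35-ms amplitude of a difference-of-exponentials NMDAR waveform is a
#' fixed fraction of its peak (about 0.83 with the default 5/80-ms
#' kinetics). Useful for designing cohorts whose measured t35-based
#' NMDA/AMPA ratio equals a target value.
#'
#' @param kinetics Time constants in ms; see [default_epsc_kinetics()].
#' @param t_offset Read-out latency in seconds (default 0.035).
#' @return The waveform value at `t_offset` relative to a unit peak.
#' @export
nmda_t35_fraction <- function(kinetics = default_epsc_kinetics(),
                              t_offset = 0.035) {
  synaptic_waveform(t_offset, 0, kinetics$tau_rise_n, kinetics$tau_decay_n)
}

#' Pharmacokinetic concentration profile
#'
#' @param times Time points (min), strictly increasing.
#' @param concentrations Concentrations (uM), non-negative.
#' @param params Optional list `C0` (uM), `t_half` (min) recording the
#'   generating parameters.
#' @return An object of class `pk_profile`.
#' @export
pk_profile <- function(times, concentrations, params = NULL) {
  if (length(times) != length(concentrations))
    stop_invalid("`times` and `concentrations` must have equal length")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop_invalid("`times` must be strictly increasing")
  if (any(concentrations < 0))
    stop_invalid("concentrations must be non-negative")
  structure(list(times = as.numeric(times),
                 concentrations = as.numeric(concentrations),
                 params = params),
            class = "pk_profile")
}

#' Generate a mono-exponential concentration decay series
#'
#' `C(t) = C0 * 2^(-t / t_half)` with optional multiplicative log-normal
#' noise of coefficient of variation `noise_cv`.
#'
#' @param C0 Initial concentration (uM, > 0).
#' @param t_half Elimination half-life (min, > 0).
#' @param times Sampling times (min).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 = noiseless).
#' @param seed Integer seed.
#' @return A [pk_profile()].
#' @export
gen_pk_series <- function(C0, t_half, times, noise_cv = 0, seed = 1L) {
  check_number(C0, "C0", lower = 0, allow_equal_lower = FALSE)
  check_number(t_half, "t_half", lower = 0, allow_equal_lower = FALSE)
  check_number(noise_cv, "noise_cv", lower = 0)
  conc <- C0 * 2^(-times / t_half)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    conc <- conc * with_seed(seed, stats::rlnorm(length(times),
                                                 meanlog = -sdlog^2 / 2,
                                                 sdlog = sdlog))
  }
  pk_profile(times, conc, params = list(C0 = C0, t_half = t_half))
}

#' Generate a synthetic washout experiment
#'
#' Delegates the blocked-fraction dynamics to
#' [run_washout_experiment()] on the trapping model and adds Gaussian
#' measurement noise to the per-pulse normalized amplitudes.
#'
#' @param model A [receptor_model()] (e.g. `build_model("ketamine")`).
#' @param drug_conc Bath drug concentration during wash-in (uM).
#' @param noise_sd Gaussian noise SD on the normalized amplitude.
#' @param seed Integer seed.
#' @param ... Passed to [run_washout_experiment()] (epoch durations, pulse
#'   interval, kick-off protocol, ...).
#' @return A `washout_series` (see [washout_series()]).
#' @export
gen_washout_dataset <- function(model, drug_conc, noise_sd = 0, seed = 1L, ...) {
  ws <- run_washout_experiment(model, drug_conc, ...)
  if (noise_sd > 0) {
    ws$normalized_amplitude <- ws$normalized_amplitude +
      with_seed(seed, stats::rnorm(length(ws$normalized_amplitude), 0, noise_sd))
  }
  ws
}
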