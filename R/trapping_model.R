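#' Four-state receptor model of use-dependent open-channel block with trapping
#'
#' States: C (closed, unbound), O (open, unbound), OB (open, blocked),
#' CB (closed, blocked = trapped). The blocker can only enter (O -> OB) and
#' leave (OB -> O) the pore while the channel is open; closure around a
#' bound blocker (OB -> CB) traps it, and the only way out of CB is
#' re-opening (CB -> OB). There is no unbinding from the closed-blocked
#' state, which encodes trapping literally: with no channel opening, the
#' blocked fraction is exactly conserved.
#'
#' Rate parameters (all per second unless noted):
#' \describe{
#'   \item{kon}{binding rate constant, 1/(uM s); `Kd = koff0 / kon`.}
#'   \item{koff0}{unbinding rate at resting potential. The ketamine preset
#'     uses `ln(2)/9` (a 9-s dissociation time, the middle of the reported
#'     5-13 s in-solution range).}
#'   \item{alpha}{channel closing rate; also the trapping rate OB -> CB.
#'     Default 200 (5-ms mean open duration, within the <10 ms bound).}
#'   \item{beta_drive}{opening rate during an agonist (glutamate) exposure.
#'     Default 500, so a 2-ms exposure opens with probability
#'     `1 - exp(-1)` = 0.63.}
#'   \item{Po_spont}{intrinsic open probability of synaptic receptors
#'     without stimulation (default 0.04); together with
#'     `spont_event_rate` it sets the spontaneous opening rate
#'     `Po_spont * spont_event_rate` between agonist events.}
#'   \item{spont_event_rate}{rate of spontaneous glutamate exposures
#'     (1/s, default 0.01).}
#'   \item{depol_factor}{multiplier (>= 1) on koff during depolarization
#'     windows (default 3); depolarization also lifts the magnesium
#'     restriction on opening.}
#'   \item{mg_open_scale}{scale in (0, 1] on the opening rate outside
#'     depolarization windows under physiological magnesium; 1 in
#'     magnesium-free solution.}
#'   \item{cb_escape}{optional direct CB -> C escape rate for sensitivity
#'     analysis (default 0 = strict trapping).}
#' }
#'
#' @param kon,koff0,alpha,beta_drive,Po_spont,spont_event_rate,depol_factor,mg_open_scale,cb_escape
#'   See Details.
#' @param label Model label.
#' @return An object of class `receptor_model` with derived field `Kd`
#'   (uM).
#' @seealso [build_model()] for the drug presets.
#' @export
receptor_model <- function(kon, koff0, alpha = 200, beta_drive = 500,
                           Po_spont = 0.04, spont_event_rate = 0.01,
                           depol_factor = 3, mg_open_scale = 1,
                           cb_escape = 0, label = "custom") {
  check_number(kon, "kon", lower = 0, allow_equal_lower = FALSE)
  check_number(koff0, "koff0", lower = 0)
  check_number(alpha, "alpha", lower = 0)
  check_number(beta_drive, "beta_drive", lower = 0)
  check_number(Po_spont, "Po_spont", lower = 0, upper = 1)
  check_number(spont_event_rate, "spont_event_rate", lower = 0)
  check_number(depol_factor, "depol_factor", lower = 1)
  check_number(mg_open_scale, "mg_open_scale", lower = 0, upper = 1,
               allow_equal_lower = FALSE)
  check_number(cb_escape, "cb_escape", lower = 0)
  structure(list(kon = kon, koff0 = koff0, alpha = alpha,
                 beta_drive = beta_drive, Po_spont = Po_spont,
                 spont_event_rate = spont_event_rate,
                 depol_factor = depol_factor, mg_open_scale = mg_open_scale,
                 cb_escape = cb_escape, Kd = koff0 / kon, label = label),
            class = "receptor_model")
}

#' @export
print.receptor_model <- function(x, ...) {
  cat(sprintf("<receptor_model> %s: Kd %.3g uM (kon %.3g, koff0 %.3g), alpha %g, beta_drive %g\n",
              x$label, x$Kd, x$kon, x$koff0, x$alpha, x$beta_drive))
  invisible(x)
}

#' Build a receptor model, with drug presets
#'
#' Presets encode the single-parameter contrast between the two
#' pore-blocking drugs: similar affinity but a faster off-rate for
#' memantine. Both presets use `Kd = 0.8` uM; the ketamine off-rate is
#' `ln(2)/9` per second (9-s dissociation time) and the memantine off-rate
#' is 20x faster (with kon scaled to preserve Kd). These rates are a
#' literature-anchored calibration, not a fit.
#'
#' @param preset `"ketamine"`, `"memantine"`, or `"custom"`.
#' @param Kd Dissociation constant in uM (default 0.8).
#' @param koff_scale Off-rate multiplier relative to the ketamine off-rate
#'   (memantine preset uses 20).
#' @param ... Overrides passed to [receptor_model()].
#' @return A [receptor_model()].
#' @examples
#' build_model("ketamine")$Kd # 0.8
#' @export
build_model <- function(preset = c("ketamine", "memantine", "custom"),
                        Kd = 0.8, koff_scale = NULL, ...) {
  preset <- match.arg(preset)
  check_number(Kd, "Kd", lower = 0, allow_equal_lower = FALSE)
  koff_ket <- log(2) / 9
  scale <- if (!is.null(koff_scale)) koff_scale
           else if (preset == "memantine") 20 else 1
  koff0 <- koff_ket * scale
  args <- list(kon = koff0 / Kd, koff0 = koff0, label = preset)
  over <- list(...)
  args[names(over)] <- over
  do.call(receptor_model, args)
}

#' Stimulation protocol for the trapping simulator
#'
#' @param events data.frame with columns `time` (s) and `duration` (s):
#'   glutamate-exposure events (default duration 2 ms, the synaptic
#'   exposure time). May be empty.
#' @param depol data.frame with columns `start`, `end` (s):
#'   depolarization windows. May be empty.
#' @param conc Ambient blocker concentration: a single number (uM), or a
#'   list `list(breaks =, values =)` describing a right-open piecewise
#'   constant function (`values[i]` holds on `[breaks[i], breaks[i+1])`,
#'   with `values[n]` from `breaks[n]` on).
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(events = data.frame(time = numeric(),
                                              duration = numeric()),
                          depol = data.frame(start = numeric(),
                                             end = numeric()),
                          conc = 0) {
  if (nrow(events)) {
    if (any(events$duration < 0)) stop_invalid("event durations must be >= 0")
    events <- events[order(events$time), , drop = FALSE]
  }
  if (is.numeric(conc) && length(conc) == 1L) {
    if (conc < 0) stop_invalid("concentration must be >= 0")
    conc <- list(breaks = 0, values = conc)
  } else {
    if (any(conc$values < 0)) stop_invalid("concentration must be >= 0 everywhere")
    if (length(conc$breaks) != length(conc$values))
      stop_invalid("conc breaks/values length mismatch")
  }
  structure(list(events = events, depol = depol, conc = conc),
            class = "stim_protocol")
}

# rate/generator matrix for one piecewise-constant regime.
# Rows = from-state, cols = to-state; states C, O, OB, CB.
#' @keywords internal
rate_matrix <- function(model, conc, in_event, in_depol) {
  open_scale <- if (in_depol) 1 else model$mg_open_scale
  r_open <- open_scale * if (in_event) model$beta_drive
                         else model$Po_spont * model$spont_event_rate
  koff <- model$koff0 * if (in_depol) model$depol_factor else 1
  Q <- matrix(0, 4, 4, dimnames = list(c("C", "O", "OB", "CB"),
                                       c("C", "O", "OB", "CB")))
  Q["C", "O"] <- r_open
  Q["O", "C"] <- model$alpha
  Q["O", "OB"] <- model$kon * conc
  Q["OB", "O"] <- koff
  Q["OB", "CB"] <- model$alpha
  Q["CB", "OB"] <- r_open
  Q["CB", "C"] <- model$cb_escape
  diag(Q) <- -rowSums(Q)
  Q
}

#' @keywords internal
conc_at_time <- function(conc, t) {
  i <- findInterval(t, conc$breaks)
  conc$values[pmax(i, 1L)]
}

#' Integrate the trapping-block master equation over a protocol
#'
#' The four-state occupancy vector evolves under a piecewise-constant-rate
#' linear master equation: within each regime (inside/outside an agonist
#' event, inside/outside a depolarization window, at the current ambient
#' concentration) the rates are constant and the occupancies are propagated
#' exactly with the matrix exponential of the generator; regime boundaries
#' are stepped exactly, so brief events are never aliased. An explicit-Euler
#' integrator (`method = "euler"`) is available; it requires
#' `dt <= 0.1 / max rate` and errors otherwise.
#'
#' @param model A [receptor_model()].
#' @param protocol A [stim_protocol()].
#' @param t_end End of the simulation (s).
#' @param p0 Initial occupancy (C, O, OB, CB), summing to 1; default all
#'   closed-unbound.
#' @param sample_times Extra times (s) at which occupancies are recorded
#'   (regime boundaries are always recorded).
#' @param method `"expm"` (default, exact per segment) or `"euler"`.
#' @param dt Euler step (s); ignored for `"expm"`.
#' @return A data.frame of class `sim_result`: `time`, `C`, `O`, `OB`,
#'   `CB`, `blocked` (= OB + CB).
#' @export
simulate_trapping <- function(model, protocol, t_end,
                              p0 = c(C = 1, O = 0, OB = 0, CB = 0),
                              sample_times = NULL,
                              method = c("expm", "euler"), dt = NULL) {
  stopifnot(inherits(model, "receptor_model"), inherits(protocol, "stim_protocol"))
  method <- match.arg(method)
  if (abs(sum(p0) - 1) > 1e-9 || any(p0 < 0))
    stop_invalid("`p0` must be a probability vector over (C, O, OB, CB)")
  ev <- protocol$events
  bounds <- c(0, t_end,
              ev$time, ev$time + ev$duration,
              protocol$depol$start, protocol$depol$end,
              protocol$conc$breaks, sample_times)
  bounds <- sort(unique(pmin(pmax(bounds, 0), t_end)))

  n <- length(bounds)
  occ <- matrix(NA_real_, n, 4, dimnames = list(NULL, c("C", "O", "OB", "CB")))
  occ[1L, ] <- p0
  p <- p0
  eps <- 1e-12

  # regime of each segment, classified at its midpoint (boundaries include
  # all event/depol/concentration edges, so no segment straddles a regime)
  tms <- (bounds[-n] + bounds[-1L]) / 2
  segs <- bounds[-1L] - bounds[-n]
  in_regime <- function(tm, start, end) {
    if (!length(start)) return(rep(FALSE, length(tm)))
    i <- findInterval(tm, start)
    ok <- i >= 1L
    ok[ok] <- tm[ok] < end[i[ok]] + eps
    ok
  }
  in_event_v <- in_regime(tms, ev$time, ev$time + ev$duration)
  in_depol_v <- in_regime(tms, protocol$depol$start, protocol$depol$end)
  conc_v <- conc_at_time(protocol$conc, tms)

  # propagators are cached per (regime, concentration, segment length):
  # long protocols reuse a handful of distinct segments
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n - 1L)) {
    seg <- segs[i]
    if (method == "expm") {
      key <- paste(in_event_v[i], in_depol_v[i],
                   sprintf("%.17g|%.17g", conc_v[i], seg), sep = "|")
      P <- cache[[key]]
      if (is.null(P)) {
        Q <- rate_matrix(model, conc_v[i], in_event_v[i], in_depol_v[i])
        P <- as.matrix(Matrix::expm(Matrix::Matrix(t(Q) * seg)))
        cache[[key]] <- P
      }
      p <- as.numeric(P %*% p)
    } else {
      Q <- rate_matrix(model, conc_v[i], in_event_v[i], in_depol_v[i])
      max_rate <- max(-diag(Q))
      if (is.null(dt)) stop_invalid("`dt` is required for method = 'euler'")
      if (max_rate > 0 && dt > 0.1 / max_rate)
        stop_invalid(sprintf("dt = %g too large for max rate %g (stability)",
                             dt, max_rate),
                     class = "habtrap_stability_error")
      nstep <- max(1L, ceiling(seg / dt))
      h <- seg / nstep
      QT <- t(Q)
      for (k in seq_len(nstep)) p <- p + h * as.numeric(QT %*% p)
    }
    p <- pmax(p, 0); p <- p / sum(p)
    occ[i + 1L, ] <- p
  }
  out <- data.frame(time = bounds, occ, blocked = occ[, "OB"] + occ[, "CB"])
  class(out) <- c("sim_result", "data.frame")
  out
}

#' Steady-state blocked fraction of open receptors under sustained agonist
#'
#' With the channel continuously driven open and no depolarization, the
#' stationary distribution of the master equation gives a blocked fraction
#' among open receptors of `conc / (conc + Kd)` — the binding isotherm of
#' the dynamic-equilibrium picture: below the dissociation constant the
#' interaction leads to net unbinding, above it to net binding. The value is
#' obtained by numerically solving for the stationary distribution of the
#' full generator.
#'
#' @param model A [receptor_model()].
#' @param conc Ambient concentration (uM, >= 0; vectorized).
#' @param of `"open"` (default): OB / (O + OB); `"all"`: OB + CB.
#' @return Blocked fraction(s) in `[0, 1]`.
#' @export
equilibrium_occupancy <- function(model, conc, of = c("open", "all")) {
  of <- match.arg(of)
  vapply(conc, function(cc) {
    if (cc < 0) stop_invalid("concentration must be >= 0")
    Q <- rate_matrix(model, cc, in_event = TRUE, in_depol = FALSE)
    A <- rbind(t(Q), rep(1, 4))
    p <- stats::lm.fit(A, c(0, 0, 0, 0, 1))$coefficients
    p <- pmax(as.numeric(p), 0); p <- p / sum(p)
    if (of == "open") {
      if (p[2L] + p[3L] == 0) return(0)
      p[3L] / (p[2L] + p[3L])
    } else p[3L] + p[4L]
  }, numeric(1L))
}

#' Half-occupancy concentration of the steady-state binding curve
#'
#' Solves numerically for the ambient concentration at which the
#' steady-state blocked fraction of open receptors reaches one half; for
#' the trapping scheme this equals the dissociation constant.
#'
#' @param model A [receptor_model()].
#' @param interval Search interval in uM.
#' @return Concentration (uM).
#' @export
half_occupancy_conc <- function(model, interval = c(1e-4, 1e4)) {
  stats::uniroot(function(cc) equilibrium_occupancy(model, cc) - 0.5,
                 interval = interval, tol = 1e-12)$root
}

#' Apparent IC50 of a finite drug application under restricted opening
#'
#' For each concentration the model starts unblocked and a finite
#' application (default 10 min) with brief periodic agonist events is
#' simulated under the model's magnesium opening scale; inhibition is the
#' blocked fraction at the end of the application. The IC50 interpolates
#' the 50% crossing in log-concentration. With unrestricted opening and a
#' long sustained application the curve collapses onto the equilibrium
#' isotherm and the IC50 equals the dissociation constant; restricted
#' opening (magnesium, brief events) lowers apparent potency and pushes the
#' IC50 above it.
#'
#' @param model A [receptor_model()] (set `mg_open_scale < 1` for
#'   physiological magnesium).
#' @param concentrations At least 5 concentrations (uM) spanning the
#'   transition.
#' @param app_dur Application duration (s, default 600).
#' @param event_rate Agonist-event rate during the application (Hz,
#'   default 2).
#' @param event_duration Event duration (s, default 0.002).
#' @param mode `"transient"` (default, simulate the finite application) or
#'   `"equilibrium"` (steady-state isotherm).
#' @return A list: `ic50` (uM), `concentrations`, `inhibition`.
#' @export
dose_inhibition_ic50 <- function(model, concentrations, app_dur = 600,
                                 event_rate = 2, event_duration = 0.002,
                                 mode = c("transient", "equilibrium")) {
  mode <- match.arg(mode)
  if (length(concentrations) < 5L)
    stop_invalid("need at least 5 concentrations spanning the transition")
  concentrations <- sort(concentrations)
  inh <- if (mode == "equilibrium") {
    equilibrium_occupancy(model, concentrations)
  } else {
    ev_times <- seq(0, app_dur - event_duration, by = 1 / event_rate)
    vapply(concentrations, function(cc) {
      pr <- stim_protocol(events = data.frame(time = ev_times,
                                              duration = event_duration),
                          conc = cc)
      sim <- simulate_trapping(model, pr, t_end = app_dur)
      sim$blocked[nrow(sim)]
    }, numeric(1L))
  }
  if (max(inh) < 0.5 || min(inh) > 0.5)
    stop_invalid("inhibition curve does not cross 50% in the given range",
                 class = "habtrap_out_of_range")
  i <- which(inh >= 0.5)[1L]
  if (inh[i] == 0.5 || i == 1L) {
    ic50 <- concentrations[i]
  } else {
    lx <- log(concentrations)
    ic50 <- exp(lx[i - 1L] + (0.5 - inh[i - 1L]) / (inh[i] - inh[i - 1L]) *
                  (lx[i] - lx[i - 1L]))
  }
  list(ic50 = ic50, concentrations = concentrations, inhibition = inh)
}

#' Build the kick-off stimulation protocol
#'
#' Two sessions of five 3-s pairings of 1-Hz presynaptic stimulation with
#' postsynaptic depolarization, one pairing per minute within a session and
#' a 4-min gap between sessions: 2 x 5 x 3 = 30 presynaptic events in
#' total. With `depol = "paired"` each pairing carries a co-extensive
#' depolarization window; `depol = "absent"` gives the same presynaptic
#' events with no depolarization (the "pre alone" control).
#'
#' @param n_sessions Number of sessions (default 2).
#' @param pairings_per_session Pairings per session (default 5).
#' @param pairing_len Pairing length (s, default 3).
#' @param pre_freq Presynaptic stimulation rate within a pairing (Hz,
#'   default 1: events at 0, 1, 2 s of each pairing).
#' @param pairing_interval Time between pairing onsets within a session
#'   (s, default 60).
#' @param inter_session_gap Gap between the end of one session and the
#'   start of the next (s, default 240).
#' @param depol `"paired"` or `"absent"`.
#' @param t0 Protocol start time (s, default 0).
#' @param event_duration Glutamate-exposure duration per event (s,
#'   default 0.002).
#' @param conc Ambient concentration forcing (default 0).
#' @return A [stim_protocol()].
#' @export
make_kickoff_protocol <- function(n_sessions = 2, pairings_per_session = 5,
                                  pairing_len = 3, pre_freq = 1,
                                  pairing_interval = 60,
                                  inter_session_gap = 240,
                                  depol = c("paired", "absent"), t0 = 0,
                                  event_duration = 0.002, conc = 0) {
  depol <- match.arg(depol)
  check_number(n_sessions, "n_sessions", lower = 0)
  check_number(pairings_per_session, "pairings_per_session", lower = 0)
  check_number(pairing_len, "pairing_len", lower = 0, allow_equal_lower = FALSE)
  check_number(pre_freq, "pre_freq", lower = 0, allow_equal_lower = FALSE)
  session_len <- (pairings_per_session - 1) * pairing_interval + pairing_len
  starts <- numeric(0)
  for (s in seq_len(n_sessions)) {
    s0 <- t0 + (s - 1) * (session_len + inter_session_gap)
    starts <- c(starts, s0 + (seq_len(pairings_per_session) - 1) * pairing_interval)
  }
  ev_off <- seq(0, pairing_len - 1e-9, by = 1 / pre_freq)
  ev_times <- if (length(starts)) as.numeric(outer(ev_off, starts, `+`)) else numeric(0)
  events <- data.frame(time = sort(ev_times),
                       duration = rep(event_duration, length(ev_times)))
  dep <- if (depol == "paired" && length(starts)) {
    data.frame(start = starts, end = starts + pairing_len)
  } else data.frame(start = numeric(), end = numeric())
  stim_protocol(events = events, depol = dep, conc = conc)
}

#' Simulate a drug wash-in/washout experiment
#'
#' Timeline: a drug-free baseline (default 5 min), a wash-in epoch at the
#' bath concentration (default 10 min), then drug-free washout (default
#' 50 min). Test pulses — brief agonist events — are delivered at a fixed
#' interval (default 10 s) throughout; the predicted normalized eEPSC at
#' each pulse is `1 - blocked_fraction` at the pulse time. An optional
#' kick-off protocol is inserted at a delay after washout onset (default
#' 10 min).
#'
#' @param model A [receptor_model()].
#' @param drug_conc Bath concentration during wash-in (uM; 0 = vehicle).
#' @param baseline_min,wash_in_min,washout_min Epoch durations (min;
#'   washout must be >= 50).
#' @param pulse_every Test-pulse interval (s, default 10).
#' @param pulse_duration Test-pulse agonist exposure (s, default 0.002).
#' @param kickoff `NULL`, `"paired"` or `"absent"`: insert a kick-off (or
#'   pre-alone) protocol after washout onset.
#' @param kickoff_delay_min Delay of the kick-off after washout onset
#'   (min, default 10).
#' @return A [washout_series()] with attribute `sim` holding the
#'   [simulate_trapping()] result.
#' @export
run_washout_experiment <- function(model, drug_conc, baseline_min = 5,
                                   wash_in_min = 10, washout_min = 50,
                                   pulse_every = 10, pulse_duration = 0.002,
                                   kickoff = NULL, kickoff_delay_min = 10) {
  check_number(drug_conc, "drug_conc", lower = 0)
  if (washout_min < 50)
    stop_invalid("washout epoch must cover at least 50 min")
  t_base <- baseline_min * 60
  t_wash_in <- t_base + wash_in_min * 60
  t_end <- t_wash_in + washout_min * 60
  pulse_times <- seq(0, t_end, by = pulse_every)
  events <- data.frame(time = pulse_times,
                       duration = rep(pulse_duration, length(pulse_times)))
  depol <- data.frame(start = numeric(), end = numeric())
  if (!is.null(kickoff)) {
    kp <- make_kickoff_protocol(depol = kickoff,
                                t0 = t_wash_in + kickoff_delay_min * 60)
    events <- rbind(events, kp$events)
    events <- events[order(events$time), ]
    events <- events[!duplicated(events$time), ]
    depol <- kp$depol
  }
  conc <- list(breaks = c(0, t_base, t_wash_in),
               values = c(0, drug_conc, 0))
  pr <- stim_protocol(events = events, depol = depol, conc = conc)
  sim <- simulate_trapping(model, pr, t_end = t_end)
  blocked_at <- stats::approx(sim$time, sim$blocked, xout = pulse_times,
                              method = "constant", rule = 2)$y
  ws <- washout_series(
    pulse_times = pulse_times,
    normalized_amplitude = 1 - blocked_at,
    epochs = list(baseline = c(0, t_base),
                  wash_in = c(t_base, t_wash_in),
                  washout = c(t_wash_in, t_end)),
    drug = model$label, concentration = drug_conc)
  attr(ws, "sim") <- sim
  ws
}

#' Single-channel Gillespie simulation of the trapping scheme
#'
#' Stochastic per-channel counterpart of [simulate_trapping()] for
#' small-n illustration: one trajectory through the C/O/OB/CB states under
#' the same piecewise-constant rates. Not the quantitative analysis
#' surface — the mean-field master equation is.
#'
#' @param model A [receptor_model()].
#' @param protocol A [stim_protocol()].
#' @param t_end End time (s).
#' @param seed Integer seed.
#' @param state0 Initial state (default `"C"`).
#' @return A data.frame `time`, `state` of state-entry times.
#' @export
simulate_gillespie <- function(model, protocol, t_end, seed = 1L,
                               state0 = "C") {
  states <- c("C", "O", "OB", "CB")
  ev <- protocol$events
  bounds <- sort(unique(pmin(pmax(
    c(0, t_end, ev$time, ev$time + ev$duration,
      protocol$depol$start, protocol$depol$end, protocol$conc$breaks),
    0), t_end)))
  with_seed(seed, {
    t <- 0; s <- match(state0, states)
    out_t <- 0; out_s <- states[s]
    for (i in seq_len(length(bounds) - 1L)) {
      t0 <- bounds[i]; t1 <- bounds[i + 1L]; tm <- (t0 + t1) / 2
      in_event <- nrow(ev) > 0 &&
        any(tm > ev$time - 1e-12 & tm < ev$time + ev$duration + 1e-12)
      in_depol <- nrow(protocol$depol) > 0 &&
        any(tm > protocol$depol$start - 1e-12 & tm < protocol$depol$end + 1e-12)
      Q <- rate_matrix(model, conc_at_time(protocol$conc, tm), in_event, in_depol)
      t <- t0
      repeat {
        rates <- Q[s, ]; rates[s] <- 0
        tot <- sum(rates)
        if (tot <= 0) break
        t <- t + stats::rexp(1L, tot)
        if (t >= t1) break
        s <- sample.int(4L, 1L, prob = rates)
        out_t <- c(out_t, t); out_s <- c(out_s, states[s])
      }
    }
    data.frame(time = out_t, state = out_s)
  })
}
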