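#' Spike train container
#'
#' A `spike_train` holds the action-potential timestamps of one unit within a
#' recording window. Spike times are strictly increasing and live in the
#' half-open interval `[t_start, t_stop)`; all downstream burst and rate
#' statistics are computed over this window.
#'
#' @param spikes Numeric vector of spike times in seconds, strictly
#'   increasing (no duplicate timestamps).
#' @param t_start,t_stop Window bounds in seconds, `t_stop > t_start`.
#' @param unit_id Identifier for the unit (character or integer).
#'
#' @return An object of class `spike_train`: a list with elements `unit_id`,
#'   `spikes`, `t_start`, `t_stop`.
#' @examples
#' st <- spike_train(c(0.1, 0.5, 2.0), t_start = 0, t_stop = 10)
#' firing_rate(st)
#' @export
spike_train <- function(spikes, t_start, t_stop, unit_id = "unit") {
  spikes <- as.numeric(spikes)
  check_number(t_start, "t_start")
  check_number(t_stop, "t_stop")
  if (t_stop <= t_start)
    stop_invalid("`t_stop` must be greater than `t_start`")
  if (anyNA(spikes))
    stop_invalid("spike times must not contain NA")
  if (length(spikes) > 1L && any(diff(spikes) <= 0))
    stop_invalid("spike times must be strictly increasing")
  if (length(spikes) && (spikes[1L] < t_start || spikes[length(spikes)] >= t_stop))
    stop_invalid("all spikes must lie within [t_start, t_stop)")
  structure(list(unit_id = unit_id, spikes = spikes,
                 t_start = t_start, t_stop = t_stop),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s: %d spikes in [%g, %g) s (%.3g Hz)\n",
              x$unit_id, length(x$spikes), x$t_start, x$t_stop,
              firing_rate(x)))
  invisible(x)
}

#' Mean firing rate of a spike train
#'
#' @param train A [spike_train()].
#' @return Spikes per second over the recording window (Hz).
#' @export
firing_rate <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  length(train$spikes) / (train$t_stop - train$t_start)
}

#' Restrict a spike train to a sub-window
#'
#' @param train A [spike_train()].
#' @param from,to New window bounds in seconds (clipped to the original
#'   window); spikes in `[from, to)` are kept.
#' @return A [spike_train()] over `[from, to)`.
#' @export
window_train <- function(train, from, to) {
  stopifnot(inherits(train, "spike_train"))
  from <- max(from, train$t_start)
  to <- min(to, train$t_stop)
  if (to <= from) stop_invalid("empty window")
  s <- train$spikes
  spike_train(s[s >= from & s < to], from, to, unit_id = train$unit_id)
}

#' Session recording: one unit across baseline and post-injection epochs
#'
#' Bundles a unit's full-session spike train with named epoch intervals and
#' the drug injection time, the layout assumed by in vivo unit-response
#' analysis (10-min pre-injection baseline, post-injection period).
#'
#' @param train A [spike_train()] spanning the whole session.
#' @param injection_time Injection time in seconds (session clock).
#' @param epochs Named list of `c(start, end)` intervals in seconds. Must
#'   contain a `baseline` epoch ending at or before `injection_time`;
#'   epochs must not overlap.
#' @return An object of class `session_recording`.
#' @export
session_recording <- function(train, injection_time,
                              epochs = list(
                                baseline = c(injection_time - 600, injection_time),
                                post = c(injection_time, train$t_stop))) {
  stopifnot(inherits(train, "spike_train"))
  check_number(injection_time, "injection_time")
  if (is.null(epochs$baseline))
    stop_invalid("epochs must include a `baseline` interval")
  if (epochs$baseline[2L] > injection_time + 1e-9)
    stop_invalid("baseline epoch must end at or before injection_time")
  iv <- do.call(rbind, epochs)
  if (any(iv[, 2L] <= iv[, 1L])) stop_invalid("epoch intervals must have end > start")
  o <- order(iv[, 1L])
  if (nrow(iv) > 1L && any(iv[o, 1L][-1L] < iv[o, 2L][-nrow(iv)] - 1e-9))
    stop_invalid("epochs must be non-overlapping")
  structure(list(train = train, injection_time = injection_time,
                 epochs = epochs),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> unit %s, injection at %g s, epochs: %s\n",
              x$train$unit_id, x$injection_time,
              paste(names(x$epochs), collapse = ", ")))
  invisible(x)
}
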