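#' Burst-detection parameters (max-interval criteria)
#'
#' Parameters of the inter-spike-interval burst definition used for LHb
#' recordings: a burst opens at an ISI of at most `max_start_isi` and extends
#' while ISIs stay at or below `max_end_isi`; bursts closer together than
#' `min_interburst` are merged, and bursts with fewer than `min_spikes`
#' spikes are discarded.
#'
#' `max_end_isi` is the largest ISI allowed to remain inside a burst: the
#' burst terminates at the first ISI exceeding it. `min_interburst` is read
#' as the minimum separation between distinct bursts (with the default
#' `max_end_isi` of 50 ms, gaps below 50 ms are consumed by burst extension,
#' so merging only matters for non-default parameter choices).
#'
#' @param max_start_isi Maximal onset ISI in ms (default 20).
#' @param max_end_isi Maximal intra-burst ISI in ms (default 50).
#' @param min_interburst Minimal separation between bursts in ms (default 50).
#' @param min_spikes Minimal number of spikes in a burst (default 2).
#' @return An object of class `burst_params`.
#' @export
burst_params <- function(max_start_isi = 20, max_end_isi = 50,
                         min_interburst = 50, min_spikes = 2L) {
  check_number(max_start_isi, "max_start_isi", lower = 0, allow_equal_lower = FALSE)
  check_number(max_end_isi, "max_end_isi", lower = 0, allow_equal_lower = FALSE)
  check_number(min_interburst, "min_interburst", lower = 0, allow_equal_lower = FALSE)
  check_number(min_spikes, "min_spikes", lower = 2)
  if (max_start_isi > max_end_isi)
    stop_invalid("`max_start_isi` must not exceed `max_end_isi`")
  structure(list(max_start_isi = max_start_isi, max_end_isi = max_end_isi,
                 min_interburst = min_interburst,
                 min_spikes = as.integer(min_spikes)),
            class = "burst_params")
}

#' Detect bursts in a spike train
#'
#' Greedy left-to-right scan over inter-spike intervals: a burst opens at
#' spike i when ISI(i, i+1) <= `max_start_isi`, extends while subsequent
#' ISIs are <= `max_end_isi`, and closes at the first longer interval.
#' Bursts separated by less than `min_interburst` are merged, then bursts
#' with fewer than `min_spikes` spikes are discarded. Returned bursts are
#' disjoint and ordered by onset.
#'
#' @param train A [spike_train()].
#' @param params A [burst_params()].
#' @return A data.frame of class `burst_set` with one row per burst:
#'   `start_index`, `end_index` (1-based spike indices), `n_spikes`,
#'   `start_time`, `end_time`, `duration` (s).
#' @examples
#' st <- spike_train(c(0, 0.015, 0.040, 0.300, 0.310), 0, 1)
#' detect_bursts(st)
#' @export
detect_bursts <- function(train, params = burst_params()) {
  stopifnot(inherits(train, "spike_train"), inherits(params, "burst_params"))
  s <- train$spikes
  n <- length(s)
  empty <- data.frame(start_index = integer(), end_index = integer(),
                      n_spikes = integer(), start_time = numeric(),
                      end_time = numeric(), duration = numeric())
  class(empty) <- c("burst_set", "data.frame")
  if (n < 2L) return(empty)

  isi_ms <- diff(s) * 1000
  inside <- isi_ms <= params$max_end_isi   # ISI short enough to stay in a burst
  onset <- isi_ms <= params$max_start_isi  # ISI short enough to open a burst

  # maximal runs of consecutive "inside" ISIs; within each run the burst
  # starts at the first onset-qualifying ISI and extends to the run's end
  r <- rle(inside)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- which(r$values)
  starts <- integer(0); ends <- integer(0)
  for (k in keep) {
    idx <- run_start[k]:run_end[k]
    first_on <- idx[match(TRUE, onset[idx])]
    if (!is.na(first_on)) {
      starts <- c(starts, first_on)          # burst covers spikes first_on .. run_end+1
      ends <- c(ends, run_end[k] + 1L)
    }
  }
  if (!length(starts)) return(empty)

  # merge bursts separated by < min_interburst (gap between last spike of one
  # and first spike of the next)
  if (length(starts) > 1L) {
    gap_ms <- (s[starts[-1L]] - s[ends[-length(ends)]]) * 1000
    merge_with_prev <- gap_ms < params$min_interburst
    grp <- cumsum(c(TRUE, !merge_with_prev))
    starts <- tapply(starts, grp, min)
    ends <- tapply(ends, grp, max)
    starts <- as.integer(starts); ends <- as.integer(ends)
  }

  n_spk <- ends - starts + 1L
  ok <- n_spk >= params$min_spikes
  starts <- starts[ok]; ends <- ends[ok]; n_spk <- n_spk[ok]
  out <- data.frame(start_index = starts, end_index = ends, n_spikes = n_spk,
                    start_time = s[starts], end_time = s[ends],
                    duration = s[ends] - s[starts])
  class(out) <- c("burst_set", "data.frame")
  out
}

#' Burst metrics over a recording window
#'
#' The two summary statistics of burst firing: the bursting spike frequency
#' (number of spikes contained in bursts, per second of recording) and
#' bursts per minute (number of bursts per minute of recording).
#'
#' @param train A [spike_train()] over the window of interest.
#' @param bursts Output of [detect_bursts()] on `train`; detected internally
#'   when omitted.
#' @param params A [burst_params()] (used only when `bursts` is omitted).
#' @return A list of class `burst_metrics`: `bursting_spike_frequency` (Hz),
#'   `bursts_per_minute` (1/min), `n_bursting_spikes`, `n_bursts`,
#'   `window` (s).
#' @export
burst_metrics <- function(train, bursts = NULL, params = burst_params()) {
  stopifnot(inherits(train, "spike_train"))
  if (is.null(bursts)) bursts <- detect_bursts(train, params)
  window <- train$t_stop - train$t_start
  if (window <= 0) stop_invalid("zero-length window")
  n_bspk <- sum(bursts$n_spikes)
  n_b <- nrow(bursts)
  structure(list(bursting_spike_frequency = n_bspk / window,
                 bursts_per_minute = n_b / (window / 60),
                 n_bursting_spikes = n_bspk, n_bursts = n_b,
                 window = window),
            class = "burst_metrics")
}

#' Neuron firing-type criteria
#'
#' Thresholds for the three-way silent / tonic / burst typing of
#' spontaneously active LHb neurons. The source recordings report the
#' three categories without numeric thresholds, so these defaults are
#' explicit, configurable assumptions: a unit is silent below
#' `silent_rate`, a burst-firing unit produces at least
#' `min_bursts_per_min` detected bursts per minute, and anything else
#' is tonic.
#'
#' @param silent_rate Firing-rate ceiling for "silent", Hz (default 0.1).
#' @param min_bursts_per_min Minimal bursts/min for "burst" (default 1).
#' @return An object of class `typing_criteria`.
#' @export
typing_criteria <- function(silent_rate = 0.1, min_bursts_per_min = 1.0) {
  check_number(silent_rate, "silent_rate", lower = 0)
  check_number(min_bursts_per_min, "min_bursts_per_min", lower = 0)
  structure(list(silent_rate = silent_rate,
                 min_bursts_per_min = min_bursts_per_min),
            class = "typing_criteria")
}

#' Classify a neuron as silent, tonic or burst firing
#'
#' @param train A [spike_train()]; windows of at least 60 s are recommended
#'   (a warning is emitted below that).
#' @param params A [burst_params()].
#' @param criteria A [typing_criteria()].
#' @return One of `"silent"`, `"tonic"`, `"burst"`.
#' @export
classify_neuron <- function(train, params = burst_params(),
                            criteria = typing_criteria()) {
  stopifnot(inherits(train, "spike_train"))
  if (train$t_stop - train$t_start < 60)
    warning("recording window shorter than 60 s; typing may be unreliable")
  if (firing_rate(train) < criteria$silent_rate) return("silent")
  m <- burst_metrics(train, params = params)
  if (m$bursts_per_minute >= criteria$min_bursts_per_min) "burst" else "tonic"
}

#' Proportions of neuron firing types
#'
#' Tabulates silent/tonic/burst labels into counts and proportions; when a
#' second group is supplied the two distributions are compared with a
#' chi-square contingency test via [stats::chisq.test()].
#'
#' @param labels Character vector of labels from [classify_neuron()].
#' @param labels2 Optional second group for a chi-square comparison.
#' @return A list with `counts`, `proportions`, `n`, and (when `labels2`
#'   is given) `chisq` holding the `htest` result.
#' @export
type_proportions <- function(labels, labels2 = NULL) {
  if (!length(labels)) stop_invalid("empty label list")
  lv <- c("silent", "tonic", "burst")
  if (!all(labels %in% lv)) stop_invalid("labels must be silent/tonic/burst")
  counts <- table(factor(labels, levels = lv))
  out <- list(counts = counts, proportions = as.numeric(counts) / length(labels),
              n = length(labels))
  names(out$proportions) <- lv
  if (!is.null(labels2)) {
    counts2 <- table(factor(labels2, levels = lv))
    tab <- rbind(counts, counts2)
    nz <- colSums(tab) > 0
    out$chisq <- stats::chisq.test(tab[, nz, drop = FALSE])
  }
  out
}
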