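#' Binned z-score classification of a unit's drug response
#'
#' The post-injection response of an in vivo unit is scored as
#' `z = (xbar - mu) / sigma`, where `xbar` is the mean of the 100-s-bin
#' metric values during the post-injection window (by default 20-30 min
#' after injection) and `mu`, `sigma` are the mean and standard deviation of
#' the 100-s-bin values during the 10-min pre-injection baseline. A unit is
#' classified inhibited when `z <= -threshold`, excited when
#' `z >= threshold` (threshold 1.67, the two-tailed P < 0.05 point), and
#' unchanged otherwise.
#'
#' Bins tile each window contiguously from its start; bins not fully covered
#' by the recording are dropped. The baseline standard deviation uses the
#' sample (n-1) denominator. A zero baseline sigma makes the unit
#' unclassifiable and raises a degenerate-baseline error.
#'
#' @param session A [session_recording()].
#' @param metric Binned metric, currently `"bursting_spike_frequency"` or
#'   `"bursts_per_minute"`.
#' @param bin Bin width in seconds (default 100).
#' @param baseline_window Offsets (s) of the baseline window relative to the
#'   injection time (default `c(-600, 0)`, the 10 min before injection).
#' @param post_window Offsets (s) of the post window relative to injection
#'   (default `c(1200, 1800)`, i.e. 20-30 min after injection).
#' @param threshold Classification threshold on |z| (default 1.67).
#' @param params [burst_params()] used for the binned metric.
#' @return A list of class `zscore_result`: `z`, `xbar`, `mu`, `sigma`,
#'   `classification`, and the per-bin values `baseline_bins`, `post_bins`.
#' @export
unit_zscore <- function(session, metric = c("bursting_spike_frequency",
                                            "bursts_per_minute"),
                        bin = 100, baseline_window = c(-600, 0),
                        post_window = c(1200, 1800), threshold = 1.67,
                        params = burst_params()) {
  stopifnot(inherits(session, "session_recording"))
  metric <- match.arg(metric)
  check_number(bin, "bin", lower = 0, allow_equal_lower = FALSE)
  tr <- session$train
  inj <- session$injection_time

  bin_values <- function(win) {
    from <- inj + win[1L]; to <- inj + win[2L]
    starts <- seq(from, to - bin + 1e-9, by = bin)
    starts <- starts[starts + bin <= min(to, tr$t_stop) + 1e-9 &
                       starts >= tr$t_start - 1e-9]
    vapply(starts, function(s0) {
      m <- burst_metrics(window_train(tr, s0, s0 + bin), params = params)
      m[[metric]]
    }, numeric(1L))
  }

  base_bins <- bin_values(baseline_window)
  if (length(base_bins) < 2L)
    stop_invalid("baseline must provide at least 2 full bins")
  post_bins <- bin_values(post_window)
  if (!length(post_bins))
    stop_invalid("post window not covered by the recording")
  mu <- mean(base_bins)
  sigma <- stats::sd(base_bins)
  if (sigma == 0)
    stop_invalid("baseline bins have zero variance; unit is unclassifiable",
                 class = "habtrap_degenerate_baseline")
  xbar <- mean(post_bins)
  z <- (xbar - mu) / sigma
  classification <- if (z <= -threshold) "inhibited"
                    else if (z >= threshold) "excited" else "unchanged"
  structure(list(z = z, xbar = xbar, mu = mu, sigma = sigma,
                 classification = classification,
                 baseline_bins = base_bins, post_bins = post_bins),
            class = "zscore_result")
}

#' Split units by basal bursting spike frequency
#'
#' Partitions units into a `> cutoff` Hz group and a `<= cutoff` Hz group on
#' their baseline bursting spike frequency (cutoff 2 Hz by default; a unit
#' exactly at the cutoff goes to the low group, matching the "larger than
#' 2 Hz" wording) and reports the per-group fraction of inhibited units.
#'
#' @param basal_freq Numeric vector of baseline bursting spike frequencies
#'   (Hz), one per unit.
#' @param inhibited Logical vector, same length: was the unit classified
#'   inhibited?
#' @param cutoff Split point in Hz (default 2).
#' @return A list: `high` / `low` (indices), `n_high`, `n_low`,
#'   `frac_high`, per-group `inhibited_fraction`, and
#'   `inhibited_share_high` (share of all inhibited units falling in the
#'   high group).
#' @export
basal_split <- function(basal_freq, inhibited = rep(FALSE, length(basal_freq)),
                        cutoff = 2) {
  if (length(basal_freq) != length(inhibited))
    stop_invalid("`basal_freq` and `inhibited` must have equal length")
  high <- which(basal_freq > cutoff)
  low <- which(basal_freq <= cutoff)
  n_inh <- sum(inhibited)
  list(high = high, low = low,
       n_high = length(high), n_low = length(low),
       frac_high = length(high) / length(basal_freq),
       inhibited_fraction = c(
         high = if (length(high)) mean(inhibited[high]) else NA_real_,
         low = if (length(low)) mean(inhibited[low]) else NA_real_),
       inhibited_share_high = if (n_inh) sum(inhibited[high]) / n_inh else NA_real_)
}

#' Percentage blockade against a reference group
#'
#' `blockade_i = 100 * (mean(reference) - treated_i) / mean(reference)` for
#' each treated value, with the group mean and standard error of those
#' per-value blockades. Blockade is 100 when a treated value is zero, 0 when
#' it equals the reference mean, and may be negative (facilitation).
#'
#' @param reference_values Numeric vector (e.g. saline group), mean must be
#'   nonzero.
#' @param treated_values Numeric vector (e.g. ketamine group).
#' @return A list of class `blockade_stat`: `percent_blockade` (per treated
#'   value), `group_mean`, `sem`.
#' @export
percent_blockade_group <- function(reference_values, treated_values) {
  ref <- mean(reference_values)
  if (!is.finite(ref) || ref == 0)
    stop_invalid("reference mean is zero; blockade undefined",
                 class = "habtrap_undefined_blockade")
  pb <- 100 * (ref - treated_values) / ref
  structure(list(percent_blockade = pb, group_mean = mean(pb),
                 sem = stats::sd(pb) / sqrt(length(pb))),
            class = "blockade_stat")
}

#' Percentage blockade of a time point against its own baseline
#'
#' `100 * (baseline - value) / baseline`; negative values indicate
#' facilitation.
#'
#' @param baseline_value Baseline value (nonzero).
#' @param value_at_t Value at the time point (vectorized).
#' @return Percentage blockade.
#' @export
percent_blockade_timecourse <- function(baseline_value, value_at_t) {
  if (!is.finite(baseline_value) || baseline_value == 0)
    stop_invalid("baseline value is zero; blockade undefined",
                 class = "habtrap_undefined_blockade")
  100 * (baseline_value - value_at_t) / baseline_value
}

#' Classify every unit of a session cohort
#'
#' Convenience wrapper running [unit_zscore()] and a baseline
#' bursting-spike-frequency measurement over a list of sessions.
#'
#' @param sessions List of [session_recording()] (e.g. from [gen_session()]).
#' @param ... Passed to [unit_zscore()].
#' @return A data.frame: `unit_id`, `z`, `classification`, `basal_freq`.
#' @export
classify_units <- function(sessions, ...) {
  rows <- lapply(sessions, function(s) {
    zr <- tryCatch(unit_zscore(s, ...), habtrap_degenerate_baseline = function(e) NULL)
    base <- burst_metrics(window_train(s$train, s$epochs$baseline[1L],
                                       s$epochs$baseline[2L]))
    data.frame(unit_id = s$train$unit_id,
               z = if (is.null(zr)) NA_real_ else zr$z,
               classification = if (is.null(zr)) "unclassifiable"
                                else zr$classification,
               basal_freq = base$bursting_spike_frequency,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
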