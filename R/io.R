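# Plain-text interchange: spike CSVs with JSON epoch sidecars, sweep CSVs
# with JSON metadata sidecars, PK CSVs. All writers round-trip losslessly
# through the corresponding readers (times serialized at full precision).

# serialize numeric columns at 17 significant digits so doubles survive the
# text round trip bit-exactly
#' @keywords internal
write_csv_full <- function(df, path) {
  for (nm in names(df)) if (is.double(df[[nm]]))
    df[[nm]] <- sprintf("%.17g", df[[nm]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write spike trains to CSV (+ JSON epoch sidecar)
#'
#' CSV columns `unit_id,time_s`, one row per spike. When sessions are
#' supplied, the epoch intervals go to a JSON sidecar
#' `{unit_id: {epoch: [start, end]}}` next to the CSV.
#'
#' @param x A [spike_train()], [session_recording()], or a list of either.
#' @param path Output CSV path.
#' @param sidecar Path of the JSON epoch sidecar (default: `path` with
#'   `.epochs.json` extension); only written for session recordings.
#' @return `path`, invisibly.
#' @export
write_spikes_csv <- function(x, path,
                             sidecar = sub("\\.csv$", ".epochs.json", path)) {
  if (inherits(x, c("spike_train", "session_recording"))) x <- list(x)
  trains <- lapply(x, function(e) if (inherits(e, "session_recording")) e$train else e)
  df <- do.call(rbind, lapply(trains, function(tr)
    data.frame(unit_id = rep(tr$unit_id, length(tr$spikes)), time_s = tr$spikes)))
  if (is.null(df)) df <- data.frame(unit_id = character(), time_s = numeric())
  write_csv_full(df, path)
  meta <- lapply(x, function(e) {
    if (inherits(e, "session_recording")) {
      c(e$epochs, list(.window = c(e$train$t_start, e$train$t_stop),
                       .injection_time = e$injection_time))
    } else {
      list(.window = c(e$t_start, e$t_stop))
    }
  })
  names(meta) <- vapply(trains, function(tr) as.character(tr$unit_id), character(1L))
  jsonlite::write_json(meta, sidecar, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read spike trains from CSV (+ JSON epoch sidecar)
#'
#' @param path CSV path written by [write_spikes_csv()].
#' @param sidecar JSON sidecar path.
#' @return A named list of [spike_train()] or [session_recording()]
#'   objects (sessions when the sidecar carries an injection time).
#' @export
read_spikes_csv <- function(path,
                            sidecar = sub("\\.csv$", ".epochs.json", path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  out <- lapply(names(meta), function(uid) {
    m <- meta[[uid]]
    spikes <- df$time_s[df$unit_id == uid]
    tr <- spike_train(sort(spikes), m$.window[1L], m$.window[2L], unit_id = uid)
    if (!is.null(m$.injection_time)) {
      ep <- m[setdiff(names(m), c(".window", ".injection_time"))]
      session_recording(tr, m$.injection_time, epochs = ep)
    } else tr
  })
  names(out) <- names(meta)
  out
}

#' Write a sweep to CSV (+ JSON metadata sidecar)
#'
#' CSV columns `time_s,current_pA`; sidecar carries `holding_mV`,
#' `stim_onset_s`, `stim_intensity_mA`, `sampling_rate_hz`.
#'
#' @param trace A [sweep_trace()].
#' @param path Output CSV path.
#' @param sidecar JSON sidecar path (default `path` with `.meta.json`).
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(trace, path,
                            sidecar = sub("\\.csv$", ".meta.json", path)) {
  stopifnot(inherits(trace, "sweep_trace"))
  write_csv_full(data.frame(time_s = trace$time, current_pA = trace$current),
                 path)
  jsonlite::write_json(list(holding_mV = trace$holding_potential,
                            stim_onset_s = trace$stim_onset,
                            stim_intensity_mA = trace$stim_intensity,
                            sampling_rate_hz = trace$sampling_rate),
                       sidecar, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a sweep from CSV (+ JSON metadata sidecar)
#'
#' @param path CSV path written by [write_sweep_csv()].
#' @param sidecar JSON sidecar path.
#' @return A [sweep_trace()].
#' @export
read_sweep_csv <- function(path, sidecar = sub("\\.csv$", ".meta.json", path)) {
  df <- utils::read.csv(path)
  m <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  sweep_trace(df$time_s, df$current_pA, m$holding_mV, m$stim_onset_s,
              m$stim_intensity_mA, m$sampling_rate_hz)
}

#' Write / read a concentration profile as CSV
#'
#' CSV columns `time_min,conc_uM`.
#' @param profile A [pk_profile()].
#' @param path CSV path.
#' @return `path` invisibly (writer); a [pk_profile()] (reader).
#' @export
write_pk_csv <- function(profile, path) {
  stopifnot(inherits(profile, "pk_profile"))
  write_csv_full(data.frame(time_min = profile$times,
                            conc_uM = profile$concentrations), path)
  invisible(path)
}

#' @rdname write_pk_csv
#' @export
read_pk_csv <- function(path) {
  df <- utils::read.csv(path)
  pk_profile(df$time_min, df$conc_uM)
}
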