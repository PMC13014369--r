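#' iEEG recording container
#'
#' A `soz_recording` holds a multichannel intracranial EEG segment as a
#' channels x samples numeric matrix in microvolts, together with its
#' sampling rate, channel labels, per-channel SOZ (seizure onset zone)
#' labels, seizure onset/offset events, and provenance identifiers.
#'
#' @param signal numeric matrix, channels x samples, in microvolts. All
#'   values must be finite.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per channel. Defaults
#'   to `ch01`, `ch02`, ...
#' @param soz_label logical vector, one flag per channel: `TRUE` for
#'   channels labelled as belonging to the seizure onset zone.
#' @param events data.frame with columns `onset`, `duration`, `trial_type`
#'   (seconds; BIDS-iEEG events convention, `trial_type = "sz_onset"` marks
#'   seizure onset).
#' @param patient_id,seizure_id identifiers carried through downstream
#'   tables.
#' @return an object of class `soz_recording`.
#' @export
new_recording <- function(signal, fs, channel_labels = NULL,
                          soz_label = NULL, events = NULL,
                          patient_id = "P01", seizure_id = "S01") {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("signal must be a numeric channels x samples matrix")
  if (!all(is.finite(signal)))
    stop("signal contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  nch <- nrow(signal)
  if (is.null(channel_labels))
    channel_labels <- sprintf("ch%02d", seq_len(nch))
  if (length(channel_labels) != nch)
    stop("channel_labels length must equal the channel count")
  if (is.null(soz_label)) soz_label <- rep(FALSE, nch)
  if (length(soz_label) != nch)
    stop("soz_label length must equal the channel count")
  if (is.null(events))
    events <- data.frame(onset = numeric(0), duration = numeric(0),
                         trial_type = character(0))
  structure(
    list(signal = signal, fs = fs,
         channel_labels = as.character(channel_labels),
         soz_label = as.logical(soz_label),
         events = events,
         patient_id = patient_id, seizure_id = seizure_id),
    class = "soz_recording")
}

#' @export
print.soz_recording <- function(x, ...) {
  cat(sprintf("<soz_recording> %s/%s: %d channels x %d samples @ %g Hz (%.1f s), %d SOZ-labelled\n",
              x$patient_id, x$seizure_id, nrow(x$signal), ncol(x$signal),
              x$fs, ncol(x$signal) / x$fs, sum(x$soz_label)))
  if (nrow(x$events))
    cat(sprintf("  events: %s\n",
                paste(sprintf("%s@%gs", x$events$trial_type, x$events$onset),
                      collapse = ", ")))
  invisible(x)
}

rec_duration_s <- function(rec) ncol(rec$signal) / rec$fs

#' First seizure onset of a recording
#'
#' @param rec a `soz_recording`.
#' @return onset time in seconds of the first `sz_onset` event.
#' @export
seizure_onset <- function(rec) {
  ev <- rec$events
  ev <- ev[ev$trial_type == "sz_onset", , drop = FALSE]
  if (!nrow(ev)) stop("recording has no sz_onset event")
  min(ev$onset)
}

#' Write a recording in the plain-matrix dialect
#'
#' Writes `<stem>_ieeg.tsv` (samples x channels, tab-separated, header =
#' channel labels), a JSON sidecar `<stem>_ieeg.json` with `fs`,
#' `channel_labels` and `units`, and `<stem>_events.tsv` in BIDS-iEEG form
#' (columns `onset`, `duration`, `trial_type`).
#'
#' @param rec a `soz_recording`.
#' @param dir output directory (created if missing).
#' @param stem file-name stem; default `<patient_id>_<seizure_id>`.
#' @return invisibly, the paths written.
#' @export
write_recording <- function(rec, dir, stem = NULL) {
  if (is.null(stem)) stem <- paste(rec$patient_id, rec$seizure_id, sep = "_")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig_path <- file.path(dir, paste0(stem, "_ieeg.tsv"))
  json_path <- file.path(dir, paste0(stem, "_ieeg.json"))
  ev_path <- file.path(dir, paste0(stem, "_events.tsv"))
  m <- t(rec$signal)
  colnames(m) <- rec$channel_labels
  utils::write.table(format(m, digits = 8, trim = TRUE), sig_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, channel_labels = rec$channel_labels, units = "uV",
         patient_id = rec$patient_id, seizure_id = rec$seizure_id),
    json_path, auto_unbox = TRUE, digits = NA)
  utils::write.table(rec$events, ev_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(signal = sig_path, sidecar = json_path, events = ev_path))
}

#' Read a recording written by [write_recording()]
#'
#' @param dir directory containing the triplet.
#' @param stem file-name stem used at write time.
#' @param soz_label optional logical vector of per-channel SOZ labels (the
#'   plain dialect stores labels in the cohort-level `channels.tsv`, not in
#'   the sidecar).
#' @return a `soz_recording`.
#' @export
read_recording <- function(dir, stem, soz_label = NULL) {
  sidecar <- jsonlite::read_json(file.path(dir, paste0(stem, "_ieeg.json")),
                                 simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(file.path(dir, paste0(stem, "_ieeg.tsv")),
                                   sep = "\t", header = TRUE,
                                   check.names = FALSE))
  dimnames(m) <- NULL
  ev <- utils::read.table(file.path(dir, paste0(stem, "_events.tsv")),
                          sep = "\t", header = TRUE,
                          colClasses = c("numeric", "numeric", "character"))
  new_recording(t(m), fs = sidecar$fs, channel_labels = sidecar$channel_labels,
                soz_label = soz_label, events = ev,
                patient_id = sidecar$patient_id %||% "P01",
                seizure_id = sidecar$seizure_id %||% "S01")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
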