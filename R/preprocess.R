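#' Remove artifact channels
#'
#' Drops the listed channels from a recording and filters the channel
#' label and SOZ label vectors consistently. Artifact identification is
#' visual/manual upstream; this function only applies an exclusion list.
#'
#' @param rec a `soz_recording`.
#' @param bad character vector of channel labels to remove (may be empty).
#' @return the recording without the listed channels.
#' @export
drop_artifact_channels <- function(rec, bad) {
  stopifnot(inherits(rec, "soz_recording"))
  bad <- as.character(bad)
  if (!length(bad)) return(rec)
  unknown <- setdiff(bad, rec$channel_labels)
  if (length(unknown))
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
  keep <- !(rec$channel_labels %in% bad)
  rec$signal <- rec$signal[keep, , drop = FALSE]
  rec$channel_labels <- rec$channel_labels[keep]
  rec$soz_label <- rec$soz_label[keep]
  rec
}

#' Zero-phase notch filter at the mains frequency and harmonics
#'
#' Applies an order-2 Butterworth band-stop filter forward and backward
#' (zero phase, so seizure-onset timing is preserved) at `line_hz` and its
#' first `n_harmonics - 1` harmonics.
#'
#' @param rec a `soz_recording`.
#' @param line_hz mains frequency, Hz.
#' @param n_harmonics how many notch centres (`line_hz`, `2*line_hz`, ...).
#' @param bw_hz stop-band width around each centre, Hz.
#' @return the filtered recording.
#' @export
notch_filter <- function(rec, line_hz = 60, n_harmonics = 3, bw_hz = 2) {
  stopifnot(inherits(rec, "soz_recording"))
  nyq <- rec$fs / 2
  centres <- line_hz * seq_len(n_harmonics)
  if (any(centres + bw_hz / 2 >= nyq))
    stop(sprintf("notch centre %g Hz (+bw/2) is at or above Nyquist (%g Hz)",
                 max(centres), nyq))
  filts <- lapply(centres, function(f0)
    signal::butter(2, c(f0 - bw_hz / 2, f0 + bw_hz / 2) / nyq, type = "stop"))
  for (ch in seq_len(nrow(rec$signal))) {
    x <- rec$signal[ch, ]
    for (flt in filts) x <- signal::filtfilt(flt, x)
    rec$signal[ch, ] <- x
  }
  rec
}

#' Common average reference
#'
#' Re-references every channel by subtracting, at each sample, the mean
#' across all channels. After CAR the across-channel mean is zero at every
#' sample (to floating tolerance); applying CAR twice is idempotent.
#'
#' @param rec a `soz_recording` with at least two channels.
#' @return the re-referenced recording.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "soz_recording"))
  if (nrow(rec$signal) < 2)
    stop("common average reference needs >= 2 channels")
  rec$signal <- sweep(rec$signal, 2, colMeans(rec$signal))
  rec
}

#' Extract the ictal and baseline epochs around seizure onset
#'
#' Cuts the first 20 s after seizure onset (ictal) and the 10 s interval
#' starting 30 s before onset (baseline). Sample indices follow the
#' convention `floor(t * fs)` with half-open intervals `[start, end)`, so
#' epoch lengths are exact to within one sample. No resampling occurs.
#'
#' @param rec a `soz_recording`.
#' @param onset_s seizure onset in seconds; defaults to the recording's
#'   first `sz_onset` event. Must satisfy `onset_s >= 30` (full baseline)
#'   and `onset_s + 20 <= duration` (full ictal window).
#' @param ictal_s,baseline_s,baseline_lead_s epoch geometry in seconds
#'   (defaults 20, 10, 30).
#' @return an object of class `epoch_pair`: list with `ictal` and
#'   `baseline` channels x samples matrices, `fs`, labels and provenance.
#' @export
epoch <- function(rec, onset_s = NULL, ictal_s = 20, baseline_s = 10,
                  baseline_lead_s = 30) {
  stopifnot(inherits(rec, "soz_recording"))
  if (is.null(onset_s)) onset_s <- seizure_onset(rec)
  dur <- rec_duration_s(rec)
  if (onset_s < baseline_lead_s)
    stop(sprintf("onset %g s leaves no room for the baseline window (needs >= %g s of pre-onset data)",
                 onset_s, baseline_lead_s))
  if (onset_s + ictal_s > dur)
    stop(sprintf("onset %g s leaves no room for the ictal window (needs %g s after onset, record is %g s)",
                 onset_s, ictal_s, dur))
  fs <- rec$fs
  cut <- function(from_s, to_s) {
    i0 <- floor(from_s * fs) + 1L
    i1 <- floor(to_s * fs)
    rec$signal[, i0:i1, drop = FALSE]
  }
  structure(
    list(ictal = cut(onset_s, onset_s + ictal_s),
         baseline = cut(onset_s - baseline_lead_s,
                        onset_s - baseline_lead_s + baseline_s),
         fs = fs, channel_labels = rec$channel_labels,
         soz_label = rec$soz_label,
         patient_id = rec$patient_id, seizure_id = rec$seizure_id),
    class = "epoch_pair")
}

#' Full preprocessing chain
#'
#' Fixed-order chain: artifact-channel removal, zero-phase notch filtering,
#' common average reference (computed after bad-channel removal so
#' artifacts cannot contaminate the reference), then epoching.
#'
#' @param rec a `soz_recording`.
#' @param bad_channels labels to exclude before anything else.
#' @param line_hz,n_harmonics,bw_hz notch parameters; `n_harmonics = 0`
#'   skips the notch.
#' @param onset_s seizure onset (default: first `sz_onset` event).
#' @return an `epoch_pair`.
#' @export
preprocess_recording <- function(rec, bad_channels = character(),
                                 line_hz = 60, n_harmonics = 3, bw_hz = 2,
                                 onset_s = NULL) {
  rec <- drop_artifact_channels(rec, bad_channels)
  if (n_harmonics > 0)
    rec <- notch_filter(rec, line_hz = line_hz, n_harmonics = n_harmonics,
                        bw_hz = bw_hz)
  rec <- common_average_reference(rec)
  epoch(rec, onset_s = onset_s)
}
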