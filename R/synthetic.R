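#' Seizure-onset pattern specification
#'
#' Describes one of the eight canonical intracranial seizure-onset
#' morphologies (Lagarde classes A-H) to inject into a synthetic recording:
#'
#' * A — low-voltage fast activity (LVFA): 30-150 Hz chirp of growing
#'   amplitude
#' * B — preictal spiking followed by LVFA
#' * C — polyspike bursts followed by LVFA
#' * D — high-amplitude slow wave followed by LVFA
#' * E — rhythmic 1-2 Hz spike train
#' * F — rhythmic sharp activity, theta/alpha range
#' * G — rhythmic sharp activity, beta range
#' * H — delta-brush: 1-4 Hz slow wave with superimposed 90-150 Hz bursts
#'
#' Morphologies are additive sinusoid/burst templates with amplitude
#' envelopes, not neural-mass simulations; downstream stages consume only
#' band power, for which the spectral signature is what matters.
#'
#' @param pattern_class one of `"A"` ... `"H"`.
#' @param onset_s pattern onset in seconds from record start.
#' @param duration_s pattern duration, seconds (> 0).
#' @param amplitude_gain amplitude of the injected template as a multiple
#'   of the background RMS of the target channel (>= 0; 0 injects nothing).
#' @param carrier_bands character vector of band names the pattern
#'   energizes; defaults per class.
#' @return an object of class `pattern_spec`.
#' @export
pattern_spec <- function(pattern_class, onset_s, duration_s = 20,
                         amplitude_gain = 5, carrier_bands = NULL) {
  pattern_class <- as.character(pattern_class)
  if (!pattern_class %in% LETTERS[1:8])
    stop("unknown pattern class '", pattern_class, "' (expected A..H)")
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (amplitude_gain < 0) stop("amplitude_gain must be >= 0")
  if (is.null(carrier_bands))
    carrier_bands <- default_carrier_bands(pattern_class)
  structure(list(pattern_class = pattern_class, onset_s = onset_s,
                 duration_s = duration_s, amplitude_gain = amplitude_gain,
                 carrier_bands = carrier_bands),
            class = "pattern_spec")
}

default_carrier_bands <- function(cls) {
  switch(cls,
         A = c("gamma", "high_gamma"),
         B = c("gamma", "high_gamma"),
         C = c("gamma", "high_gamma"),
         D = c("delta", "gamma", "high_gamma"),
         E = c("delta", "theta"),
         F = c("theta", "alpha"),
         G = "beta",
         H = c("delta", "high_gamma"))
}

#' Generate multichannel 1/f background iEEG
#'
#' Synthesizes independent per-channel background activity as Gaussian
#' noise with a 1/f^beta amplitude spectrum (frequency-domain shaping,
#' flat below 0.5 Hz), rescaled exactly to a target RMS, plus an optional
#' mains-frequency line component.
#'
#' @param n_channels number of channels.
#' @param duration_s record duration in seconds (>= 60 so that a full
#'   baseline and ictal epoch always fit after a later onset).
#' @param fs sampling rate, Hz (>= 500).
#' @param seed integer seed; identical inputs give bitwise-identical output.
#' @param beta spectral slope of the 1/f^beta background (0 = white).
#' @param target_rms_uv per-channel RMS of the shaped noise, microvolts.
#' @param line_hz mains frequency, Hz (US-centric 60 by default; set 50
#'   for European-style mains).
#' @param line_amp_uv amplitude of the line component, microvolts (0
#'   disables it).
#' @param patient_id,seizure_id provenance identifiers.
#' @return a `soz_recording` with no events and all-FALSE SOZ labels.
#' @export
generate_background <- function(n_channels, duration_s, fs, seed,
                                beta = 1, target_rms_uv = 50,
                                line_hz = 60, line_amp_uv = 5,
                                patient_id = "P01", seizure_id = "S01") {
  if (duration_s < 60) stop("duration_s must be >= 60 s")
  if (fs < 500) stop("fs must be >= 500 Hz")
  if (n_channels < 1) stop("n_channels must be >= 1")
  n <- round(duration_s * fs)
  set.seed(as.integer(seed))
  # spectral shaping gains on the two-sided FFT grid; flat below 0.5 Hz
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)               # fold to physical frequency
  shape <- pmax(f, 0.5)^(-beta / 2)
  shape[1] <- 0                      # no DC
  t_s <- (seq_len(n) - 1) / fs
  line <- line_amp_uv * sin(2 * pi * line_hz * t_s)
  sig <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels)) {
    w <- stats::rnorm(n)
    x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
    x <- x - mean(x)
    x <- x * (target_rms_uv / sqrt(mean(x^2)))
    sig[ch, ] <- x + line
  }
  new_recording(sig, fs = fs, patient_id = patient_id,
                seizure_id = seizure_id)
}

#' Inject a seizure-onset morphology into selected channels
#'
#' Adds the template described by a [pattern_spec()] to the listed channels
#' only; every other channel is returned bit-identical to the input. The
#' template amplitude scales with `amplitude_gain` times the pre-existing
#' RMS of each target channel, so a gain of 0 is an exact identity.
#'
#' @param rec a `soz_recording`.
#' @param channels integer indices or channel labels to inject into.
#' @param spec a [pattern_spec()]. Its `[onset_s, onset_s + duration_s]`
#'   window (and the 5 s preictal lead-in of class B) must lie inside the
#'   record.
#' @return the modified `soz_recording`.
#' @export
inject_onset_pattern <- function(rec, channels, spec) {
  stopifnot(inherits(rec, "soz_recording"), inherits(spec, "pattern_spec"))
  if (is.character(channels)) {
    idx <- match(channels, rec$channel_labels)
    if (anyNA(idx))
      stop("unknown channel label(s): ",
           paste(channels[is.na(idx)], collapse = ", "))
    channels <- idx
  }
  if (!length(channels) || any(channels < 1 | channels > nrow(rec$signal)))
    stop("channel indices out of range")
  dur <- rec_duration_s(rec)
  lead <- if (spec$pattern_class == "B") 5 else 0
  if (spec$onset_s - lead < 0 || spec$onset_s + spec$duration_s > dur)
    stop(sprintf("pattern window [%g, %g] s does not fit inside the %g s record",
                 spec$onset_s - lead, spec$onset_s + spec$duration_s, dur))
  n <- ncol(rec$signal)
  tpl <- onset_template(spec, rec$fs, n)    # unit-amplitude template
  for (ch in channels) {
    amp <- spec$amplitude_gain * sqrt(mean(rec$signal[ch, ]^2))
    rec$signal[ch, ] <- rec$signal[ch, ] + amp * tpl
  }
  rec
}

# Unit-amplitude template over the whole record (zeros outside the pattern
# window).  All classes use deterministic waveforms so cohort generation is
# reproducible from the config seed alone.
onset_template <- function(spec, fs, n_samples) {
  out <- numeric(n_samples)
  t0 <- spec$onset_s
  d <- spec$duration_s
  idx <- which_window(t0, t0 + d, fs, n_samples)
  u <- (idx - 1) / fs - t0                     # time since onset, in [0, d)
  cls <- spec$pattern_class

  lvfa <- function(u, d, f0 = 30, f1 = 150) {
    f1 <- min(f1, 0.8 * fs / 2)
    # linear chirp with a growing envelope (low voltage at onset)
    phase <- 2 * pi * (f0 * u + (f1 - f0) * u^2 / (2 * d))
    (0.15 + 0.85 * u / d) * sin(phase)
  }
  spike <- function(tt, centers, sigma) {
    # biphasic (Gaussian-derivative) transients, unit peak
    s <- numeric(length(tt))
    for (c0 in centers) {
      z <- (tt - c0) / sigma
      s <- s + (-z) * exp(0.5) * exp(-z^2 / 2)
    }
    s
  }

  w <- switch(cls,
    A = lvfa(u, d),
    B = lvfa(u, d),                             # preictal spikes added below
    C = {                                       # polyspike bursts then LVFA
      burst_t <- 3
      w <- numeric(length(u))
      pre <- u < burst_t
      centers <- as.vector(outer(seq(0.2, burst_t - 0.4, by = 1),
                                 seq(0, 0.12, by = 0.04), `+`))
      w[pre] <- 1.5 * spike(u[pre], centers, sigma = 0.008)
      post <- !pre
      w[post] <- lvfa(u[post] - burst_t, d - burst_t)
      w
    },
    D = {                                       # slow wave then LVFA
      w <- lvfa(u, d)
      sw <- u < 1.5
      w[sw] <- w[sw] + 2 * sin(pi * u[sw] / 1.5)
      w
    },
    E = spike(u, seq(0.1, d - 0.1, by = 1 / 1.5), sigma = 0.04) +
        0.7 * sin(2 * pi * 1.5 * u),
    F = sin(2 * pi * 9 * u) + 0.25 * sin(2 * pi * 18 * u),
    G = sin(2 * pi * 20 * u) + 0.25 * sin(2 * pi * 40 * u),
    H = {
      slow <- sin(2 * pi * 2.5 * u)
      brush <- 0.6 * sin(2 * pi * 120 * u) * pmax(slow, 0)
      slow + brush
    })

  # short cosine ramps keep epoch edges free of clicks
  w <- w * edge_ramp(length(w), round(0.25 * fs))
  out[idx] <- w

  if (cls == "B") {                             # 1 Hz spikes in the 5 s lead-in
    pidx <- which_window(t0 - 5, t0, fs, n_samples)
    pt <- (pidx - 1) / fs - (t0 - 5)
    out[pidx] <- out[pidx] +
      1.5 * spike(pt, seq(0.5, 4.5, by = 1), sigma = 0.03)
  }
  out
}

which_window <- function(from_s, to_s, fs, n) {
  i0 <- floor(from_s * fs) + 1L
  i1 <- min(floor(to_s * fs), n)
  seq.int(max(i0, 1L), i1)
}

edge_ramp <- function(n, nr) {
  r <- rep(1, n)
  nr <- min(nr, floor(n / 2))
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    r[seq_len(nr)] <- ramp
    r[n + 1 - seq_len(nr)] <- ramp
  }
  r
}

#' Synthetic cohort configuration
#'
#' @param n_patients number of patients.
#' @param channels_per_patient electrodes per patient.
#' @param soz_channels_per_patient true-SOZ electrodes per patient (strictly
#'   fewer than `channels_per_patient`).
#' @param seizures_per_patient seizure recordings per patient.
#' @param fs sampling rate, Hz (>= 500).
#' @param pattern_assignment list of [pattern_spec()] objects, one per
#'   patient; default cycles classes A-H with the configured gain and an
#'   onset `pre_onset_s` seconds into each record.
#' @param label_noise fraction of true-SOZ channels whose clinician label is
#'   dropped (mislabelled as non-SOZ); a scalar applied to every patient, or
#'   a per-patient vector (recycled).
#' @param outcome_rule if `TRUE`, a patient is seizure-free iff the
#'   clinician-labelled SOZ set covers the true SOZ set (resecting what the
#'   labels say removes the true onset zone).
#' @param seed integer master seed; the full cohort is a pure function of
#'   the config.
#' @param pre_onset_s,post_onset_s seconds of record before/after seizure
#'   onset (defaults 60 + 30 so the 10 s baseline starting 30 s pre-onset
#'   and the 20 s ictal epoch always fit).
#' @param amplitude_gain gain used for default pattern assignment.
#' @param ... further arguments passed to [generate_background()] (e.g.
#'   `beta`, `line_amp_uv`, `target_rms_uv`).
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, channels_per_patient,
                          soz_channels_per_patient, seizures_per_patient,
                          fs = 500, pattern_assignment = NULL,
                          label_noise = 0, outcome_rule = TRUE, seed = 1,
                          pre_onset_s = 60, post_onset_s = 30,
                          amplitude_gain = 5, ...) {
  if (fs < 500) stop("fs must be >= 500 Hz")
  if (any(label_noise < 0 | label_noise > 1))
    stop("label_noise must be in [0, 1]")
  if (soz_channels_per_patient >= channels_per_patient)
    stop("soz_channels_per_patient must be < channels_per_patient")
  if (n_patients < 1 || seizures_per_patient < 1)
    stop("need at least one patient and one seizure each")
  if (is.null(pattern_assignment))
    pattern_assignment <- lapply(seq_len(n_patients), function(i)
      pattern_spec(LETTERS[(i - 1) %% 8 + 1], onset_s = pre_onset_s,
                   duration_s = 20, amplitude_gain = amplitude_gain))
  if (length(pattern_assignment) != n_patients)
    stop("pattern_assignment must have one spec per patient")
  structure(list(n_patients = n_patients,
                 channels_per_patient = channels_per_patient,
                 soz_channels_per_patient = soz_channels_per_patient,
                 seizures_per_patient = seizures_per_patient,
                 fs = fs, pattern_assignment = pattern_assignment,
                 label_noise = rep_len(label_noise, n_patients),
                 outcome_rule = outcome_rule, seed = as.integer(seed),
                 pre_onset_s = pre_onset_s, post_onset_s = post_onset_s,
                 background_args = list(...)),
            class = "cohort_config")
}

#' Generate a synthetic iEEG cohort with known ground truth
#'
#' Produces `n_patients x seizures_per_patient` recordings. Each patient
#' has a fixed true-SOZ electrode set carrying that patient's onset
#' morphology in every seizure; clinician labels are derived from the true
#' set by dropping a `label_noise` fraction of true-SOZ channels; the
#' outcome flag marks a patient seizure-free iff the labelled set covers
#' the true set (when `outcome_rule` is on).
#'
#' @param cfg a [cohort_config()].
#' @param write_dir optional directory: writes `channels.tsv` (patient_id,
#'   name, soz, true_soz), `patients.tsv` (patient_id, outcome) and each
#'   recording in the plain-matrix dialect.
#' @return list with `recordings` (list of `soz_recording`), `channels`
#'   and `patients` data.frames, and the `config`.
#' @export
generate_cohort <- function(cfg, write_dir = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  # pre-draw every random decision so per-recording seeds are independent
  rec_seeds <- matrix(sample.int(.Machine$integer.max,
                                 cfg$n_patients * cfg$seizures_per_patient),
                      cfg$n_patients, cfg$seizures_per_patient)
  duration_s <- cfg$pre_onset_s + cfg$post_onset_s
  recordings <- list()
  chan_rows <- list()
  pat_rows <- list()
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%02d", p)
    true_soz_idx <- sort(sample.int(cfg$channels_per_patient,
                                    cfg$soz_channels_per_patient))
    n_flip <- round(cfg$label_noise[p] * length(true_soz_idx))
    flipped <- if (n_flip > 0) sample(true_soz_idx, n_flip) else integer(0)
    labelled_idx <- setdiff(true_soz_idx, flipped)
    soz_lab <- seq_len(cfg$channels_per_patient) %in% labelled_idx
    true_lab <- seq_len(cfg$channels_per_patient) %in% true_soz_idx
    outcome <- if (cfg$outcome_rule) as.integer(n_flip == 0) else 1L
    spec <- cfg$pattern_assignment[[p]]
    for (s in seq_len(cfg$seizures_per_patient)) {
      sid <- sprintf("S%02d", s)
      rec <- do.call(generate_background,
                     c(list(n_channels = cfg$channels_per_patient,
                            duration_s = duration_s, fs = cfg$fs,
                            seed = rec_seeds[p, s],
                            patient_id = pid, seizure_id = sid),
                       cfg$background_args))
      rec <- inject_onset_pattern(rec, true_soz_idx, spec)
      rec$soz_label <- soz_lab
      rec$events <- data.frame(onset = spec$onset_s,
                               duration = spec$duration_s,
                               trial_type = "sz_onset")
      recordings[[length(recordings) + 1L]] <- rec
    }
    chan_rows[[p]] <- data.frame(patient_id = pid,
                                 name = recordings[[length(recordings)]]$channel_labels,
                                 soz = as.integer(soz_lab),
                                 true_soz = as.integer(true_lab))
    pat_rows[[p]] <- data.frame(patient_id = pid, outcome = outcome)
  }
  cohort <- list(recordings = recordings,
                 channels = do.call(rbind, chan_rows),
                 patients = do.call(rbind, pat_rows),
                 config = cfg)
  if (!is.null(write_dir)) {
    dir.create(write_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(cohort$channels, file.path(write_dir, "channels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cohort$patients, file.path(write_dir, "patients.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (rec in recordings) write_recording(rec, write_dir)
  }
  cohort
}
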