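#' Spectral analysis configuration
#'
#' Sliding-window multitaper settings and the six canonical frequency
#' bands. Defaults: 2.5 s windows advanced in 0.5 s steps, time-bandwidth
#' product NW = 3 with K = 5 DPSS tapers — the usual compromise between
#' variance reduction and spectral resolution for 2.5 s iEEG windows.
#'
#' @param window_s window length, seconds.
#' @param step_s step between window starts, seconds (< `window_s`).
#' @param time_bandwidth dimensionless time-bandwidth product NW.
#' @param n_tapers number of DPSS tapers K (<= 2*NW - 1).
#' @param bands named list of `c(lo, hi)` band edges in Hz; bands are
#'   half-open `[lo, hi)`, must be ordered and non-overlapping.
#' @return an object of class `spectral_config`.
#' @export
spectral_config <- function(window_s = 2.5, step_s = 0.5,
                            time_bandwidth = 3, n_tapers = 5,
                            bands = canonical_bands()) {
  if (!(window_s > step_s && step_s > 0))
    stop("need window_s > step_s > 0")
  if (n_tapers > 2 * time_bandwidth - 1)
    stop("n_tapers must be <= 2*NW - 1")
  lo <- vapply(bands, `[`, numeric(1), 1)
  hi <- vapply(bands, `[`, numeric(1), 2)
  if (any(hi <= lo) || any(lo[-1] < hi[-length(hi)]))
    stop("bands must be ordered and non-overlapping")
  structure(list(window_s = window_s, step_s = step_s,
                 time_bandwidth = time_bandwidth, n_tapers = n_tapers,
                 bands = bands),
            class = "spectral_config")
}

#' The six canonical iEEG frequency bands
#'
#' delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-90 and high
#' gamma 90-150 Hz, as half-open intervals so shared edges are not double
#' counted.
#' @return named list of `c(lo, hi)` pairs (Hz).
#' @export
canonical_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 90), high_gamma = c(90, 150))
}

# DPSS tapers via the symmetric tridiagonal formulation (Percival & Walden).
# Columns are unit-energy tapers, ordered by decreasing concentration.
# Cached per (n, nw, k) because the eigendecomposition dominates cost.
.dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw, k) {
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  w <- nw / n
  t0 <- 0:(n - 1)
  dg <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  od <- t0[-1] * (n - t0[-1]) / 2
  m <- matrix(0, n, n)
  diag(m) <- dg
  m[cbind(1:(n - 1), 2:n)] <- od
  m[cbind(2:n, 1:(n - 1))] <- od
  ev <- eigen(m, symmetric = TRUE)
  v <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    s <- sum(v[, j])
    if (abs(s) > 1e-8) { if (s < 0) v[, j] <- -v[, j] }
    else if (sum((n - t0) * v[, j]) < 0) v[, j] <- -v[, j]
  }
  .dpss_cache[[key]] <- v
  v
}

#' Sliding-window multitaper power spectral density
#'
#' For each window, the PSD is the unweighted average of K DPSS-tapered
#' periodograms, scaled as a one-sided density (uV^2/Hz) so that the
#' integral of the PSD over frequency approximates the windowed signal
#' variance. Windows start at the segment start and advance by `step_s`;
#' windows that would run past the segment end are not produced.
#'
#' @param segment numeric channels x samples matrix (a vector is treated
#'   as one channel).
#' @param fs sampling rate, Hz.
#' @param cfg a [spectral_config()].
#' @return list of class `mt_psd`: `psd` (channels x frequency bins x
#'   windows, all >= 0), `freq` (Hz), `window_centers_s` (relative to
#'   segment start), `fs`, `cfg`.
#' @export
multitaper_psd <- function(segment, fs, cfg = spectral_config()) {
  if (is.vector(segment)) segment <- matrix(segment, nrow = 1)
  stopifnot(inherits(cfg, "spectral_config"))
  nch <- nrow(segment)
  ns <- ncol(segment)
  nwin_len <- round(cfg$window_s * fs)
  nstep <- round(cfg$step_s * fs)
  if (ns < nwin_len)
    stop(sprintf("segment (%d samples) shorter than one %g s window (%d samples)",
                 ns, cfg$window_s, nwin_len))
  n_win <- floor((ns - nwin_len) / nstep) + 1L
  tapers <- dpss_tapers(nwin_len, cfg$time_bandwidth, cfg$n_tapers)
  nfreq <- floor(nwin_len / 2) + 1L
  freq <- (seq_len(nfreq) - 1) * fs / nwin_len
  # one-sided doubling: all bins except DC (and Nyquist when n is even)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nwin_len %% 2 == 0) dbl[nfreq] <- 1
  psd <- array(0, dim = c(nch, nfreq, n_win))
  xt <- t(segment)                               # samples x channels
  for (w in seq_len(n_win)) {
    i0 <- (w - 1L) * nstep
    xw <- xt[(i0 + 1):(i0 + nwin_len), , drop = FALSE]
    acc <- matrix(0, nfreq, nch)
    for (k in seq_len(cfg$n_tapers)) {
      f <- stats::mvfft(xw * tapers[, k])
      acc <- acc + Mod(f[seq_len(nfreq), , drop = FALSE])^2
    }
    psd[, , w] <- t(acc * dbl / (cfg$n_tapers * fs))
  }
  structure(list(psd = psd, freq = freq,
                 window_centers_s = (seq_len(n_win) - 1) * cfg$step_s +
                   cfg$window_s / 2,
                 fs = fs, cfg = cfg),
            class = "mt_psd")
}

#' Aggregate a multitaper PSD into band power
#'
#' Mean PSD over the frequency bins falling in each half-open band
#' `[lo, hi)`, per electrode and window.
#'
#' @param mt an `mt_psd` from [multitaper_psd()].
#' @param cfg a [spectral_config()] supplying the bands (defaults to the
#'   config stored in `mt`).
#' @return object of class `band_power_tensor`: `values` (electrodes x
#'   bands x windows array, uV^2/Hz), `band_names`, `window_centers_s`.
#' @export
band_power <- function(mt, cfg = mt$cfg) {
  stopifnot(inherits(mt, "mt_psd"))
  nyq <- mt$fs / 2
  hi <- vapply(cfg$bands, `[`, numeric(1), 2)
  if (any(hi > nyq))
    stop(sprintf("band upper edge %g Hz exceeds Nyquist (%g Hz)", max(hi), nyq))
  nb <- length(cfg$bands)
  d <- dim(mt$psd)
  vals <- array(0, dim = c(d[1], nb, d[3]),
                dimnames = list(NULL, names(cfg$bands), NULL))
  for (b in seq_len(nb)) {
    sel <- mt$freq >= cfg$bands[[b]][1] & mt$freq < cfg$bands[[b]][2]
    if (!any(sel))
      stop("no frequency bins inside band ", names(cfg$bands)[b])
    vals[, b, ] <- apply(mt$psd[, sel, , drop = FALSE], c(1, 3), mean)
  }
  structure(list(values = vals, band_names = names(cfg$bands),
                 window_centers_s = mt$window_centers_s),
            class = "band_power_tensor")
}

#' Band power of one epoch in a single call
#'
#' Convenience wrapper: [multitaper_psd()] followed by [band_power()].
#'
#' @param segment channels x samples matrix.
#' @param fs sampling rate, Hz.
#' @param cfg a [spectral_config()].
#' @return a `band_power_tensor`.
#' @export
epoch_band_power <- function(segment, fs, cfg = spectral_config()) {
  band_power(multitaper_psd(segment, fs, cfg))
}

#' Long-format band-power table
#'
#' Flattens a `band_power_tensor` into the CSV-friendly long format used
#' for export: one row per electrode/band/window.
#'
#' @param bp a `band_power_tensor`.
#' @param channel_labels electrode names (default `e1`, `e2`, ...).
#' @param patient_id,seizure_id,epoch_name provenance columns.
#' @return data.frame with columns electrode, band, window_center_s,
#'   power_uv2_per_hz, patient_id, seizure_id, epoch.
#' @export
band_power_long <- function(bp, channel_labels = NULL, patient_id = NA,
                            seizure_id = NA, epoch_name = "ictal") {
  stopifnot(inherits(bp, "band_power_tensor"))
  d <- dim(bp$values)
  if (is.null(channel_labels)) channel_labels <- paste0("e", seq_len(d[1]))
  out <- expand.grid(electrode = channel_labels, band = bp$band_names,
                     window_center_s = bp$window_centers_s,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$power_uv2_per_hz <- as.vector(bp$values)
  out$patient_id <- patient_id
  out$seizure_id <- seizure_id
  out$epoch <- epoch_name
  out
}
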