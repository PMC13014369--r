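#' Group mean and SEM power over time for SOZ vs non-SOZ electrodes
#'
#' @param bp a `band_power_tensor` (electrodes x bands x windows).
#' @param soz logical vector, one flag per electrode; both groups must be
#'   non-empty.
#' @return data.frame with columns band, group (`"SOZ"`/`"nonSOZ"`),
#'   window_center_s, mean, sem, n. SEM is sd/sqrt(n), with the sd of a
#'   single electrode defined as 0.
#' @export
group_mean_sem <- function(bp, soz) {
  stopifnot(inherits(bp, "band_power_tensor"))
  soz <- as.logical(soz)
  if (length(soz) != dim(bp$values)[1])
    stop("soz label vector must align with electrodes")
  if (!any(soz) || all(soz))
    stop("both SOZ and non-SOZ groups must be non-empty")
  rows <- list()
  for (g in c(TRUE, FALSE)) {
    sub <- bp$values[soz == g, , , drop = FALSE]
    n <- dim(sub)[1]
    mu <- apply(sub, c(2, 3), mean)
    sem <- if (n > 1) apply(sub, c(2, 3), stats::sd) / sqrt(n) else mu * 0
    for (b in seq_along(bp$band_names))
      rows[[length(rows) + 1L]] <- data.frame(
        band = bp$band_names[b], group = if (g) "SOZ" else "nonSOZ",
        window_center_s = bp$window_centers_s,
        mean = mu[b, ], sem = sem[b, ], n = n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trapezoidal area under a power-over-time series
#'
#' @param series numeric vector of W >= 2 values.
#' @param centers strictly increasing window-centre times, seconds.
#' @return scalar AUC (uV^2/Hz * s for power series).
#' @export
auc_over_time <- function(series, centers) {
  if (length(series) < 2) stop("need at least two points for an AUC")
  if (length(series) != length(centers))
    stop("series and centers lengths differ")
  if (any(diff(centers) <= 0)) stop("centers must be strictly increasing")
  sum(0.5 * (series[-1] + series[-length(series)]) * diff(centers))
}

#' Per-seizure AUC records for group mean power
#'
#' For one seizure's ictal band-power tensor, computes the group-mean power
#' series (SOZ and non-SOZ) per band and its AUC over the analysis window —
#' one record per band x electrode group, tagged with the patient's
#' outcome group.
#'
#' @param bp a `band_power_tensor` for the ictal epoch of one seizure.
#' @param soz per-electrode SOZ labels.
#' @param outcome outcome group label, e.g. `"seizure_free"` /
#'   `"not_seizure_free"`.
#' @param patient_id,seizure_id provenance.
#' @return data.frame: patient_id, seizure_id, outcome, group, band, auc.
#' @export
auc_records <- function(bp, soz, outcome, patient_id = NA, seizure_id = NA) {
  gs <- group_mean_sem(bp, soz)
  out <- do.call(rbind, lapply(split(gs, list(gs$band, gs$group)), function(d)
    data.frame(patient_id = patient_id, seizure_id = seizure_id,
               outcome = outcome, group = d$group[1], band = d$band[1],
               auc = auc_over_time(d$mean, d$window_center_s))))
  rownames(out) <- NULL
  out
}

#' Compare AUC distributions across the four outcome/electrode groups
#'
#' Welch two-sample t-tests per band for the four group pairs
#' (SF = seizure-free, NSF = not seizure-free):
#' SF-SOZ vs SF-nonSOZ, NSF-SOZ vs NSF-nonSOZ, SF-SOZ vs NSF-SOZ,
#' SF-nonSOZ vs NSF-nonSOZ. P-values are Bonferroni-corrected for the
#' full family of `m` comparisons (default 24 = 6 bands x 4 pairs).
#' A cell with fewer than 2 records flags the contrast rather than
#' silently dropping it.
#'
#' @param records data.frame as returned by [auc_records()] (rows may be
#'   concatenated over seizures); `outcome` must have exactly two levels,
#'   the seizure-free level first alphabetically is taken as printed.
#' @param sf_level,nsf_level the `outcome` values denoting seizure-free
#'   and not-seizure-free.
#' @param m Bonferroni family size.
#' @return data.frame: band, pair, n1, n2, t, df, p_raw, p_adj, degenerate.
#' @export
compare_auc_groups <- function(records, sf_level = "seizure_free",
                               nsf_level = "not_seizure_free", m = 24) {
  pairs <- list(
    SF_SOZ_vs_SF_nonSOZ   = list(c(sf_level, "SOZ"),  c(sf_level, "nonSOZ")),
    NSF_SOZ_vs_NSF_nonSOZ = list(c(nsf_level, "SOZ"), c(nsf_level, "nonSOZ")),
    SF_SOZ_vs_NSF_SOZ     = list(c(sf_level, "SOZ"),  c(nsf_level, "SOZ")),
    SF_nonSOZ_vs_NSF_nonSOZ = list(c(sf_level, "nonSOZ"), c(nsf_level, "nonSOZ")))
  cell <- function(band, key)
    records$auc[records$band == band & records$outcome == key[1] &
                records$group == key[2]]
  rows <- list()
  for (band in unique(records$band)) {
    for (pn in names(pairs)) {
      x <- cell(band, pairs[[pn]][[1]])
      y <- cell(band, pairs[[pn]][[2]])
      if (length(x) < 2 || length(y) < 2) {
        rows[[length(rows) + 1L]] <- data.frame(
          band = band, pair = pn, n1 = length(x), n2 = length(y),
          t = NA_real_, df = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
          degenerate = TRUE)
        next
      }
      tt <- stats::t.test(x, y)        # Welch by default
      rows[[length(rows) + 1L]] <- data.frame(
        band = band, pair = pn, n1 = length(x), n2 = length(y),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p_raw = tt$p.value, p_adj = min(1, m * tt$p.value),
        degenerate = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value, computed from group means, standard
#' deviations and sizes. Degenerate case sd1 = sd2 = 0: p = 1 when the
#' means are equal, p = 0 otherwise (flagged).
#'
#' @param mean1,sd1,n1 first group summary (n1 >= 2, sd1 >= 0).
#' @param mean2,sd2,n2 second group summary.
#' @return list with `t`, `df`, `p`, `degenerate` flag.
#' @export
welch_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  if (sd1 == 0 && sd2 == 0) {
    eq <- isTRUE(all.equal(mean1, mean2))
    return(list(t = if (eq) 0 else Inf * sign(mean1 - mean2),
                df = n1 + n2 - 2, p = if (eq) 1 else 0, degenerate = TRUE))
  }
  se2 <- sd1^2 / n1 + sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Decile table of electrode power distributions
#'
#' For each band, electrode group (SOZ / non-SOZ) and time window, the
#' 10th...100th percentiles (10% increments, linear-interpolation
#' convention, i.e. `quantile(type = 7)`) of the member-electrode power
#' distribution.
#'
#' @param bp a `band_power_tensor`.
#' @param soz per-electrode SOZ labels; both groups must be non-empty.
#' @return object of class `decile_table`: 4-d array `deciles` indexed
#'   [group, band, decile, window] with groups `SOZ`/`nonSOZ` and deciles
#'   `d10`...`d100`, plus `band_names` and `window_centers_s`.
#' @export
decile_table <- function(bp, soz) {
  stopifnot(inherits(bp, "band_power_tensor"))
  soz <- as.logical(soz)
  if (length(soz) != dim(bp$values)[1])
    stop("soz label vector must align with electrodes")
  if (!any(soz) || all(soz))
    stop("both SOZ and non-SOZ groups must be non-empty")
  probs <- seq(0.1, 1, by = 0.1)
  nb <- length(bp$band_names)
  nw <- dim(bp$values)[3]
  dec <- array(NA_real_, dim = c(2, nb, 10, nw),
               dimnames = list(c("SOZ", "nonSOZ"), bp$band_names,
                               paste0("d", seq(10, 100, 10)), NULL))
  for (gi in 1:2) {
    sub <- bp$values[soz == (gi == 1), , , drop = FALSE]
    for (b in seq_len(nb)) for (w in seq_len(nw))
      dec[gi, b, , w] <- stats::quantile(sub[, b, w], probs = probs,
                                         type = 7, names = FALSE)
  }
  structure(list(deciles = dec, band_names = bp$band_names,
                 window_centers_s = bp$window_centers_s),
            class = "decile_table")
}

#' Decile-ratio features for outcome prediction
#'
#' Within each band, group and time window the 10 decile values are
#' min-max mapped onto `[1, 10]` (a degenerate all-equal profile maps to
#' 1 for every decile, so the ratio is 1, never undefined). The feature is
#' the ratio of normalized SOZ over normalized non-SOZ power per decile
#' and window; all ratios lie in `[0.1, 10]`.
#'
#' @param dt a [decile_table()].
#' @return list of class `decile_ratio_features`: `per_band` (list of
#'   10 x W ratio matrices, one per band) and `features` (named numeric
#'   vector, `band.dXX.wYY` flattened).
#' @export
decile_ratio_features <- function(dt) {
  stopifnot(inherits(dt, "decile_table"))
  norm110 <- function(v) {
    r <- max(v) - min(v)
    if (r == 0) rep(1, length(v)) else 1 + 9 * (v - min(v)) / r
  }
  nb <- length(dt$band_names)
  nw <- dim(dt$deciles)[4]
  per_band <- vector("list", nb)
  names(per_band) <- dt$band_names
  for (b in seq_len(nb)) {
    rat <- matrix(NA_real_, 10, nw,
                  dimnames = list(dimnames(dt$deciles)[[3]], NULL))
    for (w in seq_len(nw)) {
      s <- norm110(dt$deciles["SOZ", b, , w])
      ns <- norm110(dt$deciles["nonSOZ", b, , w])
      rat[, w] <- s / ns
    }
    per_band[[b]] <- rat
  }
  feats <- unlist(lapply(seq_len(nb), function(b) {
    v <- as.vector(per_band[[b]])
    names(v) <- as.vector(outer(rownames(per_band[[b]]),
                                sprintf("w%02d", seq_len(nw)),
                                function(a, b2) paste(dt$band_names[b], a, b2,
                                                      sep = ".")))
    v
  }))
  structure(list(per_band = per_band, features = feats),
            class = "decile_ratio_features")
}
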