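# Independent oracles. These deliberately avoid the package's code paths:
# dense-matrix DPSS, explicit DFT loops, O(n^2) pair counting, exhaustive
# threshold scans.

# DPSS via the dense sinc-Toeplitz concentration matrix (as opposed to the
# package's tridiagonal formulation).
oracle_dpss <- function(n, nw, k) {
  w <- nw / n
  ij <- outer(0:(n - 1), 0:(n - 1), `-`)
  s <- ifelse(ij == 0, 2 * w, sin(2 * pi * w * ij) / (pi * ij))
  v <- eigen(s, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  apply(v, 2, function(col) col / sqrt(sum(col^2)))
}

# Single-window multitaper PSD with an explicit O(n^2) discrete Fourier
# transform and an unweighted mean over tapers; one-sided density scaling.
oracle_mt_psd_1win <- function(x, fs, nw, k) {
  n <- length(x)
  tapers <- oracle_dpss(n, nw, k)
  nfreq <- floor(n / 2) + 1
  t0 <- 0:(n - 1)
  psd <- numeric(nfreq)
  for (fi in seq_len(nfreq)) {
    f <- (fi - 1) / n
    e <- exp(-2i * pi * f * t0)
    acc <- 0
    for (kk in seq_len(k)) acc <- acc + Mod(sum(x * tapers[, kk] * e))^2
    dbl <- if (fi == 1 || (n %% 2 == 0 && fi == nfreq)) 1 else 2
    psd[fi] <- dbl * acc / (k * fs)
  }
  psd
}

oracle_trapz <- function(y, x) {
  s <- 0
  for (i in seq_len(length(y) - 1))
    s <- s + 0.5 * (y[i] + y[i + 1]) * (x[i + 1] - x[i])
  s
}

# all-pairs ROC AUC: ties count one half
oracle_roc_auc <- function(probs, labels) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# exhaustive scans over every threshold in [0, 1] that changes the
# labelling (all unique probabilities and a value above the maximum)
oracle_best_ppv_threshold <- function(probs, labels, ppv_min) {
  cands <- c(sort(unique(probs)), max(probs) + 1)
  best <- list(theta = max(probs) + 1, tp = 0, feasible = FALSE)
  for (th in cands) {
    pos <- probs >= th
    if (!sum(pos)) next
    tp <- sum(pos & labels == 1)
    if (tp / sum(pos) >= ppv_min && tp > best$tp)
      best <- list(theta = th, tp = tp, feasible = TRUE)
  }
  best
}

oracle_best_accuracy <- function(probs, labels) {
  cands <- c(sort(unique(probs)), max(probs) + 1)
  max(vapply(cands, function(th) mean((probs >= th) == labels), numeric(1)))
}
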