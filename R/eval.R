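#' Confusion-matrix metrics
#'
#' Computes accuracy, PPV, NPV, sensitivity and specificity from the four
#' counts. Any metric with a zero denominator is returned as `NA` and
#' named in the `undefined` field — never silently reported as 0.
#'
#' @param tp,fp,tn,fn non-negative counts with a positive total.
#' @return object of class `confusion_metrics`: the four counts plus the
#'   five metrics and `undefined` (character vector of metrics whose
#'   denominator was zero).
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (sum(counts) == 0) stop("all counts are zero")
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  m <- list(tp = tp, fp = fp, tn = tn, fn = fn,
            accuracy = (tp + tn) / sum(counts),
            ppv = frac(tp, tp + fp),
            npv = frac(tn, tn + fn),
            sensitivity = frac(tp, tp + fn),
            specificity = frac(tn, tn + fp))
  m$undefined <- names(which(vapply(m[c("ppv", "npv", "sensitivity",
                                        "specificity")], is.na, logical(1))))
  structure(m, class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  for (k in c("accuracy", "ppv", "npv", "sensitivity", "specificity"))
    cat(sprintf("  %-12s %s\n", k,
                if (is.na(x[[k]])) "undefined" else
                  sprintf("%.1f%%", pct_round(100 * x[[k]]))))
  invisible(x)
}

# round-half-away-from-zero at 1 decimal, matching clinical reporting
pct_round <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10

#' Confusion metrics from predictions and labels
#'
#' @param pred binary predictions (0/1 or logical).
#' @param labels binary ground truth.
#' @return a [confusion_metrics()] object.
#' @export
confusion_from_predictions <- function(pred, labels) {
  pred <- as.integer(as.logical(pred))
  labels <- as.integer(as.logical(labels))
  confusion_metrics(tp = sum(pred == 1 & labels == 1),
                    fp = sum(pred == 1 & labels == 0),
                    tn = sum(pred == 0 & labels == 0),
                    fn = sum(pred == 0 & labels == 1))
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney formulation with midranks for ties: the probability that a
#' randomly chosen positive outranks a randomly chosen negative, ties
#' counting one half.
#'
#' @param probs predicted scores.
#' @param labels binary labels; both classes must be present.
#' @return scalar in `[0, 1]`.
#' @export
roc_auc <- function(probs, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("ROC AUC needs both classes present")
  r <- rank(probs)                 # midranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Meta-learner band-importance coefficients
#'
#' Extracts the GLM meta-learner's per-band coefficients from a fitted
#' SRFE (and, when fold models are given, their mean and sd across folds)
#' and reports the bands ranked by absolute coefficient.
#'
#' @param model a fitted `srfe_model` (may be `NULL` if `per_fold_models`
#'   is given).
#' @param per_fold_models optional list of fold `srfe_model`s from
#'   [lopo_cv()].
#' @return data.frame: band, coefficient (from `model`, or the fold mean),
#'   mean, sd (across folds; NA without folds), rank (1 = largest |coef|).
#' @export
band_importance <- function(model = NULL, per_fold_models = NULL) {
  if (is.null(model) && !length(per_fold_models))
    stop("need a fitted model or fold models")
  pick <- function(m) m$coefficients[-1]
  if (!is.null(model)) {
    if (is.null(model$coefficients)) stop("model is not fitted")
    co <- pick(model)
  }
  if (length(per_fold_models)) {
    mat <- vapply(per_fold_models, pick,
                  numeric(length(pick(per_fold_models[[1]]))))
    mu <- rowMeans(mat)
    sdv <- apply(mat, 1, stats::sd)
    if (is.null(model)) co <- mu
  } else {
    mu <- rep(NA_real_, length(co))
    sdv <- mu
  }
  out <- data.frame(band = names(co), coefficient = unname(co),
                    mean = unname(mu), sd = unname(sdv))
  out$rank <- rank(-abs(out$coefficient), ties.method = "first")
  out[order(out$rank), ]
}

#' Per-band variable importance over time
#'
#' The impurity-decrease importance of each base forest's time-window
#' features, normalized to sum to 1 within each band (a degenerate
#' all-zero band maps to the uniform profile).
#'
#' @param base_models named list of fitted per-band `ranger` forests (e.g.
#'   `model$base` of an `srfe_model`), trained with impurity importance.
#' @param window_centers_s optional window-centre times for the long
#'   format.
#' @return object of class `importance_over_time`: `matrix` (band x
#'   window, rows sum to 1) and `long` data.frame (band, window,
#'   window_center_s, importance).
#' @export
varimp_over_time <- function(base_models, window_centers_s = NULL) {
  imp <- t(vapply(base_models, function(m) {
    v <- ranger::importance(m)
    v <- pmax(v, 0)
    if (sum(v) == 0) rep(1 / length(v), length(v)) else v / sum(v)
  }, numeric(length(ranger::importance(base_models[[1]])))))
  rownames(imp) <- names(base_models)
  w <- seq_len(ncol(imp))
  if (is.null(window_centers_s)) window_centers_s <- rep(NA_real_, ncol(imp))
  long <- data.frame(band = rep(rownames(imp), each = ncol(imp)),
                     window = rep(w, times = nrow(imp)),
                     window_center_s = rep(window_centers_s, times = nrow(imp)),
                     importance = as.vector(t(imp)))
  structure(list(matrix = imp, long = long), class = "importance_over_time")
}

#' Long-format heatmap export
#'
#' Band-power values in long format with electrodes ordered so that
#' SOZ-labelled channels are grouped last (the bottom of a heatmap), and
#' a flag for predicted-SOZ channels. Power values pass through unchanged.
#'
#' @param bp a `band_power_tensor`.
#' @param soz per-electrode SOZ labels.
#' @param predicted per-electrode predicted-SOZ flags.
#' @param channel_labels electrode names.
#' @return data.frame: electrode (factor, SOZ levels last), band,
#'   window_center_s, power_uv2_per_hz, soz, predicted.
#' @export
heatmap_export <- function(bp, soz, predicted, channel_labels = NULL) {
  stopifnot(inherits(bp, "band_power_tensor"))
  ne <- dim(bp$values)[1]
  if (length(soz) != ne || length(predicted) != ne)
    stop("soz / predicted label vectors must align with electrodes")
  if (is.null(channel_labels)) channel_labels <- paste0("e", seq_len(ne))
  soz <- as.logical(soz)
  ord <- order(soz, seq_len(ne))     # non-SOZ first, SOZ grouped last
  long <- band_power_long(bp, channel_labels)
  long$soz <- rep(soz, times = length(bp$band_names) *
                    length(bp$window_centers_s))
  long$predicted <- rep(as.logical(predicted),
                        times = length(bp$band_names) *
                          length(bp$window_centers_s))
  long$electrode <- factor(long$electrode,
                           levels = channel_labels[ord])
  long[order(long$band, long$window_center_s, long$electrode), ] ->
    long
  rownames(long) <- NULL
  long
}

#' Write a metrics report as JSON
#'
#' @param cm a [confusion_metrics()] object.
#' @param auc optional ROC AUC to include.
#' @param path output path.
#' @return invisibly, the list written.
#' @export
export_metrics_json <- function(cm, auc = NULL, path) {
  x <- cm[c("tp", "fp", "tn", "fn", "accuracy", "ppv", "npv",
            "sensitivity", "specificity")]
  if (!is.null(auc)) x$roc_auc <- auc
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(x)
}
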