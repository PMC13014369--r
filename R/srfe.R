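#' Stacked random-forest ensemble configuration
#'
#' The SRFE trains one 100-tree random forest per frequency band and
#' combines the six per-band probabilities with a penalized logistic GLM
#' meta-learner. The electrode model uses ridge (`meta_alpha = 0`) with a
#' cross-validated lambda search; the outcome model uses an elastic net
#' with `meta_alpha = 0.5` and `meta_lambda = 0.1` (fixed, to avoid
#' over-regularizing already normalized ratio features).
#'
#' @param n_trees trees per base forest.
#' @param meta_alpha elastic-net mixing parameter in `[0, 1]` (0 = ridge).
#' @param meta_lambda penalty strength, or `"search"` for selection by
#'   internal cross-validated deviance.
#' @param rf_seed integer seed driving forest growth and fold assignment.
#' @param stack_nfolds internal CV folds used to produce out-of-fold base
#'   probabilities for meta-training (standard stacking hygiene: the
#'   meta-learner never sees in-sample base fits).
#' @return an object of class `srfe_config`.
#' @export
srfe_config <- function(n_trees = 100, meta_alpha = 0,
                        meta_lambda = "search", rf_seed = 1,
                        stack_nfolds = 5) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (meta_alpha < 0 || meta_alpha > 1) stop("meta_alpha must be in [0, 1]")
  if (!identical(meta_lambda, "search") &&
      (!is.numeric(meta_lambda) || meta_lambda < 0))
    stop("meta_lambda must be >= 0 or \"search\"")
  structure(list(n_trees = n_trees, meta_alpha = meta_alpha,
                 meta_lambda = meta_lambda, rf_seed = as.integer(rf_seed),
                 stack_nfolds = stack_nfolds),
            class = "srfe_config")
}

as_binary_factor <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  factor(as.integer(y), levels = c(0, 1))
}

#' Train one per-band random forest
#'
#' A 100-tree (by default) probability forest on one band's
#' time-window features, with impurity variable importance for the
#' importance-over-time report.
#'
#' @param x numeric feature matrix (rows = electrode x seizure instances,
#'   columns = analysis time windows).
#' @param y binary labels (0/1 or logical); both classes must be present.
#' @param n_trees number of trees.
#' @param seed integer seed (forests are deterministic given it).
#' @return a fitted `ranger` probability forest.
#' @export
train_band_rf <- function(x, y, n_trees = 100, seed = 1) {
  y <- as_binary_factor(y)
  if (length(unique(y[!is.na(y)])) < 2)
    stop("labels contain a single class; cannot train a classifier")
  # min.node.size 1: grow to purity as classification forests do (the
  # probability-forest default of 10 would leave tiny training sets unsplit)
  ranger::ranger(x = as.data.frame(x), y = y, num.trees = n_trees,
                 probability = TRUE, importance = "impurity",
                 min.node.size = 1, seed = seed, num.threads = 1)
}

rf_prob <- function(model, x)
  stats::predict(model, data = as.data.frame(x),
                 num.threads = 1)$predictions[, "1"]

# stratified fold assignment, deterministic under the current RNG state
make_folds <- function(y, nfolds) {
  y <- as.integer(as.character(as_binary_factor(y)))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  fold
}

# out-of-fold probabilities of a forest trained on (x, y)
oof_rf_probs <- function(x, y, n_trees, seed, nfolds) {
  x <- as.matrix(x)
  fold <- make_folds(y, nfolds)
  p <- numeric(nrow(x))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    m <- train_band_rf(x[tr, , drop = FALSE], y[tr], n_trees, seed + f)
    p[!tr] <- rf_prob(m, x[!tr, , drop = FALSE])
  }
  p
}

fit_meta_glm <- function(z, y, cfg) {
  y <- as_binary_factor(y)
  if (identical(cfg$meta_lambda, "search")) {
    ycount <- min(table(y))
    if (ycount >= 3) {
      foldid <- make_folds(y, min(5, ycount))   # stratified: every CV fold
      cv <- glmnet::cv.glmnet(z, y, family = "binomial",   # sees both classes
                              alpha = cfg$meta_alpha, foldid = foldid)
      return(list(fit = cv$glmnet.fit, lambda = cv$lambda.min))
    }
    # too few minority-class rows for an inner CV: modest fixed ridge penalty
    cfg$meta_lambda <- 0.1
  }
  {
    lam <- cfg$meta_lambda
    path <- sort(unique(c(lam * c(16, 8, 4, 2), lam)), decreasing = TRUE)
    fit <- glmnet::glmnet(z, y, family = "binomial",
                          alpha = cfg$meta_alpha, lambda = path)
    list(fit = fit, lambda = lam)
  }
}

#' Train a stacked random-forest ensemble
#'
#' Fits one random forest per band on the full training rows, obtains
#' out-of-fold base probabilities by internal stratified cross-validation,
#' and fits the penalized logistic meta-learner on those out-of-fold
#' probability columns (never on in-sample base fits).
#'
#' @param band_x named list of per-band feature matrices, identical row
#'   order, aligned with `labels`.
#' @param labels binary labels (0/1 or logical).
#' @param cfg an [srfe_config()].
#' @return object of class `srfe_model`: `base` (list of forests),
#'   `meta` (glmnet fit + lambda), `coefficients` (intercept + one
#'   coefficient per band), `oof_probs` (meta-training matrix),
#'   `train_probs` (ensemble probabilities on the out-of-fold columns,
#'   used for threshold tuning), `threshold` (NA until tuned), `cfg`.
#' @export
train_srfe <- function(band_x, labels, cfg = srfe_config()) {
  stopifnot(is.list(band_x), length(band_x) >= 1)
  labels <- as.integer(as.logical(labels))
  set.seed(cfg$rf_seed)
  base <- lapply(seq_along(band_x), function(b)
    train_band_rf(band_x[[b]], labels, cfg$n_trees, cfg$rf_seed + 1000 * b))
  names(base) <- names(band_x)
  z <- vapply(seq_along(band_x), function(b)
    oof_rf_probs(band_x[[b]], labels, cfg$n_trees, cfg$rf_seed + 1000 * b,
                 cfg$stack_nfolds),
    numeric(length(labels)))
  colnames(z) <- names(band_x)
  meta <- fit_meta_glm(z, labels, cfg)
  co <- as.numeric(stats::coef(meta$fit, s = meta$lambda))
  names(co) <- c("(Intercept)", names(band_x))
  train_probs <- as.numeric(stats::predict(meta$fit, newx = z,
                                           s = meta$lambda,
                                           type = "response"))
  structure(list(base = base, meta = meta, coefficients = co,
                 oof_probs = z, train_probs = train_probs,
                 band_names = names(band_x), threshold = NA_real_,
                 cfg = cfg),
            class = "srfe_model")
}

#' Predict ensemble probabilities
#'
#' @param object an `srfe_model`.
#' @param band_x named list of per-band feature matrices (same bands and
#'   column layout as at training).
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict.srfe_model <- function(object, band_x, ...) {
  z <- vapply(seq_along(object$base), function(b)
    rf_prob(object$base[[b]], band_x[[b]]),
    numeric(nrow(as.matrix(band_x[[1]]))))
  if (is.vector(z)) z <- matrix(z, nrow = 1)
  colnames(z) <- object$band_names
  as.numeric(stats::predict(object$meta$fit, newx = z,
                            s = object$meta$lambda, type = "response"))
}

#' Single random-forest baseline on all bands concatenated
#'
#' One forest on the concatenation of all six bands' time-window features
#' (6 x W columns), tuned with the same threshold protocol as the SRFE.
#'
#' @param band_x named list of per-band feature matrices.
#' @param labels binary labels.
#' @param cfg an [srfe_config()].
#' @return object of class `simple_rf_model` with `model`, `train_probs`
#'   (out-of-fold), `threshold`, `cfg`.
#' @export
simple_rf_baseline <- function(band_x, labels, cfg = srfe_config()) {
  labels <- as.integer(as.logical(labels))
  x <- do.call(cbind, lapply(seq_along(band_x), function(b) {
    m <- as.matrix(band_x[[b]])
    colnames(m) <- paste(names(band_x)[b], seq_len(ncol(m)), sep = "_w")
    m
  }))
  set.seed(cfg$rf_seed)
  model <- train_band_rf(x, labels, cfg$n_trees, cfg$rf_seed)
  oof <- oof_rf_probs(x, labels, cfg$n_trees, cfg$rf_seed, cfg$stack_nfolds)
  structure(list(model = model, train_probs = oof, threshold = NA_real_,
                 cfg = cfg, band_names = names(band_x)),
            class = "simple_rf_model")
}

#' @export
predict.simple_rf_model <- function(object, band_x, ...) {
  x <- do.call(cbind, lapply(seq_along(band_x), function(b) {
    m <- as.matrix(band_x[[b]])
    colnames(m) <- paste(object$band_names[b], seq_len(ncol(m)), sep = "_w")
    m
  }))
  rf_prob(object$model, x)
}

#' Averaged random-forest baseline
#'
#' Per-band forests combined by the unweighted mean of the six
#' probabilities, with no meta-learner.
#'
#' @param band_x named list of per-band feature matrices.
#' @param labels binary labels.
#' @param cfg an [srfe_config()].
#' @return object of class `averaged_rf_model`.
#' @export
averaged_rf_baseline <- function(band_x, labels, cfg = srfe_config()) {
  labels <- as.integer(as.logical(labels))
  set.seed(cfg$rf_seed)
  base <- lapply(seq_along(band_x), function(b)
    train_band_rf(band_x[[b]], labels, cfg$n_trees, cfg$rf_seed + 1000 * b))
  names(base) <- names(band_x)
  z <- vapply(seq_along(band_x), function(b)
    oof_rf_probs(band_x[[b]], labels, cfg$n_trees, cfg$rf_seed + 1000 * b,
                 cfg$stack_nfolds),
    numeric(length(labels)))
  structure(list(base = base, train_probs = rowMeans(z),
                 threshold = NA_real_, cfg = cfg,
                 band_names = names(band_x)),
            class = "averaged_rf_model")
}

#' @export
predict.averaged_rf_model <- function(object, band_x, ...) {
  z <- vapply(seq_along(object$base), function(b)
    rf_prob(object$base[[b]], band_x[[b]]),
    numeric(nrow(as.matrix(band_x[[1]]))))
  if (is.vector(z)) z <- matrix(z, nrow = 1)
  rowMeans(z)
}

#' PPV-constrained decision threshold
#'
#' Over the candidate thresholds (the sorted unique predicted
#' probabilities plus a sentinel above the maximum), selects the threshold
#' maximizing the number of true positives subject to positive predictive
#' value >= `ppv_min`; ties break toward the lower threshold. If no
#' candidate satisfies the constraint, no unit is labelled positive
#' (`theta` just above the maximum probability) and the result is flagged.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels; at least one positive required.
#' @param ppv_min minimum PPV (default 0.95, prioritizing specificity to
#'   avoid false-positive SOZ labelling).
#' @return list with `theta`, `tp`, `ppv`, `feasible`.
#' @export
tune_threshold_ppv <- function(probs, labels, ppv_min = 0.95) {
  if (!length(probs)) stop("empty input")
  labels <- as.integer(as.logical(labels))
  if (!any(labels == 1)) {
    return(list(theta = max(probs) + 1e-9, tp = 0, ppv = NA_real_,
                feasible = FALSE))
  }
  cand <- sort(unique(probs))
  best <- NULL
  for (th in cand) {                 # ascending: first (lowest) wins ties
    pos <- probs >= th
    tp <- sum(pos & labels == 1)
    npos <- sum(pos)
    if (npos == 0) next
    ppv <- tp / npos
    if (ppv >= ppv_min && (is.null(best) || tp > best$tp))
      best <- list(theta = th, tp = tp, ppv = ppv, feasible = TRUE)
  }
  if (is.null(best))
    best <- list(theta = max(probs) + 1e-9, tp = 0, ppv = NA_real_,
                 feasible = FALSE)
  best
}

#' Accuracy-maximizing decision threshold
#'
#' Same candidate grid as [tune_threshold_ppv()] (sorted unique
#' probabilities plus a sentinel above the maximum, which corresponds to
#' labelling everything negative); selects the threshold maximizing
#' accuracy, ties toward the lower threshold.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels.
#' @return list with `theta`, `accuracy`.
#' @export
tune_threshold_accuracy <- function(probs, labels) {
  if (!length(probs)) stop("empty input")
  labels <- as.integer(as.logical(labels))
  cand <- c(sort(unique(probs)), max(probs) + 1e-9)
  best <- NULL
  for (th in cand) {
    acc <- mean((probs >= th) == labels)
    if (is.null(best) || acc > best$accuracy)
      best <- list(theta = th, accuracy = acc)
  }
  best
}

#' Majority vote across seizures
#'
#' Returns 1 iff at least 50% of the per-seizure binary calls are 1.
#'
#' @param votes vector of 0/1 calls (>= 1 element).
#' @return 0 or 1.
#' @export
majority_vote <- function(votes) {
  if (!length(votes)) stop("empty vote list")
  as.integer(mean(as.integer(votes)) >= 0.5)
}

#' Per-electrode ictal band-power features for the whole cohort
#'
#' Runs every recording through the preprocessing chain (notch at the
#' cohort's line frequency, common average reference, epoching) and the
#' sliding-window multitaper analysis, and assembles one feature row per
#' electrode x seizure: W ictal band-power values per band.
#'
#' @param cohort result of [generate_cohort()] (or a list with the same
#'   shape built from real recordings).
#' @param spec_cfg a [spectral_config()].
#' @param line_hz,n_harmonics notch settings; `n_harmonics = 0` skips.
#' @param keep_tensors if `TRUE`, also return the per-seizure ictal
#'   `band_power_tensor`s (for group statistics on the same spectra).
#' @return object of class `electrode_features`: `meta` data.frame
#'   (patient_id, seizure_id, electrode, label = clinician SOZ label,
#'   true_soz) and `band_x`, a named list of row-aligned feature matrices;
#'   plus `tensors` when requested.
#' @export
electrode_features <- function(cohort, spec_cfg = spectral_config(),
                               line_hz = 60, n_harmonics = 3,
                               keep_tensors = FALSE) {
  meta <- list()
  mats <- NULL
  tensors <- list()
  true_map <- cohort$channels
  for (rec in cohort$recordings) {
    ep <- preprocess_recording(rec, line_hz = line_hz,
                               n_harmonics = n_harmonics)
    bp <- epoch_band_power(ep$ictal, ep$fs, spec_cfg)
    if (keep_tensors)
      tensors[[paste(rec$patient_id, rec$seizure_id, sep = "_")]] <-
        list(bp = bp, soz = rec$soz_label, patient_id = rec$patient_id,
             seizure_id = rec$seizure_id)
    tr <- true_map$true_soz[match(
      paste(rec$patient_id, rec$channel_labels),
      paste(true_map$patient_id, true_map$name))]
    meta[[length(meta) + 1L]] <- data.frame(
      patient_id = rec$patient_id, seizure_id = rec$seizure_id,
      electrode = rec$channel_labels,
      label = as.integer(rec$soz_label),
      true_soz = if (all(is.na(tr))) as.integer(rec$soz_label) else tr)
    bymat <- lapply(seq_along(bp$band_names), function(b)
      bp$values[, b, , drop = TRUE])
    if (is.null(mats)) mats <- bymat
    else mats <- lapply(seq_along(mats), function(b)
      rbind(mats[[b]], bymat[[b]]))
  }
  names(mats) <- names(spec_cfg$bands)
  structure(list(meta = do.call(rbind, meta), band_x = mats,
                 tensors = if (keep_tensors) tensors),
            class = "electrode_features")
}

#' Leave-one-patient-out cross-validation
#'
#' One fold per patient: the held-out patient's rows (all seizures, all
#' electrodes) are absent from base-model training, meta-training and
#' threshold tuning of that fold. The threshold is tuned on the training
#' fold's out-of-fold ensemble probabilities; held-out probabilities are
#' thresholded and then majority-voted per patient x electrode across
#' seizures.
#'
#' @param feat an [electrode_features()] object (or any object with
#'   `meta` containing `patient_id`, `seizure_id`, a unit column and
#'   `label`, plus row-aligned `band_x`).
#' @param model `"srfe"`, `"averaged"` or `"simple"`.
#' @param cfg an [srfe_config()].
#' @param threshold_mode `"ppv"` (maximize TP subject to PPV >= `ppv_min`)
#'   or `"accuracy"`.
#' @param ppv_min PPV floor for `threshold_mode = "ppv"`.
#' @param unit_col column of `feat$meta` identifying the prediction unit
#'   (default `"electrode"`; votes are per patient x unit across seizures).
#' @return object of class `lopo_result`: `predictions` (one row per
#'   unit x seizure: prob, pred, label, fold), `votes` (per patient x
#'   unit majority-voted call), `thresholds`, `fold_models`, `audit`
#'   (per-fold train/test patient-id sets), `flagged_folds`.
#' @export
lopo_cv <- function(feat, model = c("srfe", "averaged", "simple"),
                    cfg = srfe_config(),
                    threshold_mode = c("ppv", "accuracy"), ppv_min = 0.95,
                    unit_col = "electrode") {
  model <- match.arg(model)
  threshold_mode <- match.arg(threshold_mode)
  meta <- feat$meta
  patients <- unique(meta$patient_id)
  if (length(patients) < 2) stop("leave-one-patient-out needs >= 2 patients")
  if (any(!table(meta$patient_id) > 0)) stop("patient with zero rows")
  preds <- list()
  audit <- list()
  thresholds <- list()
  fold_models <- list()
  flagged <- character(0)
  for (p in patients) {
    tr <- meta$patient_id != p
    stopifnot(length(intersect(meta$patient_id[tr], p)) == 0)  # leakage audit
    tr_band_x <- lapply(feat$band_x, function(m)
      as.matrix(m)[tr, , drop = FALSE])
    te_band_x <- lapply(feat$band_x, function(m)
      as.matrix(m)[!tr, , drop = FALSE])
    y_tr <- meta$label[tr]
    if (length(unique(y_tr)) < 2) {
      flagged <- c(flagged, p)
      const <- as.integer(round(mean(y_tr)))
      preds[[p]] <- data.frame(meta[!tr, , drop = FALSE],
                               prob = as.numeric(const), pred = const,
                               fold = p, row.names = NULL)
      audit[[p]] <- list(fold = p, train = unique(meta$patient_id[tr]),
                         test = p)
      next
    }
    fit <- switch(model,
                  srfe = train_srfe(tr_band_x, y_tr, cfg),
                  averaged = averaged_rf_baseline(tr_band_x, y_tr, cfg),
                  simple = simple_rf_baseline(tr_band_x, y_tr, cfg))
    tune <- if (threshold_mode == "ppv")
      tune_threshold_ppv(fit$train_probs, y_tr, ppv_min)
    else tune_threshold_accuracy(fit$train_probs, y_tr)
    fit$threshold <- tune$theta
    pr <- stats::predict(fit, te_band_x)
    preds[[p]] <- data.frame(meta[!tr, , drop = FALSE], prob = pr,
                             pred = as.integer(pr >= tune$theta), fold = p,
                             row.names = NULL)
    thresholds[[p]] <- tune
    fold_models[[p]] <- fit
    audit[[p]] <- list(fold = p, train = unique(meta$patient_id[tr]),
                       test = p)
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  key <- interaction(predictions$patient_id, predictions[[unit_col]],
                     drop = TRUE)
  votes <- do.call(rbind, lapply(split(predictions, key), function(d)
    data.frame(patient_id = d$patient_id[1], unit = d[[unit_col]][1],
               label = d$label[1],
               true_soz = if ("true_soz" %in% names(d)) d$true_soz[1] else NA,
               n_seizures = nrow(d), vote = majority_vote(d$pred))))
  rownames(votes) <- NULL
  structure(list(predictions = predictions, votes = votes,
                 thresholds = thresholds, fold_models = fold_models,
                 audit = audit, flagged_folds = flagged,
                 model = model, threshold_mode = threshold_mode),
            class = "lopo_result")
}

#' Per-seizure decile-ratio features for outcome prediction
#'
#' For every seizure recording, computes the ictal band-power tensor,
#' the SOZ/non-SOZ decile table and the normalized decile-ratio features
#' (10 deciles x W windows per band), labelled with the patient's
#' seizure-freedom outcome.
#'
#' @param cohort result of [generate_cohort()].
#' @param spec_cfg a [spectral_config()].
#' @param line_hz,n_harmonics notch settings.
#' @return list shaped like [electrode_features()] but with one row per
#'   seizure: `meta` (patient_id, seizure_id, electrode = seizure_id,
#'   label = outcome) and per-band 10 x W ratio feature matrices.
#' @export
build_outcome_features <- function(cohort, spec_cfg = spectral_config(),
                                   line_hz = 60, n_harmonics = 3) {
  out_map <- cohort$patients
  meta <- list()
  mats <- NULL
  for (rec in cohort$recordings) {
    ep <- preprocess_recording(rec, line_hz = line_hz,
                               n_harmonics = n_harmonics)
    bp <- epoch_band_power(ep$ictal, ep$fs, spec_cfg)
    drf <- decile_ratio_features(decile_table(bp, ep$soz_label))
    meta[[length(meta) + 1L]] <- data.frame(
      patient_id = rec$patient_id, seizure_id = rec$seizure_id,
      electrode = rec$seizure_id,
      label = out_map$outcome[match(rec$patient_id, out_map$patient_id)])
    row_by_band <- lapply(drf$per_band, function(m) as.vector(m))
    if (is.null(mats)) mats <- lapply(row_by_band, function(v)
      matrix(v, nrow = 1))
    else mats <- lapply(seq_along(mats), function(b)
      rbind(mats[[b]], row_by_band[[b]]))
  }
  names(mats) <- names(spec_cfg$bands)
  structure(list(meta = do.call(rbind, meta), band_x = mats),
            class = "electrode_features")
}
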