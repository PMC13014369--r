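test_that("per-band forests separate a separable toy and are chance on shuffled labels", {
  set.seed(11)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * 8), n, 8) + 10 * y   # SOZ rows 10x power
  m <- train_band_rf(x, y, n_trees = 100, seed = 1)
  expect_equal(roc_auc(rf_prob_for_test(m, x), y), 1.0)

  y_shuf <- sample(y)
  m2 <- train_band_rf(x, y_shuf, n_trees = 100, seed = 1)
  oob <- m2$predictions[, "1"]               # out-of-bag probabilities
  auc <- roc_auc(oob, y_shuf)
  expect_gt(auc, 0.3); expect_lt(auc, 0.7)

  m3 <- train_band_rf(x, y, n_trees = 100, seed = 1)
  expect_identical(rf_prob_for_test(m, x), rf_prob_for_test(m3, x))
  expect_error(train_band_rf(x, rep(1, n)), "single class")
})

test_that("the SRFE meta-learner weights an informative band highest and spreads ridge weight over clones", {
  feat <- make_separable_features(n_patients = 6, n_units = 10, n_pos = 3,
                                  shift = 8, informative_band = "beta")
  fit <- train_srfe(feat$band_x, feat$meta$label,
                    srfe_config(rf_seed = 2))
  co <- fit$coefficients[-1]
  expect_equal(names(which.max(abs(co))), "beta")
  p <- predict(fit, feat$band_x)
  expect_true(all(p >= 0 & p <= 1))

  # six identical base inputs: ridge spreads weight nearly equally
  set.seed(12)
  xb <- matrix(rnorm(120 * 8), 120, 8) +
    6 * rep(c(0, 1), each = 60)
  clones <- setNames(rep(list(xb), 6), names(canonical_bands()))
  fit2 <- train_srfe(clones, rep(c(0, 1), each = 60),
                     srfe_config(rf_seed = 3))
  co2 <- fit2$coefficients[-1]
  expect_lt(max(co2) / min(co2), 1.5)
})

test_that("PPV-constrained threshold tuning maximizes TP subject to the constraint", {
  got <- tune_threshold_ppv(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 1), 0.95)
  expect_equal(got$theta, 0.8)
  expect_equal(got$tp, 2)
  expect_true(got$feasible)

  allpos <- tune_threshold_ppv(c(0.3, 0.6, 0.5), c(1, 1, 1), 0.95)
  expect_equal(allpos$theta, 0.3)
  expect_equal(allpos$tp, 3)

  allneg <- tune_threshold_ppv(c(0.3, 0.6), c(0, 0), 0.95)
  expect_false(allneg$feasible)
  expect_equal(allneg$tp, 0)
  expect_true(all(c(0.3, 0.6) < allneg$theta))
  expect_error(tune_threshold_ppv(numeric(0), numeric(0)), "empty")
})

test_that("threshold tuning agrees with exhaustive enumeration on random instances", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    probs <- round(runif(n), 2)          # induce ties
    labels <- rbinom(n, 1, 0.4)
    if (!any(labels == 1)) labels[1] <- 1
    got <- tune_threshold_ppv(probs, labels, 0.8)
    ref <- oracle_best_ppv_threshold(probs, labels, 0.8)
    expect_equal(got$tp, ref$tp)
    expect_equal(got$feasible, ref$feasible)
    if (ref$feasible) expect_equal(got$theta, ref$theta)

    got_a <- tune_threshold_accuracy(probs, labels)
    expect_equal(got_a$accuracy, oracle_best_accuracy(probs, labels))
  }
  acc <- tune_threshold_accuracy(c(0.9, 0.2), c(1, 0))
  expect_equal(acc$theta, 0.9)
  expect_equal(acc$accuracy, 1)
  expect_equal(tune_threshold_accuracy(c(0.4, 0.7), c(1, 1))$theta, 0.4)
})

test_that("majority voting across seizures uses the >= 50% rule", {
  expect_equal(majority_vote(c(1, 1, 0, 0)), 1)   # exactly 50% is positive
  expect_equal(majority_vote(c(1, 0, 0)), 0)
  expect_equal(majority_vote(0), 0)
  expect_equal(majority_vote(1), 1)
  expect_error(majority_vote(integer(0)), "empty")
})

test_that("LOPO-CV is leak-free, one fold per patient, with majority-voted calls", {
  feat <- make_separable_features(n_patients = 5, n_seizures = 3,
                                  n_units = 8, n_pos = 2, shift = 8)
  res <- lopo_cv(feat, model = "srfe",
                 cfg = srfe_config(n_trees = 50, rf_seed = 4),
                 threshold_mode = "ppv")
  expect_length(res$audit, 5)
  for (a in res$audit) {
    expect_length(intersect(a$train, a$test), 0)
    expect_setequal(c(a$train, a$test), unique(feat$meta$patient_id))
  }
  expect_setequal(unique(res$predictions$fold),
                  unique(feat$meta$patient_id))
  # every unit x seizure predicted exactly once
  expect_equal(nrow(res$predictions), nrow(feat$meta))
  expect_equal(nrow(res$votes), 5 * 8)
  expect_true(all(res$votes$n_seizures == 3))
  expect_true(all(res$predictions$prob >= 0 & res$predictions$prob <= 1))
  expect_true(all(res$predictions$pred %in% 0:1))
  # strong separation: voted calls recover the positive units
  cm <- confusion_from_predictions(res$votes$vote, res$votes$label)
  expect_gte(cm$ppv, 0.9)
  expect_error(lopo_cv(list(meta = data.frame(patient_id = "P1"),
                            band_x = list()),
                       model = "srfe"), ">= 2 patients")
})

test_that("a single-class training fold is flagged, not fatal", {
  feat <- make_separable_features(n_patients = 3, n_seizures = 1,
                                  n_units = 6, n_pos = 2, shift = 8)
  # make all positives belong to patient P03: other folds keep both classes,
  # the fold holding out P03 trains on single-class labels
  feat$meta$label <- ifelse(feat$meta$patient_id == "P03" &
                              feat$meta$electrode %in% c("e01", "e02"), 1, 0)
  res <- lopo_cv(feat, model = "srfe",
                 cfg = srfe_config(n_trees = 20, rf_seed = 5))
  expect_identical(res$flagged_folds, "P03")
  expect_true(all(!is.na(res$predictions$pred)))
})

test_that("the averaged baseline is the unweighted mean of per-band forests", {
  feat <- make_separable_features(n_patients = 4, n_units = 8, n_pos = 2,
                                  shift = 6, seed = 14)
  cfg <- srfe_config(n_trees = 30, rf_seed = 6)
  fit <- averaged_rf_baseline(feat$band_x, feat$meta$label, cfg)
  p <- predict(fit, feat$band_x)
  # oracle: retrain the same per-band forests with the same seeds and average
  ref <- rowMeans(vapply(seq_along(feat$band_x), function(b) {
    m <- train_band_rf(feat$band_x[[b]], feat$meta$label, 30,
                       cfg$rf_seed + 1000 * b)
    rf_prob_for_test(m, feat$band_x[[b]])
  }, numeric(nrow(feat$meta))))
  expect_equal(p, ref, tolerance = 1e-12)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("the simple-RF baseline separates the separable toy under LOPO", {
  feat <- make_separable_features(n_patients = 4, n_seizures = 2,
                                  n_units = 8, n_pos = 2, shift = 8)
  res <- lopo_cv(feat, model = "simple",
                 cfg = srfe_config(n_trees = 50, rf_seed = 7),
                 threshold_mode = "ppv")
  expect_gte(roc_auc(res$predictions$prob, res$predictions$label), 0.95)
})

test_that("SRFE-outcome with LOPO and voting is exact on a constructed separable cohort", {
  # seizure-free patients: SOZ/non-SOZ gamma ratio ~5; not free: ~1
  set.seed(15)
  n_pat <- 6; n_sz <- 2; w <- 8
  outcome <- rep(c(1, 0), each = n_pat / 2)
  meta <- expand.grid(seizure_id = sprintf("S%02d", 1:n_sz),
                      patient_id = sprintf("P%02d", 1:n_pat),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- data.frame(patient_id = meta$patient_id,
                     seizure_id = meta$seizure_id,
                     electrode = meta$seizure_id,
                     label = rep(outcome, each = n_sz))
  # class-identical rows: every seizure-free seizure has SOZ/non-SOZ gamma
  # ratio 5, every not-free seizure ratio 1, so the classes are exactly
  # separable and LOPO predictions cannot straddle the tuned threshold
  band_x <- lapply(names(canonical_bands()), function(b) {
    base <- if (b == "gamma") ifelse(meta$label == 1, 5, 1) else 1
    matrix(base, nrow(meta), 10 * w)
  })
  names(band_x) <- names(canonical_bands())
  feat <- structure(list(meta = meta, band_x = band_x),
                    class = "electrode_features")
  res <- lopo_cv(feat, model = "srfe",
                 cfg = srfe_config(meta_alpha = 0.5, meta_lambda = 0.1,
                                   rf_seed = 8),
                 threshold_mode = "accuracy")
  per_patient <- res$votes[!duplicated(res$votes$patient_id), ]
  votes <- vapply(split(res$votes$vote, res$votes$patient_id),
                  majority_vote, integer(1))
  truth <- outcome[match(names(votes), sprintf("P%02d", 1:n_pat))]
  expect_equal(mean(votes == truth), 1.0)

  # identical features for everyone -> constant predictions
  band_c <- lapply(band_x, function(m) matrix(1, nrow(meta), ncol(m)))
  featc <- structure(list(meta = meta, band_x = band_c),
                     class = "electrode_features")
  resc <- lopo_cv(featc, model = "srfe",
                  cfg = srfe_config(meta_alpha = 0.5, meta_lambda = 0.1,
                                    rf_seed = 8),
                  threshold_mode = "accuracy")
  expect_lte(length(unique(resc$votes$vote)), 2)
})
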