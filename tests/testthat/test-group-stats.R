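test_that("group mean/SEM matches a direct oracle and handles tiny groups", {
  set.seed(2)
  vals <- array(rexp(6 * 6 * 5), dim = c(6, 6, 5))
  bp <- make_bp(vals, centers = 1:5)
  soz <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  gs <- group_mean_sem(bp, soz)
  for (b in seq_len(6)) for (w in seq_len(5)) {
    ref_m <- mean(vals[1:3, b, w])
    ref_se <- sd(vals[1:3, b, w]) / sqrt(3)
    row <- gs[gs$band == bp$band_names[b] & gs$group == "SOZ" &
                gs$window_center_s == w, ]
    expect_equal(row$mean, ref_m, tolerance = 1e-12)
    expect_equal(row$sem, ref_se, tolerance = 1e-12)
  }
  # n = 1 per group: mean is the series itself, SEM defined as 0
  bp1 <- make_bp(vals[1:2, , , drop = FALSE], centers = 1:5)
  gs1 <- group_mean_sem(bp1, c(TRUE, FALSE))
  expect_true(all(gs1$sem == 0))
  expect_equal(gs1$mean[gs1$group == "SOZ" & gs1$band == "delta"],
               vals[1, 1, ])
  # two identical electrodes: SEM 0
  bp2 <- make_bp(vals[c(1, 1, 2, 2), , , drop = FALSE], centers = 1:5)
  gs2 <- group_mean_sem(bp2, c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(gs2$sem == 0))
  expect_error(group_mean_sem(bp, rep(TRUE, 6)), "non-empty")
})

test_that("AUC over time is the trapezoidal integral and is linear", {
  centers <- c(0, 0.5, 1.5, 2, 4)
  expect_equal(auc_over_time(rep(3, 5), centers), 3 * 4)
  ramp <- seq(0, 1, length.out = 5)
  expect_equal(auc_over_time(ramp, seq(0, 2, length.out = 5)), 1)
  set.seed(3)
  y <- rnorm(7); x <- sort(runif(7)); z <- rnorm(7)
  expect_equal(auc_over_time(y, x), oracle_trapz(y, x))
  expect_equal(auc_over_time(2 * y + 3 * z, x),
               2 * auc_over_time(y, x) + 3 * auc_over_time(z, x))
  expect_error(auc_over_time(1, 1), "two points")
  expect_error(auc_over_time(1:3, c(1, 1, 2)), "increasing")
})

test_that("group AUC comparisons use Welch tests with a 24-fold Bonferroni family", {
  set.seed(5)
  mkrec <- function(outcome, group, band, auc, id)
    data.frame(patient_id = id, seizure_id = id, outcome = outcome,
               group = group, band = band, auc = auc)
  recs <- do.call(rbind, lapply(1:6, function(i) rbind(
    mkrec("seizure_free", "SOZ", "gamma", 10 + rnorm(1), i),
    mkrec("seizure_free", "nonSOZ", "gamma", 10 + rnorm(1), i))))
  cmp <- compare_auc_groups(recs)
  sf <- cmp[cmp$pair == "SF_SOZ_vs_SF_nonSOZ", ]
  expect_false(sf$degenerate)
  expect_equal(sf$p_adj, min(1, 24 * sf$p_raw))
  # identical groups -> t = 0, p_raw = 1
  recs2 <- recs
  recs2$auc <- rep(5, nrow(recs2))
  recs2$auc <- recs2$auc + rep(c(0.1, -0.1, 0.2, -0.2, 0.3, -0.3), each = 2)
  cmp2 <- compare_auc_groups(recs2)
  sf2 <- cmp2[cmp2$pair == "SF_SOZ_vs_SF_nonSOZ", ]
  expect_equal(sf2$t, 0, tolerance = 1e-12)
  expect_equal(sf2$p_raw, 1)
  # cells with no not-seizure-free records are flagged, not dropped
  expect_true(all(cmp$degenerate[cmp$pair == "NSF_SOZ_vs_NSF_nonSOZ"]))
  expect_equal(sum(!is.na(cmp$p_adj)) + sum(cmp$degenerate), nrow(cmp))
})

test_that("Welch test from summary statistics reproduces known p-values", {
  # SOZ channel counts: seizure-free 14.5 +/- 10.8 (n=14) vs 11.0 +/- 4.7 (n=7)
  w <- welch_from_summary(14.5, 10.8, 14, 11.0, 4.7, 7)
  expect_equal(w$p, 0.316, tolerance = 0.005)
  expect_false(w$degenerate)

  eq <- welch_from_summary(1, 1, 10, 1, 1, 10)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)

  big <- welch_from_summary(11, 1, 10, 1, 1, 10)  # 10 sd shift
  expect_lt(big$p, 1e-6)

  # agreement with stats::t.test on raw data having these exact summaries
  set.seed(6)
  x <- rnorm(14); x <- (x - mean(x)) / sd(x) * 10.8 + 14.5
  y <- rnorm(7);  y <- (y - mean(y)) / sd(y) * 4.7 + 11.0
  tt <- t.test(x, y)
  w2 <- welch_from_summary(14.5, 10.8, 14, 11.0, 4.7, 7)
  expect_equal(w2$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(w2$p, tt$p.value, tolerance = 1e-10)

  d0 <- welch_from_summary(2, 0, 5, 2, 0, 5)
  expect_equal(d0$p, 1)
  expect_equal(welch_from_summary(2, 0, 5, 3, 0, 5)$p, 0)
  expect_error(welch_from_summary(1, 1, 1, 2, 1, 5), "n >= 2")
})

test_that("decile tables follow the linear-interpolation convention and are monotone", {
  vals <- array(0, dim = c(20, 6, 3))
  for (w in 1:3) vals[, , w] <- matrix(rep(c(1:10, rep(7, 10)), 6), 20, 6)
  bp <- make_bp(vals, centers = 1:3)
  dt <- decile_table(bp, c(rep(TRUE, 10), rep(FALSE, 10)))
  expect_equal(unname(dt$deciles["SOZ", "delta", , 1]),
               unname(quantile(1:10, seq(0.1, 1, 0.1), type = 7)))
  expect_equal(dt$deciles["SOZ", "delta", "d100", 2], 10)  # max
  expect_true(all(dt$deciles["nonSOZ", , , ] == 7))        # identical -> equal
  set.seed(9)
  bp2 <- make_bp(array(rlnorm(12 * 6 * 4), dim = c(12, 6, 4)), centers = 1:4)
  dt2 <- decile_table(bp2, rep(c(TRUE, FALSE), 6))
  expect_true(all(apply(dt2$deciles, c(1, 2, 4), function(v)
    all(diff(v) >= 0))))
})

test_that("decile-ratio features are min-max normalized to [1,10] with bounded ratios", {
  # identical SOZ and nonSOZ profiles -> all ratios 1
  dec <- array(rep(seq(2, 20, by = 2), each = 2), dim = c(2, 1, 10, 1),
               dimnames = list(c("SOZ", "nonSOZ"), "delta",
                               paste0("d", seq(10, 100, 10)), NULL))
  dec <- aperm(dec, c(1, 2, 3, 4))
  dt <- structure(list(deciles = dec, band_names = "delta",
                       window_centers_s = 1),
                  class = "decile_table")
  drf <- decile_ratio_features(dt)
  expect_equal(unname(drf$per_band$delta[, 1]), rep(1, 10))

  # hand-computed toy: SOZ deciles 0..9, nonSOZ deciles all 4
  dec2 <- dec
  dec2["SOZ", 1, , 1] <- 0:9
  dec2["nonSOZ", 1, , 1] <- rep(4, 10)
  dt2 <- structure(list(deciles = dec2, band_names = "delta",
                        window_centers_s = 1),
                   class = "decile_table")
  drf2 <- decile_ratio_features(dt2)
  expect_equal(unname(drf2$per_band$delta[, 1]), 1 + 9 * (0:9) / 9)
  expect_equal(unname(drf2$per_band$delta[1, 1]), 1)    # endpoints exact
  expect_equal(unname(drf2$per_band$delta[10, 1]), 10)

  set.seed(10)
  bp <- make_bp(array(rlnorm(8 * 6 * 5), dim = c(8, 6, 5)), centers = 1:5)
  drf3 <- decile_ratio_features(decile_table(bp, rep(c(TRUE, FALSE), 4)))
  expect_true(all(drf3$features >= 0.1 - 1e-12 & drf3$features <= 10 + 1e-12))
})
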