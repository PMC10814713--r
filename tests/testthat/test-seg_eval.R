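test_that("confusion counts partition the pixel grid", {
  gt <- matrix(c(1L, 1L, 0L, 0L), 2, 2, byrow = TRUE)
  pred <- matrix(c(1L, 0L, 1L, 0L), 2, 2, byrow = TRUE)
  cc <- confusion_counts(gt, pred)
  expect_identical(unlist(cc)[c("TP", "FP", "FN", "TN")],
                   c(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  set.seed(3)
  m <- random_mask(8, 8)
  same <- confusion_counts(m, m)
  expect_identical(same$TP, sum(m))
  expect_identical(same$TN, 64L - sum(m))
  expect_identical(same$FP + same$FN, 0L)
  flip <- confusion_counts(m, 1L - m)
  expect_identical(flip$TP + flip$TN, 0L)
  expect_error(confusion_counts(m, random_mask(4, 4)), "dimension")
})

test_that("the indicator suite matches the hand-computed mixed case to 4 d.p.", {
  rep <- metric_report(list(TP = 8, FP = 2, FN = 2, TN = 88))
  expect_equal(rep$sensitivity, 0.8000, tolerance = 1e-4)
  expect_equal(rep$specificity, 0.9778, tolerance = 1e-4)
  expect_equal(rep$accuracy, 0.9600, tolerance = 1e-4)
  expect_equal(rep$precision, 0.8000, tolerance = 1e-4)
  expect_equal(rep$f_measure, 0.8000, tolerance = 1e-4)
  expect_equal(rep$dice, 0.8000, tolerance = 1e-4)
  expect_equal(rep$jaccard, 0.6667, tolerance = 1e-4)
  expect_equal(rep$mcc, 700 / 900, tolerance = 1e-4)
  expect_equal(rep$auc, 0.8889, tolerance = 1e-4)
})

test_that("perfect, complementary and single-class predictions behave", {
  perfect <- metric_report(list(TP = 5, FP = 0, FN = 0, TN = 20))
  expect_true(all(unlist(perfect) == 1))
  # complement prediction with both classes present: accuracy 0, MCC -1
  comp <- metric_report(list(TP = 0, FP = 10, FN = 15, TN = 0))
  expect_identical(comp$accuracy, 0)
  expect_identical(comp$mcc, -1)
  # no positives anywhere: positive-class metrics are undefined markers
  none <- metric_report(list(TP = 0, FP = 0, FN = 0, TN = 9))
  expect_true(is.na(none$sensitivity) && is.na(none$precision) &&
              is.na(none$f_measure) && is.na(none$dice) &&
              is.na(none$jaccard) && is.na(none$mcc))
  expect_identical(none$specificity, 1)
  expect_error(metric_report(list(TP = 0, FP = 0, FN = 0, TN = 0)), "zero")
})

test_that("algebraic identities hold on random confusion tables", {
  set.seed(14)
  for (rep in 1:200) {
    counts <- as.list(sample(0:50, 4, replace = TRUE))
    names(counts) <- c("TP", "TN", "FP", "FN")
    if (Reduce(`+`, counts) == 0) next
    r <- metric_report(counts)
    if (!is.na(r$dice) && !is.na(r$jaccard)) {
      expect_equal(r$dice, 2 * r$jaccard / (1 + r$jaccard), tolerance = 1e-12)
    }
    if (!is.na(r$f_measure)) {
      expect_equal(r$f_measure, r$dice, tolerance = 1e-12)
    }
    # label-swap symmetry: transposing FP and FN swaps Se and precision
    # and leaves the symmetric metrics unchanged
    sw <- metric_report(list(TP = counts$TP, TN = counts$TN,
                             FP = counts$FN, FN = counts$FP))
    expect_equal(sw$accuracy, r$accuracy, tolerance = 1e-12)
    expect_equal(sw$dice, r$dice, tolerance = 1e-12)
    expect_equal(sw$jaccard, r$jaccard, tolerance = 1e-12)
    expect_equal(sw$mcc, r$mcc, tolerance = 1e-12)
    expect_equal(sw$sensitivity, r$precision, tolerance = 1e-12)
    # all defined values bounded
    v <- unlist(r)
    expect_true(all(v[!is.na(v)] >= -1 & v[!is.na(v)] <= 1))
    expect_true(all(v[setdiff(names(v), "mcc")] >= 0, na.rm = TRUE))
  }
})

test_that("evaluate_pair composes counts and report end to end", {
  set.seed(8)
  m <- random_mask(8, 8, 0.5)
  if (sum(m) == 0 || sum(m) == 64) m[1, 1] <- 1L - m[1, 1]
  r <- evaluate_pair(m, m)
  expect_true(all(unlist(r) == 1))
})

test_that("threshold-sweep AUC agrees with the Mann-Whitney oracle", {
  set.seed(19)
  for (rep in 1:10) {
    X <- matrix(sample(0:20, 9, replace = TRUE), 3, 3)
    gt <- random_mask(3, 3, 0.5)
    if (sum(gt) %in% c(0L, 9L)) gt[1, 1] <- 1L - gt[1, 1]
    n1 <- sum(gt); n0 <- 9 - n1
    got <- auc_sweep(X, gt, invert = TRUE)
    # invert = TRUE scores low intensities as foreground
    want <- naive_auc(-X[gt == 1L], -X[gt == 0L])
    expect_equal(got, want, tolerance = 1 / (2 * n1 * n0))
  }
  # perfect separation and chance-level scorers
  Xs <- matrix(c(10L, 10L, 200L, 200L), 2, 2)
  gts <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  expect_equal(auc_sweep(Xs, gts, invert = TRUE), 1.0)
  expect_equal(auc_sweep(matrix(100L, 2, 2), gts, invert = TRUE), 0.5)
  expect_error(auc_sweep(Xs, matrix(1L, 2, 2)), "single class")
})

test_that("batch summaries use sample SD and exclude undefined entries", {
  r1 <- metric_report(list(TP = 7, FP = 3, FN = 3, TN = 87))   # dice 0.7
  r2 <- metric_report(list(TP = 9, FP = 1, FN = 1, TN = 89))   # dice 0.9
  s <- summarize_batch(list(r1, r2))
  expect_equal(s$mean[s$metric == "dice"], 0.8)
  expect_equal(s$sd[s$metric == "dice"], sd(c(0.7, 0.9)), tolerance = 1e-12)
  # single report: means equal the report, SDs zero
  s1 <- summarize_batch(list(r1))
  expect_equal(s1$mean[s1$metric == "dice"], r1$dice)
  expect_true(all(s1$sd == 0))
  # a report with undefined MCC is excluded for that metric only
  r3 <- metric_report(list(TP = 0, FP = 0, FN = 0, TN = 10))
  s3 <- summarize_batch(list(r1, r2, r3))
  expect_identical(s3$n_excluded[s3$metric == "mcc"], 1L)
  expect_identical(s3$n_used[s3$metric == "accuracy"], 3L)
  expect_equal(s3$mean[s3$metric == "mcc"], mean(c(r1$mcc, r2$mcc)))
  expect_error(summarize_batch(list()), "at least one")
})
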