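test_that("confusion counting partitions predictions and validated pairs", {
  val <- pair_df(c("m1", "m2"), c("t1", "t2"))
  pred <- pred_df(c("m1", "m3"), c("t1", "t3"), c(1, 2))
  cc <- confusion_from_predictions(pred, val)
  expect_equal(cc$tp, 1L); expect_equal(cc$fp, 1L); expect_equal(cc$fn, 1L)
  # perfect prediction
  cc2 <- confusion_from_predictions(pred_df(val$mirna_id, val$target_id, 1:2), val)
  expect_equal(cc2$fp, 0L); expect_equal(cc2$fn, 0L)
  # negatives give true negatives; overlap with validated is an error
  neg <- pair_df(paste0("n", 1:5), paste0("d", 1:5))
  cc3 <- confusion_from_predictions(pred, val, neg)
  expect_equal(cc3$tn, 5L)
  expect_error(confusion_from_predictions(pred, val, val), "overlap")
})

test_that("precision and recall are the closed-form ratios", {
  expect_equal(precision_recall(list(tp = 8, fp = 2, fn = 2)),
               c(precision = 0.8, recall = 0.8))
  expect_equal(precision_recall(list(tp = 0, fp = 0, fn = 5)),
               c(precision = 1.0, recall = 0.0))
  expect_equal(precision_recall(list(tp = 10, fp = 0, fn = 0)),
               c(precision = 1.0, recall = 1.0))
  expect_equal(specificity_sensitivity(list(tp = 3, fp = 1, fn = 1, tn = 9)),
               c(specificity = 0.9, sensitivity = 0.75))
})

test_that("threshold sweep walks the native score grid", {
  pred <- pred_df(c("m1", "m2", "m3"), c("t1", "t2", "t3"), c(1, 2, 3))
  val <- pair_df(c("m1", "m2"), c("t1", "t2"))
  curve <- threshold_sweep(pred, val)
  expect_equal(curve$threshold, c(1, 2, 3))
  at2 <- curve[curve$threshold == 2, ]
  expect_equal(at2$precision, 1.0)
  expect_equal(at2$recall, 1.0)
  at3 <- curve[curve$threshold == 3, ]
  expect_equal(at3$precision, 2 / 3)
  expect_equal(at3$recall, 1.0)
  # tp + fn conserved at every threshold
  expect_true(all(curve$tp + curve$fn == 2))
  # single validated prediction: one point, P = R = 1
  c1 <- threshold_sweep(pred_df("m1", "t1", 5), pair_df("m1", "t1"))
  expect_equal(nrow(c1), 1L)
  expect_equal(c1$precision, 1); expect_equal(c1$recall, 1)
  # all-false predictions: precision 0 everywhere
  c0 <- threshold_sweep(pred, pair_df("zz", "zz"))
  expect_true(all(c0$precision == 0))
  expect_error(threshold_sweep(pred[0, ], val), "no predictions")
})

test_that("recall is monotone along every sweep", {
  set.seed(91)
  for (k in 1:10) {
    n <- 30
    pred <- pred_df(paste0("m", 1:n), paste0("t", 1:n), round(runif(n), 2))
    val <- pair_df(paste0("m", sample(n, 12)), paste0("t", 1:n)[sample(n, 12)])
    val <- pair_df(paste0("m", 1:12), paste0("t", 1:12))
    curve <- threshold_sweep(pred, val)
    expect_true(all(diff(curve$recall) >= 0))
    expect_true(all(curve$tp + curve$fn == nrow(val)))
  }
})

test_that("optimal score sits at the precision-recall crossing", {
  curve <- data.frame(threshold = c(2, 4, 6),
                      precision = c(1.0, 0.9, 0.6),
                      recall = c(0.5, 0.9, 1.0))
  expect_equal(optimal_score(curve), 4)
  # P = R everywhere: the smallest threshold wins the tie
  flat <- data.frame(threshold = 1:5, precision = 0.8, recall = 0.8)
  expect_equal(optimal_score(flat), 1)
  # curves that never cross: minimal gap
  apart <- data.frame(threshold = 1:4, precision = c(.9, .8, .7, .6),
                      recall = c(.1, .3, .35, .5))
  expect_equal(optimal_score(apart), 4)
})

test_that("ROC/AUC equals the concordance oracle and handles ties", {
  # positives strictly better (lower) than negatives
  r <- roc_auc(c(1, 2), c(5, 6), "lower_better")
  expect_equal(r$auc, 1.0)
  # identical score multisets
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3), "lower_better")$auc, 0.5)
  set.seed(101)
  for (k in 1:10) {
    pos <- sample(1:20, 15, replace = TRUE)
    neg <- sample(5:25, 18, replace = TRUE)
    r <- roc_auc(pos, neg, "lower_better")
    expect_equal(r$auc, oracle_auc_lower_better(pos, neg), tolerance = 1e-12)
    rh <- roc_auc(-pos, -neg, "higher_better")
    expect_equal(rh$auc, r$auc, tolerance = 1e-12)
  }
  expect_error(roc_auc(numeric(0), 1:3), "non-empty")
})

test_that("ROC/AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(111)
  pos <- rnorm(40, 2); neg <- rnorm(50, 4)
  mine <- roc_auc(pos, neg, "lower_better")$auc
  ref <- suppressMessages(pROC::auc(
    response = c(rep(1, 40), rep(0, 50)),
    predictor = c(pos, neg), direction = ">"))
  expect_equal(mine, as.numeric(ref), tolerance = 1e-12)
})

test_that("union and intersection perform orientation-aware set algebra", {
  a <- pred_df(c("m1", "m2"), c("t1", "t2"), c(1, 3), tool = "A")
  b <- pred_df(c("m2", "m3"), c("t2", "t3"), c(2, 4), tool = "B")
  u <- combine_predictions(a, b, "union")
  expect_setequal(u$mirna_id, c("m1", "m2", "m3"))
  expect_equal(u$score[u$mirna_id == "m2"], 2)  # better of 3 and 2
  i <- combine_predictions(a, b, "intersection")
  expect_equal(i$mirna_id, "m2")
  expect_equal(i$score, 3)  # worse of the two
  # idempotence
  expect_equal(nrow(combine_predictions(a, a, "union")), 2L)
  expect_equal(nrow(combine_predictions(a, a, "intersection")), 2L)
  # empty intersection
  expect_equal(nrow(combine_predictions(
    a, pred_df("x", "y", 1), "intersection")), 0L)
})

test_that("combination containment holds on random benchmarks", {
  set.seed(121)
  val <- pair_df(paste0("m", 1:15), paste0("t", 1:15))
  for (k in 1:8) {
    ia <- sample(25, 12); ib <- sample(25, 12)
    a <- pred_df(paste0("m", ia), paste0("t", ia), runif(12), "A")
    b <- pred_df(paste0("m", ib), paste0("t", ib), runif(12), "B")
    cu <- confusion_from_predictions(combine_predictions(a, b, "union"), val)
    ci <- confusion_from_predictions(
      combine_predictions(a, b, "intersection"), val)
    ca <- confusion_from_predictions(a, val)
    cb <- confusion_from_predictions(b, val)
    expect_gte(cu$tp, max(ca$tp, cb$tp))
    expect_lte(ci$fp, min(ca$fp, cb$fp))
  }
})

test_that("the energy-length trend recovers a negative association", {
  set.seed(131)
  len <- sample(200:1500, 200, replace = TRUE)
  dg <- -0.05 * len + rnorm(200, sd = 5)
  tr <- energy_length_trend(data.frame(transcript_length = len, delta_g = dg))
  expect_lt(tr$rho, -0.5)
  expect_true(all(diff(tr$curve$delta_g_smooth) <= 1e-9))
  # constant energies: no rank trend
  flat <- energy_length_trend(
    data.frame(transcript_length = 1:20, delta_g = rep(-5, 20)))
  expect_equal(flat$rho, 0)
  # strictly decreasing, noise-free: rho = -1
  mono <- energy_length_trend(
    data.frame(transcript_length = 1:20, delta_g = -(1:20)))
  expect_equal(mono$rho, -1)
  expect_error(energy_length_trend(
    data.frame(transcript_length = 1:5, delta_g = 1:5)), "at least 10")
})
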