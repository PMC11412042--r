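test_that("confusion counts match hand counts and a per-pixel oracle", {
  truth <- matrix(c(0L, 0L, 1L, 2L), 2, 2)
  pred <- matrix(c(0L, 1L, 1L, 1L), 2, 2)
  cc <- confusion_counts(pred, truth)
  expect_equal(cc[1, 1], 1)
  expect_equal(cc[1, 2], 1)
  expect_equal(cc[2, 2], 1)
  expect_equal(cc[3, 2], 1)
  expect_equal(sum(cc), 4)

  set.seed(7)
  truth <- matrix(sample(0:2, 32 * 32, replace = TRUE), 32)
  pred <- matrix(sample(0:2, 32 * 32, replace = TRUE), 32)
  expect_equal(unclass(confusion_counts(pred, truth)),
               oracle_confusion(pred, truth), ignore_attr = TRUE)

  expect_error(confusion_counts(pred[1:10, ], truth), "shape")
  expect_error(confusion_counts(pred + 5L, truth), "labels")
})

test_that("IoU follows the one-vs-rest closed form and MIoU averages it", {
  # TP = 50, FP = 25, FN = 25 for class 1 -> IoU = 0.5
  truth <- c(rep(1L, 75), rep(0L, 50))
  pred <- c(rep(1L, 50), rep(0L, 25), rep(1L, 25), rep(0L, 25))
  cc <- confusion_counts(pred, truth, k = 2)
  res <- iou_and_miou(cc)
  expect_equal(res$iou[["class1"]], 0.5)

  # perfect prediction
  m <- matrix(sample(0:2, 100, replace = TRUE), 10)
  perfect <- iou_and_miou(confusion_counts(m, m))
  expect_equal(unname(perfect$iou), rep(1, 3))
  expect_equal(perfect$miou, 1)

  # hand-count example agrees with the set-intersection oracle
  truth <- matrix(c(0L, 0L, 1L, 2L), 2, 2)
  pred <- matrix(c(0L, 1L, 1L, 1L), 2, 2)
  res <- iou_and_miou(confusion_counts(pred, truth))
  or <- vapply(0:2, function(cl) oracle_iou(pred, truth, cl), numeric(1))
  expect_equal(unname(res$iou), or)
  expect_equal(res$miou, mean(or, na.rm = TRUE))
})

test_that("MIoU lies between the extreme per-class IoUs and excludes absent classes", {
  set.seed(11)
  truth <- matrix(sample(0:2, 400, replace = TRUE), 20)
  pred <- matrix(sample(0:2, 400, replace = TRUE), 20)
  res <- iou_and_miou(confusion_counts(pred, truth))
  expect_gte(res$miou, min(res$iou, na.rm = TRUE))
  expect_lte(res$miou, max(res$iou, na.rm = TRUE))

  # class 2 absent from both truth and prediction -> excluded
  truth <- c(0L, 0L, 1L, 1L)
  pred <- c(0L, 1L, 1L, 1L)
  res <- iou_and_miou(confusion_counts(pred, truth))
  expect_true(is.na(res$iou[["weed"]]))
  expect_equal(res$miou, mean(res$iou[1:2]))
})

test_that("precision/recall/F1 match closed forms and the printed F1 equals the harmonic form", {
  # TP=8, FP=2, FN=2, TN=88
  truth <- c(rep(1L, 10), rep(0L, 90))
  pred <- c(rep(1L, 8), 0L, 0L, rep(1L, 2), rep(0L, 88))
  prf <- precision_recall_f1(confusion_counts(pred, truth, k = 2), 1)
  expect_equal(unname(prf), c(0.8, 0.8, 0.8))

  m <- matrix(sample(0:2, 100, replace = TRUE), 10)
  perfect <- precision_recall_f1(confusion_counts(m, m), 1)
  expect_equal(unname(perfect), c(1, 1, 1))

  # algebraic identity of F1 = 2TP/(N+TP-TN) and 2TP/(2TP+FP+FN)
  set.seed(3)
  for (i in 1:1000) {
    tp <- sample(1:100, 1); fp <- sample(0:100, 1)
    fn <- sample(0:100, 1); tn <- sample(0:100, 1)
    n <- tp + fp + fn + tn
    f1_printed <- 2 * tp / (n + tp - tn)
    f1_harmonic <- 2 * tp / (2 * tp + fp + fn)
    expect_lt(abs(f1_printed - f1_harmonic), 1e-12)
  }
})

test_that("undefined precision is flagged missing, not zero", {
  # class 1 never predicted: TP + FP = 0
  truth <- c(1L, 1L, 0L, 0L)
  pred <- c(0L, 0L, 0L, 0L)
  prf <- precision_recall_f1(confusion_counts(pred, truth, k = 2), 1)
  expect_true(is.na(prf[["precision"]]))
  expect_equal(prf[["recall"]], 0)
})

test_that("consistent label permutation permutes per-class metrics identically", {
  set.seed(5)
  truth <- sample(0:2, 500, replace = TRUE)
  pred <- sample(0:2, 500, replace = TRUE)
  perm <- c(2L, 0L, 1L)   # class c -> perm[c+1]
  res1 <- iou_and_miou(confusion_counts(pred, truth))
  res2 <- iou_and_miou(confusion_counts(perm[pred + 1L], perm[truth + 1L]))
  expect_equal(unname(res1$iou), unname(res2$iou[perm + 1L]))
  expect_equal(res1$miou, res2$miou)
})

test_that("regression scores reproduce hand arithmetic and degenerate cases", {
  obs <- c(1, 2, 3); pred <- c(1, 1, 4)
  sc <- regression_scores(pred, obs)
  expect_equal(sc$rmse, sqrt(2 / 3))
  expect_equal(sc$r2, 0)          # SSE = 2, SST = 2
  expect_equal(sc$rep, 100 * sqrt(2 / 3) / 2)

  expect_equal(regression_scores(obs, obs)$rmse, 0)
  expect_equal(regression_scores(obs, obs)$r2, 1)
  expect_equal(regression_scores(rep(mean(obs), 3), obs)$r2, 0)

  # R^2 via an independent 1 - SSE/SST oracle
  set.seed(9)
  o <- rnorm(50); p <- o + rnorm(50, 0, 0.3)
  sc <- regression_scores(p, o)
  expect_lt(abs(sc$r2 - (1 - sum((p - o)^2) / sum((o - mean(o))^2))), 1e-12)

  # constant observations: R^2 undefined, flagged
  expect_true(is.na(regression_scores(c(1, 2), c(5, 5))$r2))
  expect_error(regression_scores(1, 1), "at least 2")
})

test_that("stratified metrics pool pixels rather than averaging tiles", {
  # unequal tiles: pooling and per-tile averaging must disagree
  t1 <- list(pred = matrix(c(1L, 1L, 1L, 0L), 2),
             truth = matrix(c(1L, 1L, 0L, 0L), 2), stratum = "B/W")
  t2 <- list(pred = matrix(rep(0L, 64), 8),
             truth = matrix(c(rep(0L, 60), rep(1L, 4)), 8), stratum = "B/W")
  rep_pooled <- stratified_report(list(t1, t2))
  pooled_pred <- c(t1$pred, t2$pred)
  pooled_truth <- c(t1$truth, t2$truth)
  oracle <- oracle_iou(pooled_pred, pooled_truth, 1)
  expect_equal(rep_pooled$iou[rep_pooled$class == "wheat"], oracle)
  per_tile_mean <- mean(c(oracle_iou(t1$pred, t1$truth, 1),
                          oracle_iou(t2$pred, t2$truth, 1)))
  expect_false(isTRUE(all.equal(oracle, per_tile_mean)))

  # one stratum equals unstratified metrics; identical strata give equal rows
  single <- stratified_report(list(t1))
  un <- iou_and_miou(confusion_counts(t1$pred, t1$truth))
  expect_equal(single$miou[1], un$miou)
  two <- stratified_report(list(t1, c(t1[1:2], list(stratum = "D/W"))))
  expect_equal(two$f1[two$stratum == "B/W"], two$f1[two$stratum == "D/W"])

  expect_error(stratified_report(list(t1), strata = c("D/J")), "unknown stratum")
})
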