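test_that("perfect predictions give a diagonal confusion matrix", {
  m <- matrix(sample(0:2, 64, TRUE), 8, 8)
  cm <- confusion_matrix(m, m, 3)
  expect_equal(unname(diag(cm)), c(sum(m == 0), sum(m == 1), sum(m == 2)))
  expect_equal(sum(cm) - sum(diag(cm)), 0)
})

test_that("the 2x2 toy example counts pixels exhaustively", {
  truth <- rbind(c(0L, 0L), c(1L, 1L))
  pred <- rbind(c(0L, 1L), c(1L, 1L))
  cm <- confusion_matrix(truth, pred, 2)
  expect_equal(unname(cm), rbind(c(1, 1), c(0, 2)))
})

test_that("confusion matrix equals a nested-loop tally on random masks", {
  set.seed(1)
  for (i in 1:10) {
    n <- sample(2:8, 1)
    truth <- matrix(sample(0:(n - 1), 64 * 64, TRUE), 64, 64)
    pred <- matrix(sample(0:(n - 1), 64 * 64, TRUE), 64, 64)
    expect_equal(unname(confusion_matrix(truth, pred, n)),
                 oracle_cm(truth, pred, n))
  }
})

test_that("confusion matrix validates shapes and label ranges", {
  expect_error(confusion_matrix(matrix(0, 2, 2), matrix(0, 2, 3), 2),
               "co-registered")
  expect_error(confusion_matrix(matrix(3L, 2, 2), matrix(0L, 2, 2), 2),
               "\\[0, 2\\)")
})

test_that("per-class precision/recall/F1 match the direct formulas", {
  cm <- rbind(c(1, 1), c(0, 2))
  prf <- per_class_prf(cm)
  expect_equal(prf$precision, c(1, 2 / 3))
  expect_equal(prf$recall, c(0.5, 1))
  expect_equal(prf$f1, c(2 / 3, 0.8))
})

test_that("degenerate classes are scored 0 and flagged", {
  cm <- rbind(c(5, 0, 0), c(0, 3, 0), c(2, 0, 0))   # class 2 never predicted
  prf <- per_class_prf(cm)
  expect_equal(prf$precision[3], 0)
  expect_equal(prf$f1[3], 0)
  expect_true(prf$degenerate[3])
  perfect <- per_class_prf(diag(c(4, 5, 6)))
  expect_true(all(perfect$precision == 1 & perfect$recall == 1 &
                    perfect$f1 == 1))
})

test_that("summary metrics reproduce OA, kappa and mean F1 by hand", {
  cm <- rbind(c(1, 1), c(0, 2))
  rep <- summary_metrics(cm)
  expect_equal(rep$overall_accuracy, 0.75)
  pe <- (2 * 1 + 2 * 3) / 16
  expect_equal(rep$kappa, (0.75 - pe) / (1 - pe))
  expect_equal(rep$mean_f1, mean(c(2 / 3, 0.8)))
  perfect <- summary_metrics(diag(c(3, 7)))
  expect_equal(perfect$overall_accuracy, 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$mean_f1, 1)
})

test_that("statistically independent predictions have kappa 0", {
  row_m <- c(30, 50, 20)
  col_m <- c(10, 60, 30)
  cm <- outer(row_m, col_m) / 100    # rank-1: truth independent of prediction
  rep <- summary_metrics(cm)
  expect_equal(rep$kappa, 0, tolerance = 1e-12)
})

test_that("row/column sums conserve truth and prediction counts", {
  set.seed(2)
  truth <- matrix(sample(0:3, 400, TRUE), 20, 20)
  pred <- matrix(sample(0:3, 400, TRUE), 20, 20)
  cm <- confusion_matrix(truth, pred, 4)
  expect_equal(unname(rowSums(cm)), vapply(0:3, function(i) sum(truth == i),
                                           numeric(1)))
  expect_equal(unname(colSums(cm)), vapply(0:3, function(i) sum(pred == i),
                                           numeric(1)))
})

test_that("F1 never exceeds max(P, R) and kappa never exceeds OA", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    cm <- matrix(rpois(n * n, 5), n, n)
    if (sum(cm) == 0) next
    prf <- per_class_prf(cm)
    expect_true(all(prf$f1 <= pmax(prf$precision, prf$recall) + 1e-12))
    rep <- summary_metrics(cm)
    pe <- sum(rowSums(cm) * colSums(cm)) / sum(cm)^2
    if (pe > 0 && pe < 1)
      expect_lte(rep$kappa, rep$overall_accuracy + 1e-12)
  }
})

test_that("mean F1 can exclude the background class", {
  cm <- diag(c(10, 5, 5)); cm[1, 2] <- 10
  with_bg <- summary_metrics(cm)
  without <- summary_metrics(cm, exclude_class = 0)
  expect_equal(without$mean_f1,
               mean(with_bg$per_class$f1[2:3]))
})

test_that("paired F1 t-test matches the textbook formula", {
  set.seed(4)
  for (i in 1:10) {
    a <- runif(16); b <- runif(16)
    res <- paired_f1_test(a, b)
    d <- a - b
    t_hand <- mean(d) / (sd(d) / sqrt(16))
    expect_equal(res$t, t_hand, tolerance = 1e-9)
    expect_equal(res$df, 15)
    expect_equal(res$p_value, 2 * pt(-abs(t_hand), 15), tolerance = 1e-9)
  }
})

test_that("degenerate pairings are rejected", {
  a <- runif(8)
  expect_error(paired_f1_test(a, a), "zero variance")
  expect_error(paired_f1_test(a, a + 0.1), "zero variance")
  expect_error(paired_f1_test(a[1:2], a[1:2] + c(0, 1)), "at least 3")
})
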