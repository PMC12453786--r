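test_that("confusion counts satisfy their accounting identities", {
  ## perfect prediction: no off-diagonal mass
  cc <- confusion_counts(rep(c("a", "b", "c"), c(4, 3, 3)),
                         rep(c("a", "b", "c"), c(4, 3, 3)))
  expect_true(all(cc$counts$FP == 0) && all(cc$counts$FN == 0))

  ## hand-counted two-class example
  cc2 <- confusion_counts(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  a <- cc2$counts[cc2$counts$class == "A", ]
  expect_equal(c(a$TP, a$FN, a$FP, a$TN), c(1, 1, 0, 2))

  ## random 5-class case against an independent pairwise tally
  withr::with_seed(42, {
    r <- random_labels(200, 5)
    cc3 <- confusion_counts(r$y_true, r$y_pred, r$classes)
    for (k in r$classes) {
      tp <- sum(r$y_true == k & r$y_pred == k)
      fp <- sum(r$y_true != k & r$y_pred == k)
      fn <- sum(r$y_true == k & r$y_pred != k)
      row <- cc3$counts[cc3$counts$class == k, ]
      expect_equal(c(row$TP, row$FP, row$FN), c(tp, fp, fn))
      expect_equal(row$TP + row$FP + row$FN + row$TN, 200)
    }
    expect_equal(sum(cc3$counts$TP), sum(r$y_true == r$y_pred))
  })

  expect_error(confusion_counts(c("a", "b"), "a"), "lengths")
  expect_error(confusion_counts("a", "z", classes = c("a", "b")), "vocabulary")
})

test_that("perfect prediction scores 100 on all benefit metrics and 0 loss", {
  cc <- confusion_counts(rep(c("a", "b"), 5), rep(c("a", "b"), 5))
  r <- metric_report(cc)
  expect_equal(r$precision, 100)
  expect_equal(r$recall, 100)
  expect_equal(r$f_score, 100)
  expect_equal(r$kappa, 100)
  expect_equal(r$mcc, 100)
  expect_equal(r$accuracy, 100)
  expect_equal(r$hamming_loss, 0)
})

test_that("the metric suite matches brute-force formula evaluation on 50 random cases", {
  withr::with_seed(77, {
    for (case in 1:50) {
      k <- sample(2:6, 1)
      n <- sample(20:120, 1)
      r <- random_labels(n, k, err = runif(1, 0.05, 0.6))
      mine <- metric_report(confusion_counts(r$y_true, r$y_pred, r$classes))
      oracle <- brute_metrics(r$y_true, r$y_pred, r$classes)
      for (m in names(oracle))
        expect_equal(mine[[m]], unname(oracle[m]), tolerance = 1e-9,
                     label = paste("case", case, m))
      ## single-label multiclass identity
      expect_equal(mine$hamming_loss + mine$accuracy, 100, tolerance = 1e-12)
    }
  })
})

test_that("kappa and accuracy agree with caret on a spot check", {
  skip_if_not_installed("caret")
  withr::with_seed(11, {
    r <- random_labels(300, 4, err = 0.35)
    mine <- metric_report(confusion_counts(r$y_true, r$y_pred, r$classes))
    cm <- caret::confusionMatrix(factor(r$y_pred, r$classes),
                                 factor(r$y_true, r$classes))
    expect_equal(mine$accuracy / 100, unname(cm$overall["Accuracy"]),
                 tolerance = 1e-12)
    expect_equal(mine$kappa / 100, unname(cm$overall["Kappa"]),
                 tolerance = 1e-12)
  })
})

test_that("kappa is 100 only for perfect multi-class prediction and MCC ignores labels", {
  withr::with_seed(13, {
    r <- random_labels(100, 3, err = 0.2)
    rep1 <- metric_report(confusion_counts(r$y_true, r$y_pred, r$classes))
    expect_lt(rep1$kappa, 100)
    ## relabel classes by a permutation: MCC invariant
    perm <- c(A = "C", B = "A", C = "B")
    rep2 <- metric_report(confusion_counts(unname(perm[r$y_true]),
                                           unname(perm[r$y_pred])))
    expect_equal(rep2$mcc, rep1$mcc, tolerance = 1e-12)
  })
})

test_that("overfitting percentages and statuses reproduce the closed form", {
  r1 <- overfit(1.0, 0.7976)
  expect_equal(r1$overfit_pct, 20.24)
  expect_equal(r1$status, "Yes")
  r2 <- overfit(0.6353, 0.6359)
  expect_equal(r2$overfit_pct, -0.09)
  expect_equal(r2$status, "No")
  r3 <- overfit(0.7244, 0.7214)
  expect_equal(r3$overfit_pct, 0.41)
  expect_equal(r3$status, "No")
  r4 <- overfit(0.9174, 0.841)
  expect_equal(r4$overfit_pct, 8.33)
  expect_equal(r4$status, "Mild")
  expect_equal(overfit(0.5, 0.5)$overfit_pct, 0)
  expect_equal(overfit(0.5, 0.5)$status, "No")
  expect_error(overfit(0, 0.5), "train_mean")
})

test_that("difference reports implement AD and PD per metric", {
  b <- c(m1 = 72.007, m2 = 86.131)
  u <- c(m1 = 62.539, m2 = 82.239)
  d <- diff_report(b, u)
  expect_equal(d$AD[d$metric == "m1"], 9.468, tolerance = 1e-9)
  expect_equal(d$PD[d$metric == "m1"], 15.14)
  expect_equal(d$AD[d$metric == "m2"], 3.892, tolerance = 1e-9)
  same <- diff_report(b, b)
  expect_true(all(same$AD == 0) && all(same$PD == 0))
  dz <- diff_report(c(m = 1), c(m = 0))
  expect_true(is.na(dz$PD))
  expect_match(attr(dz, "flags"), "undefined")
  expect_error(diff_report(c(a = 1), c(b = 1)), "metric sets")
})

test_that("rank-statistic AUC behaves at its reference points", {
  y <- rep(c("a", "b", "c"), times = c(5, 6, 7))
  onehot <- sapply(c("a", "b", "c"), function(k) as.numeric(y == k))
  expect_true(all(roc_auc(y, onehot)$per_class == 1))

  withr::with_seed(19, {
    yb <- sample(c("p", "q"), 4000, TRUE)
    sc <- cbind(p = runif(4000), q = runif(4000))
    a <- roc_auc(yb, sc)
    expect_lt(abs(a$per_class[["p"]] - 0.5), 0.05)  # uninformative scores
    rev <- roc_auc(yb, -sc)
    expect_equal(rev$per_class[["p"]], 1 - a$per_class[["p"]], tolerance = 1e-12)
  })
  expect_error(roc_auc(rep("a", 5), cbind(a = runif(5))), "single-class")
})

test_that("AUC agrees with pROC on a binary spot check", {
  skip_if_not_installed("pROC")
  withr::with_seed(21, {
    y <- sample(c("neg", "pos"), 150, TRUE)
    s <- rnorm(150) + (y == "pos")
    mine <- roc_auc(y, cbind(neg = -s, pos = s))$per_class[["pos"]]
    ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                          levels = c("neg", "pos"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(mine, ref, tolerance = 1e-12)
  })
})
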