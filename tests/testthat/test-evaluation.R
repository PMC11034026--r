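# Metric definitions, rank statistics against brute-force oracles, and
# the cross-validation harness.

test_that("confusion metrics match hand-evaluated formulas", {
  # perfect classifier
  expect_equal(unname(confusionMetrics(TP = 1, FP = 0, TN = 1, FN = 0)),
               rep(1, 5))

  m <- confusionMetrics(TP = 3, FP = 2, TN = 2, FN = 1)
  expect_equal(m[["Sn"]], 0.75)
  expect_equal(m[["Sp"]], 0.5)
  expect_equal(m[["ACC"]], 0.625)
  expect_equal(m[["Precision"]], 0.6)
  expect_equal(m[["F1"]], 2 * 0.6 * 0.75 / (0.6 + 0.75), tolerance = 1e-12)

  # zero denominators are missing, not zero
  m0 <- confusionMetrics(TP = 0, FP = 0, TN = 5, FN = 3)
  expect_true(is.na(m0[["Precision"]]))
  expect_true(is.na(m0[["F1"]]))
  expect_error(confusionMetrics(TP = -1, FP = 0, TN = 0, FN = 0),
               "non-negative")

  # counts vector from labels round-trips
  cc <- confusionCounts(c("prokaryotic", "prokaryotic", "eukaryotic"),
                        c("prokaryotic", "eukaryotic", "eukaryotic"))
  expect_identical(cc, c(TP = 1L, FP = 0L, TN = 1L, FN = 1L))
})

test_that("ROC-AUC matches hand cases and the pair-counting oracle", {
  expect_equal(rocAUC(c(TRUE, TRUE, FALSE, FALSE),
                      c(0.9, 0.8, 0.7, 0.1)), 1)
  expect_equal(rocAUC(c(TRUE, TRUE, FALSE, FALSE), rep(0.3, 4)), 0.5)
  # 3 of 4 ordered pairs correct
  expect_equal(rocAUC(c(TRUE, TRUE, FALSE, FALSE),
                      c(0.9, 0.4, 0.6, 0.1)), 0.75)

  expect_error(rocAUC(c(TRUE, TRUE), c(0.1, 0.2)), "negative")
  expect_error(rocAUC(c(FALSE, FALSE), c(0.1, 0.2)), "positive")

  set.seed(99)
  for (i in 1:100) {
    n <- sample(4:50, 1L)
    lab <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2L, replace = TRUE))
    # coarse grid forces plenty of ties
    sc <- sample(seq(0, 1, by = 0.2), n, replace = TRUE)
    expect_equal(rocAUC(lab, sc), aucOracle(lab, sc), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  lab <- sample(c(TRUE, FALSE), 60, replace = TRUE, prob = c(0.4, 0.6))
  lab[1:2] <- c(TRUE, FALSE)
  sc <- round(runif(60), 2)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(rocAUC(lab, sc), ref, tolerance = 1e-12)
})

test_that("label-flip symmetry holds for AUC", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(6:40, 1L)
    lab <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2L, replace = TRUE))
    sc <- runif(n)
    expect_equal(rocAUC(lab, sc), 1 - rocAUC(lab, -sc), tolerance = 1e-12)
  }
})

test_that("average precision matches hand-evaluated step sums", {
  # perfect ranking of 2 positives over 2 negatives
  expect_equal(averagePrecision(c(TRUE, TRUE, FALSE, FALSE),
                                c(4, 3, 2, 1)), 1)
  # ranking pos, neg, pos, neg: 1 * 1/2 + 2/3 * 1/2
  expect_equal(averagePrecision(c(TRUE, FALSE, TRUE, FALSE),
                                c(4, 3, 2, 1)), 0.5 + 1 / 3,
               tolerance = 1e-12)
  # all positives
  expect_equal(averagePrecision(rep(TRUE, 3), c(0.2, 0.5, 0.9)), 1)
  # tied scores are grouped: both orderings give the same AP
  expect_equal(averagePrecision(c(TRUE, FALSE), c(0.5, 0.5)),
               averagePrecision(c(FALSE, TRUE), c(0.5, 0.5)))
  expect_error(averagePrecision(c(FALSE, FALSE), c(0.1, 0.2)), "positive")

  # metrics stay within [0, 1] on random inputs
  set.seed(30)
  for (i in 1:25) {
    n <- sample(5:40, 1L)
    lab <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2L, replace = TRUE))
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    expect_true(rocAUC(lab, sc) >= 0 && rocAUC(lab, sc) <= 1)
    ap <- averagePrecision(lab, sc)
    expect_true(ap >= 0 && ap <= 1)
  }
})

test_that("cross-validation reports per-fold, per-group and summary rows", {
  ds <- tinyDataset(nGenomes = 10L, nFragments = 30L, group = "A",
                    divergence = 0.8)
  cv <- crossValidate(ds, tinyConfig(), epochs = 2L)

  # 5 folds x (group A + pooled) rows
  expect_identical(nrow(cv$perFold), 10L)
  expect_setequal(unique(cv$perFold$group), c("A", "pooled"))
  expect_setequal(unique(cv$perFold$fold), 0:4)
  expect_identical(nrow(cv$summary), 2L)
  expect_true(all(cv$perFold$AUC >= 0 & cv$perFold$AUC <= 1))

  # every fragment is scored exactly once across held-out folds
  expect_identical(sort(cv$predictions$id),
                   sort(fragmentInfo(ds)$id))

  # bookkeeping: metrics recomputed from the saved per-item predictions
  # equal the reported pooled rows
  for (f in 0:4) {
    pr <- cv$predictions[cv$predictions$fold == f, ]
    rep_ <- cv$perFold[cv$perFold$fold == f &
                         cv$perFold$group == "pooled", ]
    expect_equal(rep_$AUC, rocAUC(pr$label, pr$score), tolerance = 1e-12)
    m <- confusionMetrics(confusionCounts(pr$label, pr$predicted))
    expect_equal(rep_$Sn, m[["Sn"]], tolerance = 1e-12)
    expect_equal(rep_$ACC, m[["ACC"]], tolerance = 1e-12)
  }
})
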