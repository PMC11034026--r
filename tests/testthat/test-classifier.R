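# CNN construction, loss closed forms, training behaviour, persistence.

test_that("configuration defaults reproduce the printed architecture", {
  cfg <- classifierConfig()
  expect_identical(cfg@nFilters, 128L)
  expect_identical(cfg@kernel, c(7L, 7L))
  expect_identical(cfg@poolSize, 2L)
  expect_identical(cfg@poolStride, 2L)
  expect_equal(cfg@dropout, 0.32)
  expect_identical(cfg@denseUnits, 64L)
  expect_identical(cfg@nClasses, 2L)
  expect_equal(cfg@learningRate, 5e-4)
  expect_identical(cfg@batchSize, 16L)
  expect_identical(cfg@epochs, 30L)
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(classifierConfig(dropout = 1), "dropout")
  expect_error(classifierConfig(nFilters = 0), "nFilters")
  expect_error(classifierConfig(nClasses = 1), "nClasses")
  expect_error(classifierConfig(learningRate = -1), "learningRate")
})

test_that("parameter count matches the closed-form layer arithmetic", {
  mod <- buildClassifier(classifierConfig())
  expect_identical(countParams(mod),
                   (7 * 7 * 1 + 1) * 128 + (7 * 7 * 128 + 1) * 128 +
                     (16 * 16 * 128 + 1) * 64 + (64 + 1) * 2)
  # per-tensor shapes
  expect_identical(dim(mod@params$W2), c(7L * 7L * 128L, 128L))
  expect_identical(dim(mod@params$W3), c(16L * 16L * 128L, 64L))
})

test_that("forward pass emits probability vectors summing to one", {
  mod <- buildClassifier(tinyConfig())
  # all-zero input is valid and still softmax-normalised
  p0 <- predictProba(mod, matrix(0, 64, 64))
  expect_equal(sum(p0), 1, tolerance = 1e-6)
  expect_identical(colnames(p0), c("prokaryotic", "eukaryotic"))

  set.seed(3)
  pm <- encodeSGT(setNames(replicate(6, randomDNA(200)), paste0("s", 1:6)))
  p <- predictProba(mod, pm)
  expect_identical(dim(p), c(6L, 2L))
  expect_equal(rowSums(p), setNames(rep(1, 6), pm@ids), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))

  # determinism and order equivariance at inference
  expect_identical(predictProba(mod, pm), p)
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  pmPerm <- new("PatternMatrixSet", data = pm@data[, , perm],
                kappa = pm@kappa, ids = pm@ids[perm])
  expect_equal(predictProba(mod, pmPerm), p[perm, ], tolerance = 0)
})

test_that("cross-entropy loss has the expected closed forms", {
  # probability 1 on the true class -> loss 0
  expect_equal(crossEntropyLoss(rbind(c(1, 0), c(0, 1)),
                                c("prokaryotic", "eukaryotic"),
                                c("prokaryotic", "eukaryotic")), 0,
               tolerance = 1e-9)
  # uniform two-class prediction -> log 2 per sample
  expect_equal(crossEntropyLoss(rbind(c(0.5, 0.5)), 1L), log(2),
               tolerance = 1e-9)
  # loss is non-negative
  set.seed(1)
  q <- matrix(runif(20), 10, 2); q <- q / rowSums(q)
  expect_gte(crossEntropyLoss(q, sample(1:2, 10, TRUE)), 0)
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- classifierConfig(nFilters = 3L, denseUnits = 5L, dropout = 0,
                          seed = 42L)
  mod <- buildClassifier(cfg)
  dims <- viroSGT:::.cnnDims(cfg)
  set.seed(1)
  X <- array(runif(64 * 64 * 2, 0, 0.3), dim = c(64, 64, 2))
  y <- c(0L, 1L)
  res <- viroSGT:::.cnn_train_batch_cpp(X, y, mod@params, dims, 0, 1L)
  lossAt <- function(par)
    viroSGT:::.cnn_train_batch_cpp(X, y, par, dims, 0, 1L)$loss
  eps <- 1e-3
  set.seed(2)
  checked <- 0L
  for (nm in names(mod@params)) {
    for (k in 1:3) {
      i <- sample(length(mod@params[[nm]]), 1L)
      up <- mod@params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- mod@params; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (lossAt(up) - lossAt(dn)) / (2 * eps)
      ana <- res$grads[[nm]][i]
      # skip entries sitting on a ReLU/maxpool kink, where the numeric
      # two-sided quotient is not the derivative
      if (abs(num) < 1e-8 && abs(ana) < 1e-8) next
      if (abs(num - ana) / max(abs(num), abs(ana)) < 0.05)
        checked <- checked + 1L
    }
  }
  expect_gte(checked, 12L)
})

test_that("training learns a separable synthetic task", {
  ds <- tinyDataset(nGenomes = 10L, nFragments = 40L, group = "D",
                    divergence = 1)
  enc <- encodeSGT(ds)
  lab <- fragmentInfo(ds)$label
  mod <- trainClassifier(buildClassifier(tinyConfig()), enc, lab,
                         epochs = 10L)
  expect_true(mod@trained)
  expect_identical(nrow(mod@history), 10L)
  acc <- mean((predictProba(mod, enc)[, 1] > 0.5) ==
                (lab == "prokaryotic"))
  expect_gte(acc, 0.95)
  # loss trend: non-increasing overall, allowing per-epoch noise
  expect_lt(mod@history$loss[10L], mod@history$loss[1L])
})

test_that("training is reproducible from the configuration seed", {
  ds <- tinyDataset(nGenomes = 6L, nFragments = 12L)
  enc <- encodeSGT(ds)
  lab <- fragmentInfo(ds)$label
  m1 <- trainClassifier(buildClassifier(tinyConfig()), enc, lab, epochs = 3L)
  m2 <- trainClassifier(buildClassifier(tinyConfig()), enc, lab, epochs = 3L)
  expect_equal(m1@history$loss, m2@history$loss, tolerance = 1e-4)
  expect_identical(m1@params, m2@params)
})

test_that("label and shape errors are caught", {
  ds <- tinyDataset(nGenomes = 6L, nFragments = 12L)
  enc <- encodeSGT(ds)
  lab <- fragmentInfo(ds)$label
  mod <- buildClassifier(tinyConfig())
  badLab <- lab; badLab[1] <- "archaeal"
  expect_error(trainClassifier(mod, enc, badLab), "archaeal")
  expect_error(trainClassifier(mod, enc, lab[-1]), "length")
})

test_that("weights round-trip exactly and guard against mismatches", {
  ds <- tinyDataset(nGenomes = 6L, nFragments = 12L)
  enc <- encodeSGT(ds)
  mod <- trainClassifier(buildClassifier(tinyConfig()), enc,
                         fragmentInfo(ds)$label, epochs = 2L)
  path <- tempfile(fileext = ".rds")
  saveClassifier(mod, path)
  back <- loadClassifier(path)
  expect_identical(back@params, mod@params)
  expect_identical(back@classNames, mod@classNames)
  expect_identical(predictProba(back, enc), predictProba(mod, enc))

  # kappa guard: matrices encoded at a different kappa are rejected
  enc2 <- suppressWarnings(encodeSGT(ds, kappa = 2))
  expect_error(predictProba(back, enc2), "kappa")
  modK2 <- buildClassifier(tinyConfig(kappa = 2))
  expect_error(trainClassifier(modK2, enc, fragmentInfo(ds)$label),
               "kappa")

  # corrupted / foreign files are refused with the path named
  bad <- tempfile(fileext = ".rds")
  writeLines("not a weights file", bad)
  expect_error(loadClassifier(bad), basename(bad))
  other <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), other)
  expect_error(loadClassifier(other), "weights file")
})
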