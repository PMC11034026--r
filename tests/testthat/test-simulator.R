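# Markov genome sources, fragmenting, error injection, fold assignment.

test_that("degenerate and seeded genome sampling behave", {
  # order-0 source that always emits A
  pA <- matrix(c(1, 0, 0, 0), 1, 4)
  src <- markovSource("x", transitions = pA, order = 0L)
  expect_identical(unname(sampleGenome(src, 10L)),
                   strrep("A", 10))

  src2 <- defaultVirusSources()[[1]]
  g1 <- withr::with_seed(9L, sampleGenome(src2, 500L))
  g2 <- withr::with_seed(9L, sampleGenome(src2, 500L))
  expect_identical(g1, g2)
  expect_error(sampleGenome(src2, 2L), "order")
})

test_that("transition tables are validated", {
  bad <- matrix(1, 16, 4)
  expect_error(markovSource("x", transitions = bad), "sum to 1")
  expect_error(markovSource("", transitions = NULL), "label")
})

test_that("sampled genomes reproduce the stationary trinucleotide usage", {
  src <- defaultVirusSources()[[1]]
  st <- stationaryDistribution(src)
  expect_equal(sum(st$context), 1, tolerance = 1e-9)
  expect_equal(sum(st$trinucleotide), 1, tolerance = 1e-9)

  withr::with_seed(21L, {
    genomes <- vapply(1:30, function(i) sampleGenome(src, 5000L),
                      character(1))
  })
  counts <- integer(64)
  for (g in genomes) {
    tok <- tokenizeTrinucleotides(g)
    counts <- counts + tabulate(tok@symbols + 1L, 64L)
  }
  n <- sum(counts)
  phat <- counts / n
  p0 <- unname(st$trinucleotide)
  se <- sqrt(p0 * (1 - p0) / n)
  # overlapping windows are positively correlated, so allow a margin on
  # top of the iid 3-standard-error band
  expect_true(all(abs(phat - p0) <= 3 * se + 3e-3))
})

test_that("fragments respect group bounds with uniform lengths", {
  withr::with_seed(4L, {
    src <- defaultVirusSources()[[1]]
    genomes <- setNames(vapply(1:2, function(i) sampleGenome(src, 30000L),
                               character(1)), c("g1", "g2"))
    fs <- fragmentGenomes(genomes, "prokaryotic", group = "D",
                          nPerGenome = 5000L)
  })
  info <- fragmentInfo(fs)
  expect_identical(nrow(info), 10000L)
  expect_true(all(info$width >= 1200L & info$width <= 1800L))
  expect_setequal(unique(info$genome), c("g1", "g2"))

  # uniformity of lengths: chi-square over 6 equal bins, alpha = 0.01
  bins <- cut(info$width, breaks = seq(1199.5, 1800.5, length.out = 7L))
  expect_gt(chisq.test(table(bins))$p.value, 0.01)

  # zero request and too-short genomes
  expect_identical(length(fragmentGenomes(genomes, "p", "A", 0L)), 0L)
  shorty <- c(tiny = strrep("ACGT", 100L))
  expect_warning(fragmentGenomes(shorty, "p", "D", 2L), "tiny")
})

test_that("error injection matches its nominal rates", {
  expect_error(injectErrors("ACGT", subRate = 1), "rates")
  s <- withr::with_seed(2L, randomDNA(10000L))

  # identity at zero error (id suffix aside)
  expect_identical(unname(injectErrors(s, 0, 0)), s)

  withr::with_seed(31L, {
    mutated <- injectErrors(s, subRate = 0.15, indelRate = 0)
    indeled <- injectErrors(s, subRate = 0, indelRate = 0.10)
  })
  mism <- sum(strsplit(s, "")[[1]] != strsplit(unname(mutated), "")[[1]])
  # central 99% binomial interval, n = 10000, p = 0.15
  expect_gte(mism, qbinom(0.005, 10000L, 0.15))
  expect_lte(mism, qbinom(0.995, 10000L, 0.15))

  # length change = insertions - deletions, each Bin(10000, 0.05)
  delta <- nchar(indeled) - nchar(s)
  bound <- qbinom(0.995, 10000L, 0.05) - qbinom(0.005, 10000L, 0.05)
  expect_lte(abs(delta), bound)
  expect_match(names(injectErrors(c(f = "ACGTACGT"), 0.1, 0.1)),
               "sub0.1.*indel0.1")
})

test_that("datasets balance labels and never leak genomes across folds", {
  ds <- buildDataset(defaultVirusSources(), nGenomes = 10L,
                     genomeLength = 2000L, groups = c("A", "B"),
                     nFragments = 30L, kFolds = 5L, seed = 8L)
  info <- fragmentInfo(ds)
  # exact per-class per-group counts
  expect_true(all(table(info$label, info$group) == 30L))
  # 10 genomes over 5 folds -> 2 genomes per fold per class
  gf <- unique(info[, c("genome", "fold", "label")])
  expect_true(all(table(gf$label, gf$fold) == 2L))
  # leakage: a genome id maps to exactly one fold
  expect_true(all(tapply(info$fold, info$genome,
                         function(f) length(unique(f))) == 1L))
  expect_error(buildDataset(defaultVirusSources(), nGenomes = 3L,
                            genomeLength = 2000L, nFragments = 5L,
                            kFolds = 5L), "kFolds")
  expect_error(buildDataset(defaultVirusSources()[1], nGenomes = 5L,
                            genomeLength = 2000L, nFragments = 5L),
               "distinct labels")
})

test_that("identical seeds give byte-identical FASTA output", {
  write1 <- tempfile(fileext = ".fa"); manif1 <- tempfile(fileext = ".tsv")
  write2 <- tempfile(fileext = ".fa"); manif2 <- tempfile(fileext = ".tsv")
  d1 <- buildDataset(defaultVirusSources(), nGenomes = 5L,
                     genomeLength = 2000L, groups = "A",
                     nFragments = 10L, seed = 77L)
  d2 <- buildDataset(defaultVirusSources(), nGenomes = 5L,
                     genomeLength = 2000L, groups = "A",
                     nFragments = 10L, seed = 77L)
  writeDataset(d1, write1, manif1)
  writeDataset(d2, write2, manif2)
  expect_identical(readBin(write1, "raw", file.size(write1)),
                   readBin(write2, "raw", file.size(write2)))
  expect_identical(readLines(manif1), readLines(manif2))
  # manifest carries the five annotation columns
  expect_identical(strsplit(readLines(manif1, n = 1L), "\t")[[1]],
                   c("id", "label", "genome", "group", "fold"))
})

test_that("fold splitting is genome-level", {
  ds <- tinyDataset()
  sp <- splitByFold(ds, 0L)
  expect_identical(length(sp$train) + length(sp$test), length(ds))
  expect_length(intersect(fragmentInfo(sp$train)$genome,
                          fragmentInfo(sp$test)$genome), 0L)
})
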