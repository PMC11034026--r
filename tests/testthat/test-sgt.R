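# Trinucleotide tokenisation and the pair-weight pattern matrix.

test_that("tokenisation produces overlapping trinucleotides with positions", {
  tok <- tokenizeTrinucleotides("ATTCATAACTT")
  expect_identical(trinucleotideNames()[tok@symbols + 1L],
                   c("ATT", "TTC", "TCA", "CAT", "ATA", "TAA", "AAC",
                     "ACT", "CTT"))
  expect_identical(tok@positions, 1:9)
  expect_identical(tok@sourceLength, 11L)

  # lowercase is uppercased
  expect_identical(tokenizeTrinucleotides("attcataactt")@symbols,
                   tok@symbols)
})

test_that("short, degenerate and invalid sequences are handled", {
  expect_length(tokenizeTrinucleotides("AT")@symbols, 0L)
  expect_length(tokenizeTrinucleotides("")@symbols, 0L)

  # windows touching the N are dropped, survivor keeps its offset
  tok <- tokenizeTrinucleotides("ATNGCA")
  expect_identical(trinucleotideNames()[tok@symbols + 1L], "GCA")
  expect_identical(tok@positions, 4L)

  # IUPAC degenerate letters are skippable, non-IUPAC is an error with
  # the offending position named
  expect_length(tokenizeTrinucleotides("ACGRYSWKMBDHVN")@symbols, 1L)
  expect_error(tokenizeTrinucleotides("ACGXA"), "position 4")
})

test_that("pattern matrix matches hand-evaluated cases", {
  m <- sgtMatrix("ATTC", kappa = 1)
  expect_equal(m["ATT", "TTC"], exp(-1), tolerance = 1e-12)
  expect_equal(sum(m > 0), 1L)

  # one strict-order pair of identical symbols
  m2 <- sgtMatrix("AAAA", kappa = 1)
  expect_equal(m2["AAA", "AAA"], exp(-1), tolerance = 1e-12)

  # three ordered pairs at distances 1, 2, 1
  m3 <- sgtMatrix("AAAAA", kappa = 1)
  expect_equal(m3["AAA", "AAA"], (2 * exp(-1) + exp(-2)) / 3,
               tolerance = 1e-12)

  expect_error(sgtMatrix("ATTC", kappa = 0), "kappa")
  expect_error(sgtMatrix("ATTC", kappa = -1), "kappa")
})

test_that("streaming encoder equals the all-pairs oracle", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(4:800, 1L)
    tr <- tokenizeTrinucleotides(randomDNA(n, withN = TRUE))
    kappa <- sample(c(0.5, 1, 2.7), 1L)
    expect_lt(max(abs(unname(sgtMatrix(tr, kappa)) -
                        sgtOracle(tr, kappa))), 1e-10)
  }
})

test_that("pattern weights respect range, monotonicity and determinism", {
  set.seed(1)
  seqs <- replicate(20, randomDNA(sample(10:300, 1L)))
  for (s in seqs) {
    tr <- tokenizeTrinucleotides(s)
    m1 <- sgtMatrix(tr, 1)
    expect_true(all(m1 >= 0))
    expect_lte(max(m1), exp(-1))
    # every nonzero entry strictly decreases as kappa increases
    m2 <- sgtMatrix(tr, 2)
    nz <- m1 > 0
    expect_true(all(m2[nz] < m1[nz]))
    expect_identical(m2[!nz], m1[!nz])
    # bit-identical on repeat
    expect_identical(m1, sgtMatrix(tr, 1))
  }
})

test_that("sequences with <= 1 token give the all-zero matrix", {
  for (s in c("", "AC", "ACG", "NNNNNNN", "ANCNGN"))
    expect_true(all(sgtMatrix(s, 1) == 0))
})

test_that("batch encoding preserves order, ids and per-sequence results", {
  pm <- encodeSGT(c(x = "ATTCATAACTT", y = "ACGTACGTACGT"), kappa = 1)
  expect_s4_class(pm, "PatternMatrixSet")
  expect_identical(dim(pm@data), c(64L, 64L, 2L))
  expect_identical(pm@ids, c("x", "y"))
  expect_equal(pm[["x"]], sgtMatrix("ATTCATAACTT", 1))

  # single-sequence batch equals the direct call
  one <- encodeSGT(c(z = "ATTC"), kappa = 1)
  expect_equal(one[[1L]], sgtMatrix("ATTC", 1))

  # low-information sequences: zero matrix plus a warning naming the id
  expect_warning(pm2 <- encodeSGT(c(ok = "ACGTACGT", bad = "AANAA")),
                 "bad")
  expect_true(all(pm2[["bad"]] == 0))

  # tokenizer errors carry the sequence id
  expect_error(suppressWarnings(encodeSGT(c(broken = "ACGTX"))), "broken")
})

test_that("FASTA input round-trips through the encoder", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">frag1 some description", "ATTCATAA", "CTT",
               ">frag2", "ACGTACGT"), fa)
  pm <- encodeSGT(fa, kappa = 1)
  expect_identical(pm@ids, c("frag1", "frag2"))
  expect_equal(pm[["frag1"]], sgtMatrix("ATTCATAACTT", 1))
})
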