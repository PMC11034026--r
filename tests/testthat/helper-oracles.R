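# Independent oracles and small fixture builders used across the suite.

# naive O(T^2) evaluation of the pair-weight definition: enumerate every
# ordered occurrence pair (l < m) and average exp(-kappa * (m - l))
sgtOracle <- function(track, kappa) {
  W <- matrix(0, 64, 64)
  Cn <- matrix(0, 64, 64)
  s <- track@symbols + 1L
  p <- track@positions
  T_ <- length(s)
  if (T_ >= 2L) {
    for (a in seq_len(T_ - 1L)) {
      for (b in (a + 1L):T_) {
        W[s[a], s[b]] <- W[s[a], s[b]] + exp(-kappa * (p[b] - p[a]))
        Cn[s[a], s[b]] <- Cn[s[a], s[b]] + 1
      }
    }
  }
  ifelse(Cn > 0, W / pmax(Cn, 1), 0)
}

# the same all-pairs enumeration, vectorised so the oracle stays usable
# on sequences with thousands of tokens
sgtOracleVec <- function(track, kappa) {
  s <- track@symbols + 1L
  p <- track@positions
  T_ <- length(s)
  M <- matrix(0, 64, 64)
  if (T_ >= 2L) {
    ut <- which(upper.tri(matrix(0, T_, T_)), arr.ind = TRUE)
    w <- exp(-kappa * (p[ut[, 2L]] - p[ut[, 1L]]))
    key <- (s[ut[, 1L]] - 1L) * 64L + s[ut[, 2L]]
    sums <- rowsum(w, key)
    cnts <- rowsum(rep(1, length(w)), key)
    k <- as.integer(rownames(sums))
    M[cbind((k - 1L) %/% 64L + 1L, (k - 1L) %% 64L + 1L)] <-
      sums[, 1L] / cnts[, 1L]
  }
  M
}

# brute-force Mann-Whitney AUC: count positive > negative pairs, ties 1/2
aucOracle <- function(labels, scores, positive = "prokaryotic") {
  pos <- if (is.logical(labels)) labels else as.character(labels) == positive
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

randomDNA <- function(n, withN = FALSE) {
  alpha <- c("A", "C", "G", "T", if (withN) "N")
  prob <- if (withN) c(rep(0.24, 4), 0.04) else rep(0.25, 4)
  paste(sample(alpha, n, replace = TRUE, prob = prob), collapse = "")
}

# small two-class fragment dataset + matching tiny configuration, for
# tests that need an end-to-end train/predict cycle in seconds
tinyDataset <- function(nGenomes = 10L, nFragments = 30L, group = "A",
                        seed = 11L, divergence = 0.4) {
  src <- defaultVirusSources(divergence = divergence)
  buildDataset(src, nGenomes = nGenomes, genomeLength = 2500L,
               groups = group, nFragments = nFragments, kFolds = 5L,
               seed = seed)
}

tinyConfig <- function(...) {
  classifierConfig(nFilters = 8L, denseUnits = 16L, batchSize = 8L,
                   epochs = 5L, seed = 5L, ...)
}
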