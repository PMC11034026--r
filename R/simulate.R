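# Synthetic virome: Markov-chain genome sources, uniform fragmenting into
# length groups A-D, sequencing-error injection, and leakage-free
# genome-level fold assignment.  Emulates a MetaSim-style protocol
# ("exact" preset, uniform fragment lengths) without the external tool.

.contextWords <- function(order) {
  if (order == 0L) return("")
  out <- .BASES
  for (i in seq_len(order - 1L))
    out <- as.vector(t(outer(out, .BASES, paste0)))
  sort(out)
}

#' Create a Markov genome source
#'
#' @param label class label carried by fragments simulated from this
#'   source.
#' @param transitions 4^order x 4 row-stochastic matrix (rows: contexts
#'   in lexicographic order; columns A, C, G, T).  If `NULL`, rows are
#'   drawn from a symmetric Dirichlet(`alpha`) using the current RNG
#'   state.
#' @param order Markov order (default 2).
#' @param alpha Dirichlet concentration for random tables.
#' @return a [MarkovSource-class].
#' @export
markovSource <- function(label, transitions = NULL, order = 2L, alpha = 5) {
  order <- as.integer(order)
  if (is.null(transitions)) {
    g <- matrix(rgamma(4L^order * 4L, shape = alpha), ncol = 4L)
    transitions <- g / rowSums(g)
  }
  dimnames(transitions) <- list(.contextWords(order), .BASES)
  new("MarkovSource", label = as.character(label), order = order,
      transitions = transitions)
}

#' Default two-class virus sources
#'
#' The study's synthetic stand-in for real phage and eukaryotic-virus
#' genomes: two order-2 Markov sources derived from one common base
#' table, each perturbed independently on the log scale
#' (`p' proportional to p * exp(divergence * z)`, `z ~ N(0,1)` per
#' context/base).  `divergence` controls how far apart the two
#' compositional signals sit and hence task difficulty; the default 0.4
#' gives clearly distinct but overlapping trinucleotide usage, in the
#' spirit of the large codon/3-mer usage differences between viruses of
#' prokaryotic and eukaryotic hosts that composition-based classifiers
#' exploit.
#'
#' @param divergence standard deviation of the per-entry log-scale
#'   perturbation (default 0.4).
#' @param seed integer seed making the tables reproducible.
#' @param labels two class labels, positive class first.
#' @return list of two [MarkovSource-class] objects.
#' @export
defaultVirusSources <- function(divergence = 0.4, seed = 101L,
                                labels = c("prokaryotic", "eukaryotic")) {
  stopifnot(length(labels) == 2L, divergence >= 0)
  .withSeed(seed, {
    g <- matrix(rgamma(16L * 4L, shape = 5), ncol = 4L)
    base <- g / rowSums(g)
    perturb <- function() {
      w <- base * exp(divergence * matrix(rnorm(64), ncol = 4L))
      w / rowSums(w)
    }
    list(markovSource(labels[1], perturb()),
         markovSource(labels[2], perturb()))
  })
}

#' Stationary distributions of a Markov source
#'
#' Stationary distribution over the 4^order contexts (by power
#' iteration on the context chain) and the implied stationary
#' trinucleotide frequencies (for order <= 2).
#'
#' @param source a [MarkovSource-class].
#' @return list with `context` (named vector over contexts) and, for
#'   order 2, `trinucleotide` (named vector over the 64 trinucleotides,
#'   `pi(abc) = pi_ctx(ab) P(c|ab)`).
#' @export
stationaryDistribution <- function(source) {
  stopifnot(is(source, "MarkovSource"))
  tr <- source@transitions
  k <- source@order
  ctx <- rownames(tr)
  if (k == 0L) {
    p <- tr[1, ]
    # independence: p(a)p(b)p(c); kronecker keeps the first base slowest,
    # matching lexicographic trinucleotide order
    return(list(context = p,
                trinucleotide = setNames(kronecker(p, kronecker(p, p)),
                                         .TRINUCLEOTIDES)))
  }
  nctx <- length(ctx)
  # context chain: (x1..xk) -> (x2..xk, b) with prob P(b | x1..xk)
  M <- matrix(0, nctx, nctx)
  for (i in seq_len(nctx)) {
    tgt <- match(paste0(substr(ctx[i], 2L, k), .BASES), ctx)
    for (b in 1:4) M[i, tgt[b]] <- M[i, tgt[b]] + tr[i, b]
  }
  p <- rep(1 / nctx, nctx)
  for (it in seq_len(5000L)) {
    q <- drop(p %*% M)
    if (max(abs(q - p)) < 1e-14) { p <- q; break }
    p <- q
  }
  names(p) <- ctx
  out <- list(context = p)
  if (k == 2L) {
    tri <- as.vector(vapply(seq_len(nctx), function(i) p[i] * tr[i, ],
                            numeric(4L)))
    # vapply gives, per context ab, the 4 values abc ordered by c;
    # contexts are lexicographic, so concatenation is lexicographic abc
    out$trinucleotide <- setNames(tri, .TRINUCLEOTIDES)
  }
  out
}

#' Sample a genome from a Markov source
#'
#' Draws the first `order` bases from the stationary context
#' distribution, then extends base by base from the transition table.
#' Uses the current RNG state; wrap in `set.seed()` (or use
#' [buildDataset()]) for reproducibility.
#'
#' @param source a [MarkovSource-class].
#' @param length genome length in bases (> order).
#' @param id sequence identifier.
#' @return a length-1 named character vector (the genome).
#' @export
sampleGenome <- function(source, length, id = "genome1") {
  stopifnot(is(source, "MarkovSource"))
  k <- source@order
  if (length <= k) stop("'length' must exceed the Markov order (", k, ")")
  tr <- source@transitions
  cum <- t(apply(tr, 1L, cumsum))
  ctxNames <- rownames(tr)
  if (k == 0L) {
    draws <- findInterval(runif(length), c(0, cumsum(tr[1, ])),
                          rightmost.closed = TRUE)
    return(setNames(paste(.BASES[pmin(draws, 4L)], collapse = ""), id))
  }
  st <- stationaryDistribution(source)$context
  start <- ctxNames[findInterval(runif(1), c(0, cumsum(st)),
                                 rightmost.closed = TRUE)]
  out <- integer(length)
  out[seq_len(k)] <- match(strsplit(start, "")[[1]], .BASES)
  u <- runif(length - k)
  # context index updates by base-4 shift: idx' = 4*(idx mod 4^(k-1)) + b
  idx <- sum((out[seq_len(k)] - 1L) * 4L^((k - 1L):0)) + 1L
  mod <- 4L^(k - 1L)
  for (i in (k + 1L):length) {
    row <- cum[idx, ]
    b <- 1L + (u[i - k] >= row[1L]) + (u[i - k] >= row[2L]) +
      (u[i - k] >= row[3L])
    out[i] <- b
    idx <- 4L * ((idx - 1L) %% mod) + b
  }
  setNames(paste(.BASES[out], collapse = ""), id)
}

.newFragmentSet <- function(seqs, label, genome, group, fold,
                            errorsInjected = FALSE, manifest = list()) {
  s <- DNAStringSet(seqs)
  mcols(s) <- DataFrame(label = label, genome = genome, group = group,
                        fold = as.integer(fold))
  metadata(s)$manifest <- manifest
  new("LabeledFragmentSet", sequences = s,
      errorsInjected = errorsInjected)
}

#' Accessors for LabeledFragmentSet
#'
#' `sequences()` returns the underlying `DNAStringSet` (mcols carry
#' label/genome/group/fold); `fragmentInfo()` returns the per-fragment
#' annotation as a data.frame with an added `width` column.
#'
#' @param x a [LabeledFragmentSet-class].
#' @return see description.
#' @export
sequences <- function(x) {
  stopifnot(is(x, "LabeledFragmentSet"))
  x@sequences
}

#' @rdname sequences
#' @export
fragmentInfo <- function(x) {
  stopifnot(is(x, "LabeledFragmentSet"))
  df <- as.data.frame(mcols(x@sequences))
  df$id <- names(x@sequences)
  df$width <- width(x@sequences)
  df
}

#' @describeIn sequences number of fragments.
#' @export
setMethod("length", "LabeledFragmentSet", function(x) length(x@sequences))

setMethod("show", "LabeledFragmentSet", function(object) {
  info <- fragmentInfo(object)
  cat("LabeledFragmentSet:", nrow(info), "fragments\n")
  if (nrow(info)) {
    cat("  classes:", paste(sprintf("%s (%d)", names(table(info$label)),
                                    table(info$label)), collapse = ", "), "\n")
    cat("  groups:", paste(sort(unique(info$group)), collapse = ", "),
        "; folds:", paste(sort(unique(info$fold)), collapse = ", "), "\n")
    if (isTRUE(object@errorsInjected)) cat("  sequencing errors injected\n")
  }
})

#' Fragment genomes uniformly within a length group
#'
#' Fragment lengths are drawn uniformly (integer-inclusive) over the
#' group's bounds and start positions uniformly over valid offsets,
#' emulating a MetaSim "exact"/uniform protocol.  Genomes shorter than
#' the group's upper bound are skipped with a warning.
#'
#' @param genomes named character vector of genome sequences.
#' @param labels class label per genome (recycled if length 1).
#' @param group length group, one of `"A".."D"` (see [lengthGroups]).
#' @param nPerGenome fragments to draw per genome (recycled if length 1).
#' @param folds optional fold id per genome (propagated to fragments;
#'   NA when absent).
#' @return a [LabeledFragmentSet-class].
#' @export
fragmentGenomes <- function(genomes, labels, group = "D", nPerGenome = 10L,
                            folds = NA_integer_) {
  stopifnot(group %in% names(lengthGroups))
  bounds <- lengthGroups[[group]]
  labels <- rep_len(labels, length(genomes))
  nPerGenome <- rep_len(as.integer(nPerGenome), length(genomes))
  folds <- rep_len(as.integer(folds), length(genomes))
  gid <- names(genomes)
  if (is.null(gid)) gid <- paste0("genome", seq_along(genomes))
  frs <- character(); frLab <- character(); frGen <- character()
  frFold <- integer()
  skipped <- character()
  for (g in seq_along(genomes)) {
    glen <- nchar(genomes[[g]])
    if (glen < bounds[2]) { skipped <- c(skipped, gid[g]); next }
    n <- nPerGenome[g]
    if (n == 0L) next
    lens <- sample.int(bounds[2] - bounds[1] + 1L, n, replace = TRUE) +
      bounds[1] - 1L
    starts <- vapply(lens, function(l)
      sample.int(glen - l + 1L, 1L), integer(1))
    frs <- c(frs, substring(genomes[[g]], starts, starts + lens - 1L))
    frLab <- c(frLab, rep(labels[g], n))
    frGen <- c(frGen, rep(gid[g], n))
    frFold <- c(frFold, rep(folds[g], n))
  }
  if (length(skipped))
    warning("genome(s) shorter than the group ", group,
            " upper bound skipped: ", paste(skipped, collapse = ", "))
  names(frs) <- sprintf("%s_%s%04d", frGen, group, unlist(lapply(
    rle(frGen)$lengths, seq_len)))
  .newFragmentSet(frs, frLab, frGen, rep(group, length(frs)), frFold)
}

#' Inject sequencing errors
#'
#' Each base is independently substituted (to a uniformly chosen
#' different base) with probability `subRate`; independently, each
#' position receives one indel event with probability `indelRate`, an
#' insertion (random base appended after the position) or a deletion
#' with equal probability.  Ids gain an error-annotation suffix.
#'
#' @param x a single sequence (character), a named character vector, a
#'   `DNAStringSet`, or a [LabeledFragmentSet-class].
#' @param subRate substitution probability per base, in \[0, 1).
#' @param indelRate indel probability per base, in \[0, 1).
#' @return object of the same flavour as `x` with mutated sequences.
#' @export
injectErrors <- function(x, subRate = 0, indelRate = 0) {
  if (!(subRate >= 0 && subRate < 1 && indelRate >= 0 && indelRate < 1))
    stop("error rates must lie in [0, 1)")
  mutateOne <- function(s) {
    if (subRate == 0 && indelRate == 0) return(s)
    b <- strsplit(s, "")[[1]]
    n <- length(b)
    sub <- runif(n) < subRate
    if (any(sub)) {
      cur <- match(b[sub], .BASES)
      shift <- sample.int(3L, sum(sub), replace = TRUE)
      # valid for ACGT positions; degenerate bases are substituted
      # uniformly over ACGT
      b[sub] <- ifelse(is.na(cur), .BASES[shift + 1L],
                       .BASES[((cur - 1L + shift) %% 4L) + 1L])
    }
    ind <- runif(n) < indelRate
    if (any(ind)) {
      isIns <- runif(sum(ind)) < 0.5
      w <- which(ind)
      b[w[!isIns]] <- ""
      wIns <- w[isIns]
      b[wIns] <- paste0(b[wIns],
                        sample(.BASES, length(wIns), replace = TRUE))
    }
    paste(b, collapse = "")
  }
  suffix <- sprintf(":sub%g:indel%g", subRate, indelRate)
  if (is(x, "LabeledFragmentSet")) {
    s <- x@sequences
    mut <- vapply(as.character(s), mutateOne, character(1),
                  USE.NAMES = FALSE)
    out <- DNAStringSet(mut)
    names(out) <- paste0(names(s), suffix)
    mcols(out) <- mcols(s)
    metadata(out) <- metadata(s)
    return(new("LabeledFragmentSet", sequences = out,
               errorsInjected = TRUE))
  }
  if (is(x, "DNAStringSet")) {
    mut <- vapply(as.character(x), mutateOne, character(1),
                  USE.NAMES = FALSE)
    out <- DNAStringSet(mut)
    names(out) <- paste0(if (is.null(names(x)))
      paste0("seq", seq_along(x)) else names(x), suffix)
    return(out)
  }
  stopifnot(is.character(x))
  out <- vapply(x, mutateOne, character(1), USE.NAMES = FALSE)
  names(out) <- paste0(if (is.null(names(x))) paste0("seq", seq_along(x))
                       else names(x), suffix)
  out
}

#' Build a labelled synthetic fragment dataset
#'
#' Simulates `nGenomes` genomes per source, assigns genomes (not
#' fragments) to `kFolds` folds so that no genome's fragments span a
#' train/test boundary, and fragments every genome into the requested
#' length groups.  Per class and group, exactly `nFragments` fragments
#' are produced (distributed as evenly as possible over genomes).  The
#' generation parameters are stored as a manifest in the metadata.
#'
#' @param sources list of [MarkovSource-class] with distinct labels
#'   (>= 2).
#' @param nGenomes genomes per class.
#' @param genomeLength genome length in bases.
#' @param groups character vector of length groups to simulate.
#' @param nFragments fragments per class per group.
#' @param kFolds number of folds (<= nGenomes).
#' @param seed integer seed; the whole dataset is a deterministic
#'   function of it.
#' @return a [LabeledFragmentSet-class].
#' @export
buildDataset <- function(sources, nGenomes = 100L, genomeLength = 5000L,
                         groups = "D", nFragments = 1000L, kFolds = 5L,
                         seed = 1L) {
  labs <- vapply(sources, function(s) s@label, character(1))
  if (length(sources) < 2L || anyDuplicated(labs))
    stop("'sources' must hold >= 2 sources with distinct labels")
  if (kFolds > nGenomes)
    stop("'kFolds' (", kFolds, ") exceeds genomes per class (", nGenomes, ")")
  stopifnot(all(groups %in% names(lengthGroups)))
  maxBound <- max(vapply(lengthGroups[groups], max, integer(1)))
  if (genomeLength < maxBound)
    stop("'genomeLength' must reach the largest group bound (", maxBound, ")")
  # near-equal split of nFragments over nGenomes, exact total
  perGenome <- diff(floor(seq(0, nFragments, length.out = nGenomes + 1L)))
  parts <- .withSeed(seed, {
    out <- list()
    for (src in sources) {
      genomes <- vapply(seq_len(nGenomes), function(i)
        sampleGenome(src, genomeLength,
                     sprintf("%s_g%03d", src@label, i)),
        character(1))
      names(genomes) <- sprintf("%s_g%03d", src@label, seq_len(nGenomes))
      folds <- sample(rep_len(0:(kFolds - 1L), nGenomes))
      counts <- sample(perGenome)  # which genome gets the remainder varies
      for (grp in groups)
        out[[length(out) + 1L]] <-
          fragmentGenomes(genomes, src@label, grp, counts, folds)
    }
    out
  })
  seqs <- do.call(c, lapply(parts, function(p) p@sequences))
  manifest <- list(nGenomes = nGenomes, genomeLength = genomeLength,
                   groups = groups, nFragments = nFragments,
                   kFolds = kFolds, seed = seed, labels = labs,
                   created = "buildDataset")
  metadata(seqs)$manifest <- manifest
  new("LabeledFragmentSet", sequences = seqs, errorsInjected = FALSE)
}

#' Split a dataset by fold
#'
#' Genome-level train/test split: fragments whose fold is in
#' `testFolds` form the test set, the rest the training set.
#'
#' @param dataset a [LabeledFragmentSet-class] with assigned folds.
#' @param testFolds fold id(s) held out.
#' @return list with elements `train` and `test`
#'   ([LabeledFragmentSet-class]).
#' @export
splitByFold <- function(dataset, testFolds = 0L) {
  info <- fragmentInfo(dataset)
  if (anyNA(info$fold)) stop("dataset has unassigned folds")
  sel <- info$fold %in% testFolds
  sub <- function(keep) new("LabeledFragmentSet",
                            sequences = dataset@sequences[keep],
                            errorsInjected = dataset@errorsInjected)
  list(train = sub(!sel), test = sub(sel))
}

#' Write a dataset as FASTA plus a TSV label manifest
#'
#' Deterministic output: the same dataset writes byte-identical files.
#' The manifest columns are id, label, genome, group, fold.
#'
#' @param dataset a [LabeledFragmentSet-class].
#' @param fastaPath output FASTA file.
#' @param manifestPath output TSV file.
#' @return invisibly, the two paths.
#' @export
writeDataset <- function(dataset, fastaPath, manifestPath) {
  writeXStringSet(dataset@sequences, fastaPath)
  info <- fragmentInfo(dataset)
  write.table(info[, c("id", "label", "genome", "group", "fold")],
              manifestPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fastaPath, manifest = manifestPath))
}
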