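# S4 classes for the encoder, classifier, simulator and pipeline.

#' Fragment length groups
#'
#' Inclusive base-pair bounds of the four simulated contig length groups:
#' A (100-400), B (400-800), C (800-1200), D (1200-1800).
#'
#' @format A named list of length-2 integer vectors.
#' @export
lengthGroups <- list(
  A = c(100L, 400L),
  B = c(400L, 800L),
  C = c(800L, 1200L),
  D = c(1200L, 1800L)
)

# lexicographic A<C<G<T: symbol index = 16*b1 + 4*b2 + b3
.BASES <- c("A", "C", "G", "T")
.TRINUCLEOTIDES <- paste0(rep(.BASES, each = 16L),
                          rep(rep(.BASES, each = 4L), 4L),
                          rep(.BASES, 16L))

#' TrinucleotideTrack
#'
#' The ordered trinucleotide tokens of one DNA sequence: for every length-3
#' window made only of A/C/G/T, its lexicographic symbol index (AAA = 0,
#' ..., TTT = 63) and its 1-based start offset in the original sequence.
#' Windows containing degenerate IUPAC letters are skipped; surviving
#' tokens keep their original positions, so genomic spacing is preserved.
#'
#' @slot symbols integer vector of symbol indices in 0..63.
#' @slot positions integer vector of 1-based start offsets, strictly
#'   increasing, parallel to `symbols`.
#' @slot sourceLength length of the source sequence in bases.
#' @export
setClass("TrinucleotideTrack",
  representation(symbols = "integer", positions = "integer",
                 sourceLength = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@symbols) != length(object@positions))
      msg <- c(msg, "'symbols' and 'positions' must be parallel")
    if (length(object@symbols) &&
        (min(object@symbols) < 0L || max(object@symbols) > 63L))
      msg <- c(msg, "symbol indices must lie in 0..63")
    if (length(object@positions) > 1L && any(diff(object@positions) <= 0L))
      msg <- c(msg, "positions must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' PatternMatrixSet
#'
#' A batch of 64 x 64 sequence-graph-transform pattern matrices, one per
#' input sequence, together with the decay parameter kappa they were
#' encoded at.  Entry (u, v) of a matrix is the mean exponentially decayed
#' distance weight over all ordered occurrence pairs of trinucleotide u
#' before trinucleotide v; all entries lie in [0, exp(-kappa)].
#'
#' @slot data numeric array of dimension 64 x 64 x n.
#' @slot kappa positive decay rate per base of separation.
#' @slot ids character vector of sequence identifiers, length n.
#' @export
setClass("PatternMatrixSet",
  representation(data = "array", kappa = "numeric", ids = "character"),
  validity = function(object) {
    d <- dim(object@data)
    msg <- character()
    if (length(d) != 3L || d[1] != 64L || d[2] != 64L)
      msg <- c(msg, "'data' must be a 64 x 64 x n array")
    else if (d[3] != length(object@ids))
      msg <- c(msg, "'ids' must have one entry per matrix")
    if (length(object@kappa) != 1L || !is.finite(object@kappa) ||
        object@kappa <= 0)
      msg <- c(msg, "'kappa' must be a single positive number")
    else if (length(d) == 3L && d[3] > 0L) {
      if (min(object@data) < 0)
        msg <- c(msg, "pattern weights must be non-negative")
      if (max(object@data) > exp(-object@kappa) + 1e-12)
        msg <- c(msg, "pattern weights must not exceed exp(-kappa)")
    }
    if (length(msg)) msg else TRUE
  })

#' ClassifierConfig
#'
#' Architecture and optimisation hyper-parameters of the pattern-matrix
#' CNN.  The defaults reproduce the reference configuration: 128 filters
#' of size 7 x 7 with "same" padding in both convolution layers, 2 x 2 max
#' pooling with stride 2, dropout 0.32 after each pooling layer, a 64-unit
#' ReLU dense layer, a softmax output over 2 classes, Adam with learning
#' rate 0.0005, batch size 16, 30 epochs.
#'
#' @slot nFilters number of convolution filters F in each conv layer.
#' @slot kernel integer length-2 kernel size (k1, k2).
#' @slot poolSize pooling window side S1.
#' @slot poolStride pooling stride S2.
#' @slot dropout drop probability P in [0, 1).
#' @slot denseUnits units R of the first dense layer.
#' @slot nClasses number C of output classes (>= 2).
#' @slot learningRate Adam learning rate.
#' @slot batchSize mini-batch size.
#' @slot epochs training epochs.
#' @slot seed integer seed controlling initialisation, shuffling, dropout.
#' @slot kappa SGT decay rate the model expects its inputs encoded at.
#' @slot inputSide side length L of the input matrix (64 for
#'   trinucleotides).
#' @export
setClass("ClassifierConfig",
  representation(nFilters = "integer", kernel = "integer",
                 poolSize = "integer", poolStride = "integer",
                 dropout = "numeric", denseUnits = "integer",
                 nClasses = "integer", learningRate = "numeric",
                 batchSize = "integer", epochs = "integer",
                 seed = "integer", kappa = "numeric",
                 inputSide = "integer"),
  validity = function(object) {
    chkPos <- function(name) {
      v <- slot(object, name)
      if (length(v) != 1L || is.na(v) || v <= 0)
        sprintf("'%s' must be a single positive value", name)
      else character()
    }
    msg <- unlist(lapply(c("nFilters", "poolSize", "poolStride",
                           "denseUnits", "learningRate", "batchSize",
                           "epochs", "kappa", "inputSide"), chkPos))
    if (length(object@kernel) != 2L || any(object@kernel < 1L))
      msg <- c(msg, "'kernel' must be two positive integers")
    if (length(object@dropout) != 1L || object@dropout < 0 ||
        object@dropout >= 1)
      msg <- c(msg, "'dropout' must lie in [0, 1)")
    if (length(object@nClasses) != 1L || object@nClasses < 2L)
      msg <- c(msg, "'nClasses' must be >= 2")
    if (length(msg)) msg else TRUE
  })

#' SGTClassifier
#'
#' A (possibly trained) pattern-matrix CNN: its configuration, the fitted
#' parameter set, the ordered class labels (first class = prokaryotic
#' virus, the positive class throughout the package), and the per-epoch
#' training history.
#'
#' @slot config a [ClassifierConfig-class].
#' @slot params named list of weight matrices and bias vectors
#'   (W1, b1, W2, b2, W3, b3, W4, b4).
#' @slot classNames ordered class labels, length `nClasses`.
#' @slot history data.frame with one row per completed training epoch.
#' @slot trained logical scalar.
#' @export
setClass("SGTClassifier",
  representation(config = "ClassifierConfig", params = "list",
                 classNames = "character", history = "data.frame",
                 trained = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@classNames) != object@config@nClasses)
      msg <- c(msg, "'classNames' must match nClasses")
    need <- c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")
    if (!all(need %in% names(object@params)))
      msg <- c(msg, "incomplete parameter set")
    if (length(msg)) msg else TRUE
  })

#' MarkovSource
#'
#' A synthetic genome source: an order-k Markov chain over {A, C, G, T}
#' standing in for the compositional signal of a real virus clade.  Rows
#' of `transitions` are contexts (all 4^order words, lexicographic), and
#' each row is a probability vector over the next base.
#'
#' @slot label class label fragments from this source will carry.
#' @slot order Markov order (context length in bases).
#' @slot transitions 4^order x 4 row-stochastic matrix.
#' @export
setClass("MarkovSource",
  representation(label = "character", order = "integer",
                 transitions = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@label) != 1L || !nzchar(object@label))
      msg <- c(msg, "'label' must be a non-empty string")
    tr <- object@transitions
    if (nrow(tr) != 4L^object@order || ncol(tr) != 4L)
      msg <- c(msg, "'transitions' must be 4^order x 4")
    else {
      if (any(tr < 0)) msg <- c(msg, "transition probabilities must be >= 0")
      if (any(abs(rowSums(tr) - 1) > 1e-9))
        msg <- c(msg, "transition rows must sum to 1 (tolerance 1e-9)")
    }
    if (length(msg)) msg else TRUE
  })

#' LabeledFragmentSet
#'
#' Simulated class-labelled sequence fragments.  Sequences live in a
#' [Biostrings::DNAStringSet] whose `mcols` carry, per fragment: `label`
#' (class), `genome` (source genome id), `group` (length group A-D) and
#' `fold` (cross-validation fold, 0-based; NA before assignment).  All
#' fragments of one source genome share a fold, so train/test splits are
#' leakage-free at the genome level.  Generation parameters are kept in
#' `metadata(sequences(x))$manifest`.
#'
#' @slot sequences DNAStringSet with mcols label/genome/group/fold.
#' @slot errorsInjected TRUE once sequencing errors were injected (indels
#'   may then push lengths outside the nominal group bounds).
#' @export
setClass("LabeledFragmentSet",
  representation(sequences = "DNAStringSet", errorsInjected = "logical"),
  validity = function(object) {
    msg <- character()
    mc <- mcols(object@sequences)
    need <- c("label", "genome", "group", "fold")
    if (!all(need %in% colnames(mc)))
      return(paste("mcols must contain:", paste(need, collapse = ", ")))
    if (length(object@sequences)) {
      bad <- !(mc$group %in% names(lengthGroups))
      if (any(bad))
        msg <- c(msg, "group tags must be one of A, B, C, D")
      else if (!isTRUE(object@errorsInjected)) {
        w <- width(object@sequences)
        lo <- vapply(lengthGroups[mc$group], `[`, integer(1), 1L)
        hi <- vapply(lengthGroups[mc$group], `[`, integer(1), 2L)
        if (any(w < lo | w > hi))
          msg <- c(msg, "fragment lengths must lie within their group bounds")
      }
      # genome-level fold integrity
      fo <- split(mc$fold, mc$genome)
      if (any(vapply(fo, function(f) length(unique(f)) > 1L, logical(1))))
        msg <- c(msg, "all fragments of a genome must share a fold")
    }
    if (length(msg)) msg else TRUE
  })

#' ScoreTable
#'
#' Per-input class likelihoods produced by the inference pipeline: one row
#' per FASTA record, in input order, with the length-weighted aggregate of
#' the per-window softmax scores, the argmax label, and flags
#' (`low_information` for records without usable trinucleotides, `tie`,
#' `nonviral` after filtering).
#'
#' @slot scores a [S4Vectors::DataFrame] with columns seq_id, length,
#'   n_windows, one score column per class, predicted_label, flags.
#' @slot classNames ordered class labels (first = prokaryotic virus).
#' @slot kappa SGT decay rate used for encoding.
#' @export
setClass("ScoreTable",
  representation(scores = "DataFrame", classNames = "character",
                 kappa = "numeric"))
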