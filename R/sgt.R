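# Sequence graph transform: trinucleotide tokenisation and the 64 x 64
# pair-weight pattern matrix.

#' Tokenize a DNA sequence into overlapping trinucleotides
#'
#' Slides a 3-base window over the sequence and keeps every window made
#' purely of A/C/G/T (case-insensitive), recording its lexicographic
#' symbol index (AAA = 0, ..., TTT = 63) and 1-based start position.
#' Windows touching a degenerate IUPAC base (N, R, Y, ...) are skipped,
#' but surviving windows keep their original offsets, so the genomic
#' spacing between tokens is preserved.  Characters outside the IUPAC
#' nucleotide alphabet are an error (reported with their position).
#'
#' @param seq a single DNA string (or anything coercible via
#'   `as.character`, e.g. one element of a `DNAStringSet`).
#' @return a [TrinucleotideTrack-class].
#' @examples
#' tok <- tokenizeTrinucleotides("ATTCATAACTT")
#' trinucleotideNames()[tok@symbols + 1]
#' @export
tokenizeTrinucleotides <- function(seq) {
  seq <- as.character(seq)
  if (length(seq) != 1L)
    stop("'seq' must be a single sequence")
  r <- .tokenize_cpp(seq)
  new("TrinucleotideTrack",
      symbols = as.integer(r$symbols),
      positions = as.integer(r$positions),
      sourceLength = as.integer(r$sourceLength))
}

#' Trinucleotide alphabet
#'
#' The 64 trinucleotides in lexicographic order (A < C < G < T), i.e. the
#' row/column labels of every pattern matrix.  This ordering is frozen:
#' trained classifier weights depend on it.
#'
#' @return character vector of length 64.
#' @export
trinucleotideNames <- function() .TRINUCLEOTIDES

#' Sequence-graph-transform pattern matrix of one sequence
#'
#' For each ordered pair of trinucleotides (u, v), the weight is the mean
#' of `exp(-kappa * (m - l))` over all occurrence pairs with u starting at
#' position l, v at position m, and l < m (strict order; distances are in
#' bases of the original sequence, so adjacent overlapping trinucleotides
#' are 1 apart).  Pairs that never occur give 0.  Every entry therefore
#' lies in `[0, exp(-kappa)]`.
#'
#' @param track a [TrinucleotideTrack-class], or a single DNA string which
#'   is tokenized first.
#' @param kappa positive decay rate per base of separation (default 1).
#' @return a 64 x 64 numeric matrix with trinucleotide dimnames; rows are
#'   the earlier symbol u, columns the later symbol v.
#' @examples
#' m <- sgtMatrix("ATTC", kappa = 1)
#' m["ATT", "TTC"]   # exp(-1): one pair at distance 1
#' @export
sgtMatrix <- function(track, kappa = 1) {
  if (!(is.numeric(kappa) && length(kappa) == 1L && is.finite(kappa) &&
        kappa > 0))
    stop("'kappa' must be a single positive number")
  if (!is(track, "TrinucleotideTrack"))
    track <- tokenizeTrinucleotides(track)
  m <- .sgt_matrix_cpp(track@symbols, track@positions, kappa)
  dimnames(m) <- list(.TRINUCLEOTIDES, .TRINUCLEOTIDES)
  m
}

#' Encode sequences as a batch of pattern matrices
#'
#' Applies [sgtMatrix()] to every input sequence, preserving order and
#' ids.  Sequences yielding fewer than two usable trinucleotide tokens
#' carry no pair information and produce all-zero matrices; a warning
#' lists their ids.
#'
#' @param x sequences: a `DNAStringSet`, a character vector of sequences
#'   (optionally named), a [LabeledFragmentSet-class], or the path of a
#'   FASTA file.
#' @param kappa positive decay rate (default 1).
#' @return a [PatternMatrixSet-class].
#' @examples
#' pm <- encodeSGT(c(a = "ATTCATAACTT", b = "ACGTACGT"))
#' dim(pm@data)
#' @export
setGeneric("encodeSGT", function(x, kappa = 1) standardGeneric("encodeSGT"))

.encodeCharacter <- function(x, kappa) {
  n <- length(x)
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  arr <- array(0, dim = c(64L, 64L, n))
  lowInfo <- character()
  for (i in seq_len(n)) {
    tr <- tryCatch(tokenizeTrinucleotides(x[[i]]), error = function(e)
      stop("sequence '", ids[i], "': ", conditionMessage(e), call. = FALSE))
    if (length(tr@symbols) < 2L) lowInfo <- c(lowInfo, ids[i])
    else arr[, , i] <- .sgt_matrix_cpp(tr@symbols, tr@positions, kappa)
  }
  if (length(lowInfo))
    warning("sequence(s) with < 2 usable trinucleotides encoded as ",
            "all-zero matrices: ", paste(lowInfo, collapse = ", "))
  new("PatternMatrixSet", data = arr, kappa = kappa, ids = ids)
}

#' @rdname encodeSGT
setMethod("encodeSGT", "character", function(x, kappa = 1) {
  if (length(x) == 1L && !grepl("^[ACGTUNRYSWKMBDHVacgtunryswkmbdhv]*$", x) &&
      file.exists(x))
    x <- .asDNAStringSet(x)
  if (is(x, "DNAStringSet")) return(encodeSGT(x, kappa))
  .encodeCharacter(x, kappa)
})

#' @rdname encodeSGT
setMethod("encodeSGT", "DNAStringSet", function(x, kappa = 1) {
  .encodeCharacter(setNames(as.character(x), names(.asDNAStringSet(x))),
                   kappa)
})

#' @rdname encodeSGT
setMethod("encodeSGT", "LabeledFragmentSet", function(x, kappa = 1) {
  encodeSGT(sequences(x), kappa)
})

#' @describeIn PatternMatrixSet-class number of matrices in the set.
#' @param x a `PatternMatrixSet`.
#' @export
setMethod("length", "PatternMatrixSet", function(x) length(x@ids))

#' @describeIn PatternMatrixSet-class extract one matrix (with dimnames)
#'   by index or id.
#' @param i index or id.
#' @export
setMethod("[[", "PatternMatrixSet", function(x, i) {
  if (is.character(i)) i <- match(i, x@ids)
  m <- x@data[, , i]
  dimnames(m) <- list(.TRINUCLEOTIDES, .TRINUCLEOTIDES)
  m
})

setMethod("show", "PatternMatrixSet", function(object) {
  cat("PatternMatrixSet of", length(object), "matrix(es), kappa =",
      object@kappa, "\n")
  if (length(object))
    cat("  ids:", paste(utils::head(object@ids, 5), collapse = ", "),
        if (length(object) > 5) "...", "\n")
})

setMethod("show", "TrinucleotideTrack", function(object) {
  cat("TrinucleotideTrack:", length(object@symbols), "tokens from a",
      object@sourceLength, "nt sequence\n")
})
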