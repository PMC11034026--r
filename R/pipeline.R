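# End-to-end FASTA prediction: window long records, encode each window,
# classify, aggregate window scores by length-weighted averaging, and
# write a deterministic TSV.  Optional second-stage nonviral filter.

#' Split a sequence into consecutive windows
#'
#' Non-overlapping windows of `window` bases, left to right.  A final
#' shorter window is kept only when it reaches `minTail` bases; a
#' sequence no longer than `window` is returned unchanged as a single
#' window (even when shorter than `minTail`).
#'
#' @param seq a single DNA string.
#' @param window window size in bases (default 1000).
#' @param minTail minimum length of the trailing partial window
#'   (default 100).
#' @return named character vector of windows; names are `w1, w2, ...`.
#' @export
splitWindows <- function(seq, window = 1000L, minTail = 100L) {
  if (!(window >= minTail && minTail >= 4L))
    stop("need window >= minTail >= 4")
  seq <- as.character(seq)
  n <- nchar(seq)
  if (n <= window) return(c(w1 = seq))
  nFull <- n %/% window
  tail <- n %% window
  starts <- seq.int(1L, by = window, length.out = nFull)
  ends <- starts + window - 1L
  if (tail >= minTail) {
    starts <- c(starts, nFull * window + 1L)
    ends <- c(ends, n)
  }
  setNames(substring(seq, starts, ends), paste0("w", seq_along(starts)))
}

#' Aggregate window scores into one score vector
#'
#' Element-wise weighted mean of the per-window class scores (weights
#' are normally the window lengths), renormalised to sum exactly 1.
#'
#' @param scores k x C matrix (or a single vector) of per-window class
#'   scores.
#' @param weights positive weights, length k.
#' @return numeric score vector of length C summing to 1.
#' @export
aggregateScores <- function(scores, weights) {
  scores <- rbind(scores)
  if (nrow(scores) == 0L) stop("no window scores to aggregate")
  if (length(weights) != nrow(scores))
    stop("'weights' must supply one value per window")
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("'weights' must be positive")
  agg <- colSums(scores * weights) / sum(weights)
  agg / sum(agg)
}

.FLAG_NONE <- "."

#' Predict host domain for FASTA records
#'
#' For every record: split into windows ([splitWindows()]), encode each
#' window at the model's kappa, run the classifier, and aggregate the
#' per-window softmax scores weighted by window length.  Records without
#' a single usable trinucleotide (e.g. all-N) get uniform scores and a
#' `low_information` flag.  Ties at the argmax go to the first
#' (prokaryotic) class and are flagged `tie`.  With a `filterModel`,
#' records whose viral score falls below `filterThreshold` are flagged
#' `nonviral` (or dropped).
#'
#' @param fasta FASTA file path or a `DNAStringSet`.
#' @param model an [SGTClassifier-class], or the path of a weights file
#'   written by [saveClassifier()].
#' @param out optional path; when given, the score table is written
#'   there as TSV ([writeScoreTable()]).
#' @param window,minTail windowing policy, see [splitWindows()].
#' @param equalWeights use equal instead of length weights when
#'   aggregating.
#' @param rcAverage also score the reverse complement and average the
#'   two score vectors.
#' @param filterModel optional viral-vs-nonviral [SGTClassifier-class]
#'   (or weights path) applied per record; its first class must be the
#'   viral one.
#' @param filterThreshold viral-score threshold of the filter
#'   (default 0.5).
#' @param filterAction `"flag"` (default) or `"drop"`.
#' @return a [ScoreTable-class], rows in input order.
#' @export
predictFasta <- function(fasta, model, out = NULL, window = 1000L,
                         minTail = 100L, equalWeights = FALSE,
                         rcAverage = FALSE, filterModel = NULL,
                         filterThreshold = 0.5,
                         filterAction = c("flag", "drop")) {
  filterAction <- match.arg(filterAction)
  if (is.character(model)) model <- loadClassifier(model)
  stopifnot(is(model, "SGTClassifier"))
  seqs <- .asDNAStringSet(fasta)
  if (length(seqs) == 0L) {
    warning("empty FASTA: returning an empty score table")
    return(.emptyScoreTable(model))
  }
  kappa <- model@config@kappa
  C_ <- model@config@nClasses

  scoreRecord <- function(s) {
    wins <- splitWindows(s, window, minTail)
    lens <- nchar(wins)
    toks <- lapply(wins, tokenizeTrinucleotides)
    usable <- vapply(toks, function(t) length(t@symbols), integer(1))
    if (sum(usable) == 0L)
      return(list(score = rep(1 / C_, C_), n = length(wins),
                  flag = "low_information"))
    arr <- array(0, dim = c(64L, 64L, length(wins)))
    for (i in seq_along(wins))
      if (usable[i] >= 2L)
        arr[, , i] <- .sgt_matrix_cpp(toks[[i]]@symbols,
                                      toks[[i]]@positions, kappa)
    p <- .cnn_predict_cpp(arr, model@params, .cnnDims(model@config))
    w <- if (equalWeights) rep(1, length(wins)) else lens
    list(score = aggregateScores(p, w), n = length(wins),
         flag = .FLAG_NONE)
  }

  n <- length(seqs)
  scoreMat <- matrix(NA_real_, n, C_)
  nWin <- integer(n)
  flags <- character(n)
  chars <- as.character(seqs)
  for (i in seq_len(n)) {
    r <- scoreRecord(chars[i])
    if (rcAverage && r$flag != "low_information") {
      rc <- scoreRecord(as.character(reverseComplement(seqs[i])))
      if (rc$flag != "low_information")
        r$score <- aggregateScores(rbind(r$score, rc$score), c(1, 1))
    }
    scoreMat[i, ] <- r$score
    nWin[i] <- r$n
    flags[i] <- r$flag
  }

  # argmax label; exact ties go to the first (prokaryotic) class
  predIdx <- apply(scoreMat, 1L, which.max)
  tied <- apply(scoreMat, 1L, function(r) sum(r == max(r)) > 1L) &
    flags != "low_information"  # uniform placeholder rows are not ties
  if (any(tied)) {
    message(sum(tied), " record(s) with tied scores assigned to the ",
            "positive class '", model@classNames[1], "'")
    flags[tied] <- ifelse(flags[tied] == .FLAG_NONE, "tie",
                          paste(flags[tied], "tie", sep = ","))
  }

  tab <- DataFrame(seq_id = names(seqs), length = width(seqs),
                   n_windows = nWin)
  for (ci in seq_len(C_))
    tab[[paste0("score_", model@classNames[ci])]] <- scoreMat[, ci]
  tab$predicted_label <- model@classNames[predIdx]
  tab$flags <- flags
  st <- new("ScoreTable", scores = tab, classNames = model@classNames,
            kappa = kappa)

  if (!is.null(filterModel))
    st <- filterNonviral(st, filterModel, seqs,
                         threshold = filterThreshold,
                         action = filterAction, window = window,
                         minTail = minTail)
  if (!is.null(out)) writeScoreTable(st, out)
  st
}

.emptyScoreTable <- function(model) {
  tab <- DataFrame(seq_id = character(), length = integer(),
                   n_windows = integer())
  for (cn in model@classNames) tab[[paste0("score_", cn)]] <- numeric()
  tab$predicted_label <- character()
  tab$flags <- character()
  new("ScoreTable", scores = tab, classNames = model@classNames,
      kappa = model@config@kappa)
}

#' Flag or drop likely nonviral records
#'
#' Applies a separately trained viral-vs-nonviral classifier (same
#' architecture, first class = viral) to the original sequences of a
#' score table; rows whose viral score is below `threshold` are flagged
#' `nonviral` or removed.
#'
#' @param table a [ScoreTable-class] from [predictFasta()].
#' @param filterModel an [SGTClassifier-class] or weights-file path.
#' @param sequences the sequences the table was computed from (FASTA
#'   path or `DNAStringSet`), needed to score them against the filter.
#' @param threshold viral-score cutoff (rows below it are nonviral).
#' @param action `"flag"` (default) or `"drop"`.
#' @param window,minTail windowing policy, see [splitWindows()].
#' @return the filtered [ScoreTable-class].
#' @export
filterNonviral <- function(table, filterModel, sequences, threshold = 0.5,
                           action = c("flag", "drop"), window = 1000L,
                           minTail = 100L) {
  action <- match.arg(action)
  stopifnot(is(table, "ScoreTable"))
  if (is.character(filterModel)) filterModel <- loadClassifier(filterModel)
  stopifnot(is(filterModel, "SGTClassifier"))
  seqs <- .asDNAStringSet(sequences)
  idx <- match(table@scores$seq_id, names(seqs))
  if (anyNA(idx))
    stop("sequences missing for table row(s): ",
         paste(table@scores$seq_id[is.na(idx)], collapse = ", "))
  vt <- predictFasta(seqs[idx], filterModel, window = window,
                     minTail = minTail)
  viralScore <- vt@scores[[paste0("score_", filterModel@classNames[1])]]
  nonviral <- viralScore < threshold
  message(sum(nonviral), " of ", length(nonviral),
          " record(s) below the viral-score threshold ", threshold)
  tab <- table@scores
  if (action == "drop") {
    tab <- tab[!nonviral, , drop = FALSE]
  } else if (any(nonviral)) {
    f <- tab$flags
    f[nonviral] <- ifelse(f[nonviral] == .FLAG_NONE, "nonviral",
                          paste(f[nonviral], "nonviral", sep = ","))
    tab$flags <- f
  }
  new("ScoreTable", scores = tab, classNames = table@classNames,
      kappa = table@kappa)
}

#' Write a score table as TSV
#'
#' Two comment lines record the class order and the encoding kappa and
#' weights-format version; then a header row and one row per record.
#' Scores are printed with 10 significant digits, so repeat runs are
#' byte-identical.
#'
#' @param table a [ScoreTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeScoreTable <- function(table, path) {
  stopifnot(is(table, "ScoreTable"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    paste0("# classes=", paste(table@classNames, collapse = ","),
           " positive=", table@classNames[1]),
    paste0("# kappa=", format(table@kappa),
           " weights_format=", .WEIGHTS_VERSION)), con)
  df <- as.data.frame(table@scores)
  for (cn in grep("^score_", colnames(df), value = TRUE))
    df[[cn]] <- sprintf("%.10g", df[[cn]])
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn ScoreTable-class per-record results as a data.frame.
#' @param x a `ScoreTable`.
#' @export
scoreTable <- function(x) {
  stopifnot(is(x, "ScoreTable"))
  as.data.frame(x@scores)
}

setMethod("show", "ScoreTable", function(object) {
  cat("ScoreTable:", nrow(object@scores), "record(s), classes:",
      paste(object@classNames, collapse = ", "),
      sprintf("(kappa = %g)\n", object@kappa))
  if (nrow(object@scores))
    print(utils::head(as.data.frame(object@scores), 5))
})
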