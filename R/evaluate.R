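# Evaluation harness: threshold metrics from a confusion table, rank
# statistics (ROC-AUC, average precision), and k-fold cross-validation
# over labelled fragment sets.  Positive class = prokaryotic virus
# (the first class) throughout.

#' Confusion counts from labels and predictions
#'
#' @param truth true labels.
#' @param predicted predicted labels.
#' @param positive the positive class (default: prokaryotic virus).
#' @return named integer vector with TP, FP, TN, FN.
#' @export
confusionCounts <- function(truth, predicted, positive = "prokaryotic") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  tpos <- truth == positive; ppos <- predicted == positive
  c(TP = sum(tpos & ppos), FP = sum(!tpos & ppos),
    TN = sum(!tpos & !ppos), FN = sum(tpos & !ppos))
}

#' Threshold metrics from confusion counts
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), ACC = (TP+TN)/total,
#' Precision = TP/(TP+FP), F1 = 2*Precision*Recall/(Precision+Recall).
#' A metric whose denominator is zero is reported as `NA` (missing),
#' never as 0.
#'
#' @param TP,FP,TN,FN non-negative counts; alternatively pass the
#'   vector returned by [confusionCounts()] as `TP`.
#' @return named numeric vector (Sn, Sp, ACC, Precision, F1).
#' @export
confusionMetrics <- function(TP, FP = NULL, TN = NULL, FN = NULL) {
  if (is.null(FP) && length(TP) == 4L && !is.null(names(TP))) {
    FP <- TP[["FP"]]; TN <- TP[["TN"]]; FN <- TP[["FN"]]; TP <- TP[["TP"]]
  }
  counts <- c(TP, FP, TN, FN)
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative")
  div <- function(num, den) if (den > 0) num / den else NA_real_
  sn <- div(TP, TP + FN)
  prec <- div(TP, TP + FP)
  f1 <- if (is.na(sn) || is.na(prec) || sn + prec == 0) NA_real_
        else 2 * prec * sn / (prec + sn)
  c(Sn = sn, Sp = div(TN, TN + FP), ACC = div(TP + TN, sum(counts)),
    Precision = prec, F1 = f1)
}

.posLogical <- function(labels, positive) {
  if (is.logical(labels)) return(labels)
  as.character(labels) == positive
}

#' Area under the ROC curve
#'
#' The Mann-Whitney probability that a random positive outscores a
#' random negative, with half credit for ties; computed from mid-ranks,
#' so it agrees exactly with O(n^2) pair counting.
#'
#' @param labels class labels (or logical: TRUE = positive).
#' @param scores numeric scores, higher = more positive.
#' @param positive the positive class label.
#' @return AUC in \[0, 1\].
#' @export
rocAUC <- function(labels, scores, positive = "prokaryotic") {
  pos <- .posLogical(labels, positive)
  stopifnot(length(pos) == length(scores))
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0L) stop("no positive ('", positive, "') observations")
  if (nNeg == 0L) stop("no negative observations")
  r <- rank(scores)  # mid-ranks handle ties as half credit
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Average precision (step-wise)
#'
#' Non-interpolated area under the precision-recall curve:
#' `sum_k (R_k - R_(k-1)) * P_k` over descending unique score
#' thresholds, with tied scores entering as one group.
#'
#' @inheritParams rocAUC
#' @return AP in (0, 1\].
#' @export
averagePrecision <- function(labels, scores, positive = "prokaryotic") {
  pos <- .posLogical(labels, positive)
  stopifnot(length(pos) == length(scores))
  nPos <- sum(pos)
  if (nPos == 0L) stop("no positive ('", positive, "') observations")
  o <- order(scores, decreasing = TRUE)
  pos <- pos[o]; s <- scores[o]
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  cumTP <- cumsum(pos)[keep]
  n <- seq_along(pos)[keep]
  prec <- cumTP / n
  rec <- cumTP / nPos
  sum(diff(c(0, rec)) * prec)
}

.rankMetrics <- function(truth, scoresPos, predicted, positive) {
  m <- confusionMetrics(confusionCounts(truth, predicted, positive))
  auc <- tryCatch(rocAUC(truth, scoresPos, positive),
                  error = function(e) NA_real_)
  ap <- tryCatch(averagePrecision(truth, scoresPos, positive),
                 error = function(e) NA_real_)
  c(m, AUC = auc, AP = ap)
}

#' k-fold cross-validation on a labelled fragment set
#'
#' For every fold: encode, train on the remaining folds, score the
#' held-out fold.  Metrics (Sn, Sp, ACC, Precision, F1, AUC, AP; the
#' positive class is the first class name) are reported per length
#' group and pooled over groups, per fold and as mean +/- sd over
#' folds.  Fold assignment is genome-level, so no genome contributes
#' to both sides of a split.
#'
#' @param dataset a [LabeledFragmentSet-class] with fold assignments.
#' @param config a [ClassifierConfig-class]; its kappa is used for
#'   encoding.
#' @param classNames ordered class labels; default: order of first
#'   appearance in the dataset (build datasets with the positive source
#'   first).
#' @param epochs training epochs per fold (default: config value).
#' @param verbose print progress.
#' @return list with `perFold` (data.frame: fold x group x metrics),
#'   `summary` (mean and sd per group), and `predictions` (per-fragment
#'   held-out scores).
#' @export
crossValidate <- function(dataset, config = classifierConfig(),
                          classNames = NULL, epochs = NULL,
                          verbose = FALSE) {
  info <- fragmentInfo(dataset)
  if (anyNA(info$fold)) stop("dataset has unassigned folds")
  folds <- sort(unique(info$fold))
  if (length(folds) < 2L) stop("need >= 2 folds")
  if (is.null(classNames)) classNames <- unique(info$label)
  if (config@nClasses != length(classNames))
    stop("config expects ", config@nClasses, " classes but the dataset has ",
         length(classNames))
  positive <- classNames[1]

  enc <- encodeSGT(dataset, kappa = config@kappa)
  preds <- vector("list", length(folds))
  rows <- list()
  for (fi in seq_along(folds)) {
    f <- folds[fi]
    testSel <- info$fold == f
    trainLab <- info$label[!testSel]
    testLab <- info$label[testSel]
    if (length(unique(testLab)) < 2L || length(unique(trainLab)) < 2L)
      stop("fold ", f, " leaves a single class on one side of the split")
    sub <- function(keep) new("PatternMatrixSet",
                              data = enc@data[, , keep, drop = FALSE],
                              kappa = enc@kappa, ids = enc@ids[keep])
    cfgF <- config
    cfgF@seed <- config@seed + fi  # per-fold stream, still deterministic
    model <- buildClassifier(cfgF, classNames)
    model <- trainClassifier(model, sub(!testSel), trainLab,
                             epochs = epochs, verbose = verbose)
    p <- predictProba(model, sub(testSel))
    predLab <- classNames[max.col(p, ties.method = "first")]
    preds[[fi]] <- data.frame(id = info$id[testSel], fold = f,
                              group = info$group[testSel],
                              label = testLab,
                              score = p[, 1L], predicted = predLab)
    grps <- c(as.list(unique(info$group[testSel])), list(NULL))
    for (g in grps) {
      sel <- if (is.null(g)) rep(TRUE, sum(testSel))
             else info$group[testSel] == g
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f, group = if (is.null(g)) "pooled" else g,
        n = sum(sel),
        t(.rankMetrics(testLab[sel], p[sel, 1L], predLab[sel], positive)))
    }
    if (verbose) message("fold ", f, " done")
  }
  perFold <- do.call(rbind, rows)
  metrics <- c("Sn", "Sp", "ACC", "Precision", "F1", "AUC", "AP")
  summ <- do.call(rbind, lapply(split(perFold, perFold$group), function(d) {
    data.frame(group = d$group[1],
               t(colMeans(d[metrics], na.rm = TRUE)),
               t(setNames(vapply(d[metrics], sd, numeric(1), na.rm = TRUE),
                          paste0(metrics, "_sd"))))
  }))
  rownames(summ) <- NULL
  list(perFold = perFold, summary = summ,
       predictions = do.call(rbind, preds))
}
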