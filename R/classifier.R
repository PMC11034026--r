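# The pattern-matrix CNN: configuration, construction, training with
# Adam on categorical cross-entropy, prediction, and weight persistence.
# All tensor work happens in the compiled kernels (src/cnn.cpp).

#' Create a classifier configuration
#'
#' Defaults reproduce the reference architecture and optimiser: two
#' convolution blocks of 128 filters (7 x 7, "same" padding, ReLU) each
#' followed by 2 x 2 max pooling (stride 2) and dropout 0.32, then a
#' 64-unit ReLU dense layer and a softmax output over 2 classes; Adam
#' with learning rate 0.0005, batch size 16, 30 epochs.
#'
#' @param nFilters filters per convolution layer (F).
#' @param kernel kernel size, length-2 integer (k1, k2).
#' @param poolSize pooling window side (S1).
#' @param poolStride pooling stride (S2).
#' @param dropout drop probability in \[0, 1).
#' @param denseUnits units of the first dense layer (R).
#' @param nClasses output classes (C >= 2).
#' @param learningRate Adam learning rate.
#' @param batchSize mini-batch size.
#' @param epochs training epochs.
#' @param seed integer seed for initialisation, shuffling and dropout.
#' @param kappa SGT decay rate the model expects its inputs encoded at;
#'   stored with the weights so inference always reuses the training
#'   value.
#' @return a [ClassifierConfig-class].
#' @export
classifierConfig <- function(nFilters = 128L, kernel = c(7L, 7L),
                             poolSize = 2L, poolStride = 2L,
                             dropout = 0.32, denseUnits = 64L,
                             nClasses = 2L, learningRate = 5e-4,
                             batchSize = 16L, epochs = 30L, seed = 1L,
                             kappa = 1.0) {
  new("ClassifierConfig",
      nFilters = as.integer(nFilters), kernel = as.integer(kernel),
      poolSize = as.integer(poolSize), poolStride = as.integer(poolStride),
      dropout = as.numeric(dropout), denseUnits = as.integer(denseUnits),
      nClasses = as.integer(nClasses),
      learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      seed = as.integer(seed), kappa = as.numeric(kappa),
      inputSide = 64L)
}

# Glorot-uniform draw using R's RNG (caller controls the seed)
.glorot <- function(nr, nc, fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an untrained classifier
#'
#' Instantiates the layer stack of the configuration and initialises all
#' weights Glorot-uniform (biases zero) from the configuration seed, so
#' two builds with the same config are identical.
#'
#' @param config a [ClassifierConfig-class].
#' @param classNames ordered class labels; the first class is the
#'   positive (prokaryotic-virus) class by package convention.
#' @return an [SGTClassifier-class] with `trained = FALSE`.
#' @export
buildClassifier <- function(config = classifierConfig(),
                            classNames = c("prokaryotic", "eukaryotic")) {
  validObject(config)
  if (length(classNames) != config@nClasses)
    stop("'classNames' must supply exactly nClasses = ", config@nClasses,
         " labels")
  L <- config@inputSide
  k1 <- config@kernel[1L]; k2 <- config@kernel[2L]
  F_ <- config@nFilters; R_ <- config@denseUnits; C_ <- config@nClasses
  L1 <- ceiling(L / config@poolStride)
  L2 <- ceiling(L1 / config@poolStride)
  flat <- L2 * L2 * F_
  params <- .withSeed(config@seed, list(
    W1 = .glorot(k1 * k2, F_, k1 * k2, k1 * k2 * F_),
    b1 = numeric(F_),
    W2 = .glorot(k1 * k2 * F_, F_, k1 * k2 * F_, k1 * k2 * F_),
    b2 = numeric(F_),
    W3 = .glorot(flat, R_, flat, R_),
    b3 = numeric(R_),
    W4 = .glorot(R_, C_, R_, C_),
    b4 = numeric(C_)))
  new("SGTClassifier", config = config, params = params,
      classNames = classNames,
      history = data.frame(epoch = integer(), loss = numeric(),
                           acc = numeric(), valLoss = numeric(),
                           valAcc = numeric()),
      trained = FALSE)
}

#' Number of trainable parameters
#'
#' @param model an [SGTClassifier-class].
#' @return integer count over all weight matrices and bias vectors.
#' @export
countParams <- function(model) {
  stopifnot(is(model, "SGTClassifier"))
  sum(vapply(model@params, length, numeric(1)))
}

# labels (factor/character) -> 0-based integer class indices
.classIndex <- function(y, classNames) {
  idx <- match(as.character(y), classNames)
  if (anyNA(idx))
    stop("label(s) outside the class set {",
         paste(classNames, collapse = ", "), "}: ",
         paste(unique(as.character(y)[is.na(idx)]), collapse = ", "))
  idx - 1L
}

.checkKappa <- function(model, x) {
  if (!isTRUE(all.equal(model@config@kappa, x@kappa)))
    stop("kappa mismatch: model expects encodings at kappa = ",
         model@config@kappa, " but matrices carry kappa = ", x@kappa,
         "; encodings at different kappa are not comparable")
}

#' Categorical cross-entropy
#'
#' Mean of `-log p(true class)` over rows; 0 exactly when every row puts
#' probability 1 on its true class, `log(2)` for uniform two-class
#' predictions.
#'
#' @param prob n x C matrix of class probabilities.
#' @param y labels (values of `classNames`) or 1-based class indices.
#' @param classNames class labels naming the columns of `prob`.
#' @return mean loss (non-negative).
#' @export
crossEntropyLoss <- function(prob, y, classNames = colnames(prob)) {
  prob <- rbind(prob)
  idx <- if (is.numeric(y)) as.integer(y)
         else .classIndex(y, classNames) + 1L
  stopifnot(length(idx) == nrow(prob), all(idx >= 1L), all(idx <= ncol(prob)))
  -mean(log(pmax(prob[cbind(seq_len(nrow(prob)), idx)], 1e-12)))
}

# forward pass over an L x L x n array, no dropout
.predictArray <- function(model, arr) {
  .cnn_predict_cpp(arr, model@params, .cnnDims(model@config))
}

.evalSet <- function(model, x, yIdx) {
  p <- .predictArray(model, x@data)
  list(loss = crossEntropyLoss(p, yIdx + 1L),
       acc = mean(max.col(p) == yIdx + 1L))
}

#' Train the classifier
#'
#' Mini-batch Adam on categorical cross-entropy.  Each epoch reshuffles
#' the training set; dropout masks are redrawn per batch.  Everything is
#' driven by the configuration seed, so a rerun with identical data and
#' seed reproduces the history.
#'
#' @param model an [SGTClassifier-class] (untrained or to be fine-tuned).
#' @param x training matrices, a [PatternMatrixSet-class] whose kappa
#'   must equal the model's.
#' @param y training labels, values of `model@classNames`.
#' @param valX,valY optional validation set, reported per epoch.
#' @param epochs number of epochs (default: the configuration value).
#' @param earlyStopping stop when validation loss has not improved for
#'   `patience` epochs (requires a validation set; off by default).
#' @param patience early-stopping patience in epochs.
#' @param verbose print one line per epoch.
#' @return the trained model; `model@history` holds per-epoch loss and
#'   accuracy (train and, when supplied, validation).
#' @export
trainClassifier <- function(model, x, y, valX = NULL, valY = NULL,
                            epochs = NULL, earlyStopping = FALSE,
                            patience = 5L, verbose = FALSE) {
  stopifnot(is(model, "SGTClassifier"), is(x, "PatternMatrixSet"))
  cfg <- model@config
  .checkKappa(model, x)
  if (length(x) == 0L) stop("training set is empty")
  yIdx <- .classIndex(y, model@classNames)
  if (length(yIdx) != length(x))
    stop("labels and matrices differ in length")
  hasVal <- !is.null(valX)
  if (hasVal) {
    stopifnot(is(valX, "PatternMatrixSet"))
    .checkKappa(model, valX)
    valIdx <- .classIndex(valY, model@classNames)
    if (length(valIdx) != length(valX))
      stop("validation labels and matrices differ in length")
  } else if (earlyStopping) {
    stop("early stopping requires a validation set")
  }
  if (is.null(epochs)) epochs <- cfg@epochs
  epochs <- as.integer(epochs)
  n <- length(x)
  # shuffling order and per-epoch dropout seeds come from R's RNG so the
  # whole run is a deterministic function of the configuration seed
  rngState <- .withSeed(cfg@seed, list(
    order = vapply(seq_len(epochs), function(e) sample.int(n), integer(n)),
    dropSeeds = sample.int(.Machine$integer.max, epochs)))
  res <- .cnn_train_cpp(x@data, yIdx, model@params, .cnnDims(cfg),
                        cfg@learningRate, cfg@batchSize, epochs,
                        cfg@dropout, rngState$order, rngState$dropSeeds,
                        if (hasVal) valX@data else NULL,
                        if (hasVal) valIdx else NULL,
                        if (earlyStopping) as.integer(patience) else 0L)
  ran <- seq_len(res$epochsRun)
  h <- as.data.frame(res$history)[ran, , drop = FALSE]
  model@params <- res$params
  model@history <- cbind(epoch = ran, h)
  model@trained <- TRUE
  if (verbose)
    message(sprintf("trained %d epoch(s); final loss %.4f acc %.4f",
                    res$epochsRun, h$loss[length(ran)], h$acc[length(ran)]))
  model
}

#' Class probabilities for a batch of pattern matrices
#'
#' Forward pass with dropout disabled.  Rows are returned in input order
#' and each sums to 1.  Errors if the matrices were encoded at a
#' different kappa than the model was trained with.
#'
#' @param model an [SGTClassifier-class].
#' @param x a [PatternMatrixSet-class] (or a single 64 x 64 matrix).
#' @return numeric matrix, one row per input, columns named by class.
#' @export
predictProba <- function(model, x) {
  stopifnot(is(model, "SGTClassifier"))
  if (is.matrix(x)) {
    arr <- array(x, dim = c(dim(x), 1L))
    ids <- "matrix1"
  } else {
    stopifnot(is(x, "PatternMatrixSet"))
    .checkKappa(model, x)
    arr <- x@data
    ids <- x@ids
  }
  p <- .predictArray(model, arr)
  dimnames(p) <- list(ids, model@classNames)
  p
}

.WEIGHTS_FORMAT <- "viroSGT-classifier"
.WEIGHTS_VERSION <- 1L

#' Save / load classifier weights
#'
#' The container holds a format tag and version, the full configuration
#' (including kappa and the seed), the ordered class names, the fitted
#' parameters and the training history; a load therefore reproduces
#' predictions exactly and refuses files written by something else.
#'
#' @param model an [SGTClassifier-class].
#' @param path file to write / read.
#' @return `saveClassifier` returns `path` invisibly; `loadClassifier`
#'   returns the restored [SGTClassifier-class].
#' @export
saveClassifier <- function(model, path) {
  stopifnot(is(model, "SGTClassifier"))
  obj <- list(format = .WEIGHTS_FORMAT, version = .WEIGHTS_VERSION,
              config = .configAsList(model@config),
              classNames = model@classNames, params = model@params,
              history = model@history, trained = model@trained)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot parse weights file '", path, "': ",
         conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, .WEIGHTS_FORMAT))
    stop("'", path, "' is not a ", .WEIGHTS_FORMAT, " weights file")
  if (!identical(obj$version, .WEIGHTS_VERSION))
    stop("weights file '", path, "' has format version ", obj$version,
         "; this build reads version ", .WEIGHTS_VERSION)
  cfg <- do.call(classifierConfig,
                 obj$config[setdiff(names(obj$config), "inputSide")])
  model <- new("SGTClassifier", config = cfg, params = obj$params,
               classNames = obj$classNames, history = obj$history,
               trained = isTRUE(obj$trained))
  validObject(model)
  model
}

setMethod("show", "SGTClassifier", function(object) {
  cfg <- object@config
  cat("SGTClassifier (", if (object@trained) "trained" else "untrained",
      ")\n", sep = "")
  cat("  classes:", paste(object@classNames, collapse = ", "),
      "(positive:", object@classNames[1], ")\n")
  cat(sprintf("  conv %dx%d x%d (same, ReLU) -> pool %d/%d -> drop %.2f, x2\n",
              cfg@kernel[1], cfg@kernel[2], cfg@nFilters, cfg@poolSize,
              cfg@poolStride, cfg@dropout))
  cat(sprintf("  dense %d (ReLU) -> dense %d (softmax); %d parameters\n",
              cfg@denseUnits, cfg@nClasses, countParams(object)))
  cat(sprintf("  Adam lr %g, batch %d, epochs %d, kappa %g, seed %d\n",
              cfg@learningRate, cfg@batchSize, cfg@epochs, cfg@kappa,
              cfg@seed))
  if (nrow(object@history))
    cat("  last epoch: loss", sprintf("%.4f", utils::tail(object@history$loss, 1)),
        "acc", sprintf("%.4f", utils::tail(object@history$acc, 1)), "\n")
})
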