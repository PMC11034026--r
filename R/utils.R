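# internal helpers

# run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# coerce FASTA path / DNAStringSet / character vector to a named
# DNAStringSet; unnamed inputs get seq1..seqN ids
.asDNAStringSet <- function(x) {
  if (is(x, "DNAStringSet")) {
    s <- x
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    s <- readDNAStringSet(x)
    # keep only the first whitespace-delimited token of FASTA headers
    names(s) <- sub("\\s.*$", "", names(s))
  } else if (is.character(x)) {
    s <- DNAStringSet(x)
  } else {
    stop("cannot interpret input as sequences (expected a FASTA path, ",
         "a DNAStringSet or a character vector)")
  }
  if (is.null(names(s)) || !all(nzchar(names(s))))
    names(s) <- paste0("seq", seq_along(s))
  s
}

.configAsList <- function(config) {
  nm <- slotNames(config)
  setNames(lapply(nm, function(n) slot(config, n)), nm)
}

# dims consumed by the C++ kernels
.cnnDims <- function(config) {
  list(L = config@inputSide, nFilters = config@nFilters,
       k1 = config@kernel[1L], k2 = config@kernel[2L],
       poolSize = config@poolSize, poolStride = config@poolStride,
       denseUnits = config@denseUnits, nClasses = config@nClasses)
}
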