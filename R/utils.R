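#' Seed all random streams
#'
#' Sets R's global RNG (Mersenne-Twister) so that every stochastic component
#' of the package -- parameter initialisation, minibatch shuffling, modality
#' dropout, missing-pattern sampling, synthetic cohorts -- is reproducible.
#' Functions that take their own `seed` argument derive an isolated stream
#' internally and restore the caller's RNG state on exit.
#'
#' @param seed integer seed.
#' @return invisibly, the seed.
#' @export
set_global_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  invisible(as.integer(seed))
}

# Evaluate expr under a local RNG stream; caller's .Random.seed is restored.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

#' Row-wise softmax
#'
#' Numerically stable softmax over the rows of a matrix.
#'
#' @param x numeric matrix.
#' @return matrix of the same shape with non-negative rows summing to 1.
#' @export
softmax_rows <- function(x) {
  x <- as.matrix(x)
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# Apply f to corresponding numeric leaves of nested parameter lists.
param_map <- function(f, ...) {
  args <- list(...)
  p1 <- args[[1]]
  if (is.list(p1)) {
    out <- vector("list", length(p1))
    names(out) <- names(p1)
    for (i in seq_along(p1)) {
      out[[i]] <- do.call(param_map, c(list(f), lapply(args, `[[`, i)))
    }
    out
  } else {
    do.call(f, args)
  }
}

# Sum of f applied over all numeric leaves (e.g. for norms).
param_reduce <- function(f, p, acc = 0) {
  if (is.list(p)) {
    for (el in p) acc <- param_reduce(f, el, acc)
    acc
  } else {
    acc + f(p)
  }
}

# Deterministic FNV-1a hash of a character scalar; used for run manifests.
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
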