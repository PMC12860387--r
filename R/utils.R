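#' Derive a module-specific seed from a global seed
#'
#' One global seed fans out to per-module seeds through a deterministic
#' splitmix-style integer mix, so each module stays independently reproducible
#' while a single `--seed` controls the whole pipeline. The result is always a
#' positive integer below 2^31.
#'
#' @param seed integer global seed.
#' @param label character tag naming the consumer (e.g. `"simulator"`).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  mix <- (abs(seed) %% 2147483647) * 2654435761
  as.integer((mix + h + 12345) %% 2147483629 + 1)
}

# run `code` under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid_mat <- function(x) 1 / (1 + exp(-x))

# clamp probabilities away from {0, 1} before log terms
clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

as_dense <- function(m) {
  if (inherits(m, "Matrix")) as.matrix(m) else m
}
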