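# Small dense-MLP helpers shared by the image-fusion block and the model
# core. An MLP is written by its dimension chain: dims = c(d0, d1, ..., dL)
# means L weight matrices with ReLU on every hidden layer and a linear final
# layer.

#' Initialise MLP parameters
#'
#' He-normal weights (`sd = sqrt(2 / fan_in)`), zero biases.
#'
#' @param dims integer dimension chain `c(d0, ..., dL)`.
#' @param seed integer seed.
#' @param scale optional multiplier on the init scale (small values are used
#'   for conditioning branches that should start near zero).
#' @return list of layers, each `list(W, b)`.
#' @export
mlp_params <- function(dims, seed = 1, scale = 1) {
  if (length(dims) < 2) stop_arg("need at least two dims")
  with_seed(seed, {
    lapply(seq_len(length(dims) - 1L), function(l) {
      list(W = scale * matrix(stats::rnorm(dims[l] * dims[l + 1], 0,
                                           sqrt(2 / dims[l])),
                              dims[l], dims[l + 1]),
           b = numeric(dims[l + 1]))
    })
  })
}

#' Forward pass through an MLP
#'
#' @param x input matrix (rows are samples).
#' @param layers list of `list(W, b)` as from [mlp_params()].
#' @param final character: `"linear"` (default), `"relu"`, `"softmax"` or
#'   `"sigmoid"` activation applied after the last layer.
#' @return output matrix.
#' @export
mlp_forward <- function(x, layers, final = c("linear", "relu", "softmax", "sigmoid")) {
  final <- match.arg(final)
  x <- as.matrix(x)
  L <- length(layers)
  for (l in seq_len(L)) {
    if (ncol(x) != nrow(layers[[l]]$W))
      stop_arg("dimension mismatch at MLP layer ", l, ": input has ", ncol(x),
               " columns, weights expect ", nrow(layers[[l]]$W))
    x <- sweep(x %*% layers[[l]]$W, 2L, layers[[l]]$b, `+`)
    if (l < L) x <- relu(x)
  }
  switch(final,
         linear = x,
         relu = relu(x),
         softmax = softmax_rows(x),
         sigmoid = sigmoid_mat(x))
}
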