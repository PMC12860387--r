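#' Build the KNN spatial graph over spots
#'
#' For each spot the `k` nearest Euclidean neighbours (self excluded, ties
#' broken by lower spot index) receive a directed edge; the adjacency is then
#' symmetrised by logical OR, self-loops are added, and the degree-normalised
#' form `D^(-1/2) (A + I) D^(-1/2)` is computed with degrees taken from the
#' self-looped matrix. Spatial neighbours in spot-based ST share cellular
#' context, so propagating expression over this graph denoises each spot with
#' its neighbourhood.
#'
#' @param coords a [spot_coords] data.frame (pixel units).
#' @param k neighbour count; must satisfy `n_spots > k` (default 5).
#' @return object of class `spatial_graph`: `adjacency` (symmetrised 0/1,
#'   zero diagonal), `adjacency_directed` (pre-symmetrisation), `self_looped`,
#'   `degrees`, `normalized`, `k`, `spot_ids`.
#' @export
build_knn_adjacency <- function(coords, k = 5) {
  stopifnot(is.data.frame(coords))
  n <- nrow(coords)
  if (n <= k) stop_arg("need more spots (", n, ") than neighbours k = ", k)
  xy <- as.matrix(coords[, c("x", "y")])
  if (!all(is.finite(xy))) stop_arg("non-finite coordinates")
  d <- as.matrix(stats::dist(xy))
  A_dir <- matrix(0, n, n)
  for (i in seq_len(n)) {
    dd <- d[i, ]
    dd[i] <- Inf
    # ties broken by lower spot index: order() is stable on the index
    nn <- order(dd)[seq_len(k)]
    A_dir[i, nn] <- 1
  }
  A <- 1 * ((A_dir + t(A_dir)) > 0)
  finalize_graph(A, A_dir, k, coords$spot_id)
}

finalize_graph <- function(A, A_dir, k, spot_ids) {
  n <- nrow(A)
  A_hat <- A + diag(n)
  deg <- rowSums(A_hat)
  dinv <- 1 / sqrt(deg)
  normalized <- A_hat * outer(dinv, dinv)
  structure(list(adjacency = A, adjacency_directed = A_dir,
                 self_looped = A_hat, degrees = deg,
                 normalized = normalized, k = k, spot_ids = spot_ids),
            class = "spatial_graph")
}

#' Recompute the degree-normalised adjacency
#'
#' `normalized = D^(-1/2) (A + I) D^(-1/2)` with `D_ii = sum_j (A + I)_ij`.
#' Self-loops guarantee strictly positive degrees, so the operation is always
#' defined; the result is symmetric with spectrum inside `[-1, 1]`.
#'
#' @param g a `spatial_graph` (only `adjacency` is consulted).
#' @return the graph with `self_looped`, `degrees` and `normalized` refreshed.
#' @export
normalize_adjacency <- function(g) {
  stopifnot(inherits(g, "spatial_graph"))
  A <- g$adjacency
  if (any(diag(A) != 0)) stop_arg("adjacency must have a zero diagonal")
  if (!isTRUE(all.equal(A, t(A)))) stop_arg("adjacency must be symmetric")
  finalize_graph(A, g$adjacency_directed, g$k, g$spot_ids)
}

#' Construct a GCN weight stack
#'
#' @param dims integer vector `d0, d1, ..., dL` of layer widths (`L >= 1`
#'   weight matrices).
#' @param init `"he"` (random, He-scaled) or `"identity"` (square layers
#'   start as the identity, so the initial forward pass is pure neighbourhood
#'   smoothing).
#' @param seed integer seed for random init.
#' @return object of class `gcn_stack` with `weights` (list of matrices) and
#'   `dims`.
#' @export
gcn_stack <- function(dims, init = c("he", "identity"), seed = 1) {
  init <- match.arg(init)
  if (length(dims) < 2) stop_arg("need at least one layer (two dims)")
  with_seed(seed, {
    weights <- lapply(seq_len(length(dims) - 1L), function(l) {
      if (init == "identity") {
        if (dims[l] != dims[l + 1])
          stop_arg("identity init requires square layers")
        diag(dims[l])
      } else {
        matrix(stats::rnorm(dims[l] * dims[l + 1], 0, sqrt(2 / dims[l])),
               dims[l], dims[l + 1])
      }
    })
    structure(list(weights = weights, dims = dims), class = "gcn_stack")
  })
}

#' Graph-convolutional encoding of spot features
#'
#' Applies `H^(l+1) = ReLU(normalized %*% H^(l) %*% W^(l))` for every layer of
#' the stack, starting from `H^(0) = features`. The output carries both
#' expression and spatial neighbourhood information.
#'
#' @param features spots x d0 numeric matrix.
#' @param g a `spatial_graph`.
#' @param stack a [gcn_stack()].
#' @return spots x dL numeric matrix.
#' @export
gcn_encode <- function(features, g, stack) {
  stopifnot(inherits(g, "spatial_graph"), inherits(stack, "gcn_stack"))
  features <- as.matrix(features)
  if (nrow(features) != nrow(g$normalized))
    stop_arg("feature rows (", nrow(features), ") != graph size (", nrow(g$normalized), ")")
  H <- features
  for (l in seq_along(stack$weights)) {
    W <- stack$weights[[l]]
    if (ncol(H) != nrow(W))
      stop_arg("dimension mismatch at layer ", l, ": features have ",
               ncol(H), " columns, weights expect ", nrow(W))
    H <- relu(g$normalized %*% H %*% W)
  }
  H
}

#' Export adjacency as a sparse triplet data.frame
#' @param g a `spatial_graph`.
#' @return data.frame with columns `i`, `j`, `value` for the symmetrised
#'   adjacency (useful for writing an inspection CSV).
#' @export
adjacency_triplets <- function(g) {
  stopifnot(inherits(g, "spatial_graph"))
  idx <- which(g$adjacency != 0, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], value = g$adjacency[idx])
}
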