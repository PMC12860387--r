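#' Extract multi-scale histology patches around each spot
#'
#' For every spot and every scale `s`, the `s x s` pixel box centred on the
#' spot coordinate is cropped (constant-white padding where the box leaves
#' the image) and resized to `out_size x out_size` with bilinear
#' interpolation. The padded area fraction of the pre-resize box is recorded.
#' A spot whose box lies entirely outside the image yields an all-white patch
#' with a warning, never an error.
#'
#' @param image H x W x 3 array in `[0,1]`.
#' @param coords a [spot_coords] data.frame; `x` indexes image columns, `y`
#'   image rows, in full-resolution pixels.
#' @param scales integer vector of pre-resize box sides (default
#'   `c(150, 100, 50)`).
#' @param out_size output side in pixels (default 224).
#' @return object of class `patch_set`: `patches[[spot]][[scale]]` arrays of
#'   `out_size x out_size x 3`, plus a `provenance` data.frame with spot id,
#'   scale, crop box and padded fraction.
#' @export
extract_patches <- function(image, coords, scales = c(150, 100, 50), out_size = 224) {
  stopifnot(length(dim(image)) == 3)
  n <- nrow(coords)
  patches <- vector("list", n)
  prov <- list()
  for (i in seq_len(n)) {
    per_scale <- list()
    for (s in scales) {
      cp <- crop_patch(image, coords$x[i], coords$y[i], s)
      per_scale[[as.character(s)]] <- resize_bilinear(cp$patch, out_size)
      prov[[length(prov) + 1L]] <- data.frame(
        spot_id = coords$spot_id[i], scale = s,
        x0 = cp$x0, x1 = cp$x1, y0 = cp$y0, y1 = cp$y1,
        padded_fraction = cp$padded_fraction)
      if (cp$padded_fraction >= 1)
        warning("spot ", coords$spot_id[i], ": patch at scale ", s,
                " lies entirely outside the image; returning all-white",
                call. = FALSE)
    }
    patches[[i]] <- per_scale
  }
  structure(list(patches = patches, provenance = do.call(rbind, prov),
                 scales = scales, out_size = out_size,
                 spot_ids = coords$spot_id),
            class = "patch_set")
}

# crop the s x s box centred at (x, y); white padding outside the image
crop_patch <- function(image, x, y, s) {
  h <- dim(image)[1]; w <- dim(image)[2]
  left <- round(x - s / 2); top <- round(y - s / 2)
  cols <- (left + 1):(left + s)
  rows <- (top + 1):(top + s)
  patch <- array(1, c(s, s, 3))
  rin <- which(rows >= 1 & rows <= h)
  cin <- which(cols >= 1 & cols <= w)
  if (length(rin) > 0 && length(cin) > 0)
    patch[rin, cin, ] <- image[rows[rin], cols[cin], , drop = FALSE]
  visible <- length(rin) * length(cin)
  list(patch = patch, x0 = left + 1, x1 = left + s, y0 = top + 1, y1 = top + s,
       padded_fraction = 1 - visible / (s * s))
}

# bilinear resize of an H x W x C array to out x out (square output, so the
# x/y storage convention of EBImage is immaterial)
resize_bilinear <- function(patch, out_size) {
  img <- EBImage::Image(patch, colormode = "Color")
  out <- EBImage::resize(img, w = out_size, h = out_size, filter = "bilinear")
  array(EBImage::imageData(out), c(out_size, out_size, dim(patch)[3]))
}

# frozen random projection of the stub backend, built once per session
stub_env <- new.env(parent = emptyenv())

stub_projection <- function(grid = 16L, n_tokens = 16L, dim = 64L) {
  key <- paste(grid, n_tokens, dim, sep = "_")
  if (is.null(stub_env[[key]])) {
    stub_env[[key]] <- with_seed(791031L, {
      matrix(stats::rnorm(grid * grid * n_tokens * dim, 0,
                          1 / sqrt(grid * grid)),
             grid * grid, n_tokens * dim)
    })
  }
  stub_env[[key]]
}

#' Encode a histology patch into token embeddings
#'
#' The `stub` backend is a deterministic, training-free encoder: the patch is
#' converted to grayscale, reduced to a 16 x 16 grid by bilinear resampling,
#' flattened, and mapped through a frozen fixed-seed random projection to
#' `n_tokens` tokens of dimension `dim`. The map is linear in the pixel
#' values. The `external` backend is the adapter point for a pretrained
#' pathology foundation encoder (patch -> tokens contract); it is not bundled
#' and must be supplied via `external_fn`.
#'
#' @param patch `out_size x out_size x 3` array in `[0,1]`.
#' @param backend `"stub"` or `"external"`.
#' @param n_tokens,dim token count / token dimension of the stub (defaults
#'   16 / 64).
#' @param external_fn optional function(patch) -> tokens matrix for the
#'   external backend.
#' @return `n_tokens x dim` numeric matrix of token embeddings.
#' @export
encode_patch <- function(patch, backend = c("stub", "external"),
                         n_tokens = 16L, dim = 64L, external_fn = NULL) {
  backend <- match.arg(backend)
  if (backend == "external") {
    if (is.null(external_fn))
      stop_arg("external backend unavailable: supply external_fn or use backend = 'stub'")
    return(external_fn(patch))
  }
  gray <- (patch[, , 1] + patch[, , 2] + patch[, , 3]) / 3
  grid <- 16L
  g <- EBImage::imageData(EBImage::resize(EBImage::Image(gray),
                                          w = grid, h = grid,
                                          filter = "bilinear"))
  v <- as.vector(g)
  matrix(v %*% stub_projection(grid, n_tokens, dim), n_tokens, dim)
}

#' Self-attention pooling of token embeddings
#'
#' `scores = tokens %*% w / sqrt(d)`, `alpha = softmax(scores)`, output is the
#' alpha-weighted sum of the tokens: a convex combination, so the pooled
#' vector always lies in the per-coordinate convex hull of the tokens.
#'
#' @param tokens `N x d` token matrix.
#' @param pool_weights length-`d` numeric pooling weight vector.
#' @return length-`d` pooled vector.
#' @export
attention_pool <- function(tokens, pool_weights) {
  tokens <- as.matrix(tokens)
  if (nrow(tokens) == 0) stop_arg("tokens must be non-empty")
  d <- ncol(tokens)
  if (length(pool_weights) != d)
    stop_arg("pool_weights length (", length(pool_weights),
             ") != token dimension (", d, ")")
  scores <- as.vector(tokens %*% pool_weights) / sqrt(d)
  alpha <- exp(scores - max(scores))
  alpha <- alpha / sum(alpha)
  as.vector(crossprod(tokens, alpha))
}

#' Fuse per-scale pooled embeddings into one perceptual vector
#'
#' Concatenates the per-scale pooled vectors and passes them through an MLP
#' with ReLU hidden activations (the fusion network), yielding the unified
#' per-spot perceptual embedding.
#'
#' @param pooled list of equal-length pooled vectors, one per scale.
#' @param fuse_layers MLP layers as from [mlp_params()]; input dim must equal
#'   `length(pooled) * d`.
#' @return numeric perceptual embedding vector.
#' @export
fuse_scales <- function(pooled, fuse_layers) {
  d <- unique(vapply(pooled, length, integer(1)))
  if (length(d) != 1) stop_arg("pooled vectors must share one dimension")
  x <- matrix(unlist(pooled), nrow = 1)
  as.vector(mlp_forward(x, fuse_layers))
}

#' Cross-attention parameter set
#'
#' @param d_query,d_kv input dims of the query rows and of the key/value
#'   (perceptual) rows.
#' @param d_k per-head attention dimension (default 64).
#' @param n_heads number of heads (default 4).
#' @param seed integer seed.
#' @param scale init scale multiplier.
#' @return list of class `cross_attention_params` with `W_Q`, `W_K`, `W_V`
#'   (projections into `d_k * n_heads`), `d_k`, `n_heads`.
#' @export
cross_attention_params <- function(d_query, d_kv, d_k = 64L, n_heads = 4L,
                                   seed = 1, scale = 1) {
  with_seed(seed, {
    pr <- function(din) scale * matrix(stats::rnorm(din * d_k * n_heads, 0,
                                                    1 / sqrt(din)),
                                       din, d_k * n_heads)
    structure(list(W_Q = pr(d_query), W_K = pr(d_kv), W_V = pr(d_kv),
                   d_k = d_k, n_heads = n_heads),
              class = "cross_attention_params")
  })
}

#' Cross-modal multi-head attention
#'
#' Queries come from spot latent rows, Keys and Values from perceptual
#' embedding rows: `Attn(Q, K, V) = softmax(Q K^T / sqrt(d_k)) V` per head,
#' heads concatenated. Three key-set modes are supported: `"paired"` (each
#' query row attends to its own single perceptual row -- the softmax over one
#' element is 1, so the output is the projected value row), `"all"` (every
#' query attends over all perceptual rows), and `"neighbors"` (per-query
#' integer index list into the perceptual rows).
#'
#' @param query_feats `B x d_query` matrix.
#' @param perceptual `M x d_kv` matrix of perceptual rows.
#' @param params a [cross_attention_params()].
#' @param mode `"paired"`, `"all"` or `"neighbors"`.
#' @param neighbors list of length `B` of key row indices (mode
#'   `"neighbors"`).
#' @return `B x (d_k * n_heads)` matrix of concatenated head outputs.
#' @export
cross_modal_attend <- function(query_feats, perceptual, params,
                               mode = c("paired", "all", "neighbors"),
                               neighbors = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "cross_attention_params"))
  query_feats <- as.matrix(query_feats)
  perceptual <- as.matrix(perceptual)
  if (ncol(query_feats) != nrow(params$W_Q))
    stop_arg("query dim ", ncol(query_feats), " inconsistent with W_Q (",
             nrow(params$W_Q), " rows)")
  if (ncol(perceptual) != nrow(params$W_K))
    stop_arg("perceptual dim inconsistent with W_K/W_V")
  B <- nrow(query_feats)
  dk <- params$d_k; H <- params$n_heads
  Q <- query_feats %*% params$W_Q
  K <- perceptual %*% params$W_K
  V <- perceptual %*% params$W_V
  if (mode == "paired") {
    if (nrow(perceptual) != B)
      stop_arg("paired mode needs one perceptual row per query row")
    return(V)  # softmax over a single key is identically 1
  }
  key_sets <- switch(mode,
    all = rep(list(seq_len(nrow(perceptual))), B),
    neighbors = {
      if (is.null(neighbors) || length(neighbors) != B)
        stop_arg("neighbors must be a list with one entry per query row")
      neighbors
    })
  out <- matrix(0, B, dk * H)
  for (h in seq_len(H)) {
    cols <- ((h - 1) * dk + 1):(h * dk)
    for (b in seq_len(B)) {
      ks <- key_sets[[b]]
      logits <- (Q[b, cols, drop = FALSE] %*% t(K[ks, cols, drop = FALSE])) / sqrt(dk)
      a <- exp(logits - max(logits)); a <- a / sum(a)
      out[b, cols] <- a %*% V[ks, cols, drop = FALSE]
    }
  }
  out
}

#' Compute per-spot multi-scale token banks
#'
#' Convenience wrapper running patch extraction and patch encoding spot by
#' spot (memory-light: full-resolution patches are never all held at once).
#'
#' @param image,coords,scales,out_size as in [extract_patches()].
#' @param backend,n_tokens,dim,external_fn as in [encode_patch()].
#' @return list of class `token_bank`: `tokens[[scale]][[spot]]` token
#'   matrices, plus `scales`, `spot_ids`, `dim`.
#' @export
spot_token_bank <- function(image, coords, scales = c(150, 100, 50),
                            out_size = 224, backend = "stub",
                            n_tokens = 16L, dim = 64L, external_fn = NULL) {
  n <- nrow(coords)
  tokens <- lapply(scales, function(s) vector("list", n))
  names(tokens) <- as.character(scales)
  for (i in seq_len(n)) {
    for (s in scales) {
      cp <- crop_patch(image, coords$x[i], coords$y[i], s)
      patch <- resize_bilinear(cp$patch, out_size)
      tokens[[as.character(s)]][[i]] <-
        encode_patch(patch, backend, n_tokens, dim, external_fn)
    }
  }
  structure(list(tokens = tokens, scales = scales, spot_ids = coords$spot_id,
                 dim = dim, n_tokens = n_tokens),
            class = "token_bank")
}
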