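#' Construct the multitask spot autoencoder
#'
#' Parameter container for the five cooperating modules:
#' \itemize{
#'   \item graph encoder: one gene-dimension-preserving GCN layer
#'     (`G -> G`, identity-initialised, learnable) so that the shared encoder
#'     sees the same input space for graph-encoded real spots and raw
#'     simulated spots;
#'   \item encoder `E`: MLP `G -> 512 -> d_f` (ReLU hidden, linear latent);
#'   \item conditional decoder `D`: mirrored MLP `d_f -> 512 -> G`; on the
#'     real branch every decoder layer additively receives a learnable
#'     projection of the sinusoidal positional encoding and a residual
#'     cross-attention read-out of the per-spot perceptual embedding; the
#'     simulated branch skips both injections identically (pure residual);
#'   \item shared extractor `F_shared`: MLP `d_f -> 128 -> d_s`, one
#'     parameter set serving both domains;
#'   \item heads: proportion head (linear `d_s -> P1` + softmax), pathology
#'     head (linear `d_s -> P2` + softmax);
#'   \item domain discriminator `M`: MLP `d_f -> 64 -> 1` + sigmoid, reached
#'     through a gradient reversal layer during training.
#' }
#' Conditioning branches (positional projections, attention value/output
#' projections, fusion output layer) are small-initialised so training starts
#' close to the unconditioned autoencoder.
#'
#' @param n_genes gene count `G` of the aligned gene space.
#' @param n_types cell-type count `P1`.
#' @param n_classes pathology class count `P2`.
#' @param d_f latent dimension (default 256).
#' @param d_s shared-feature dimension (default 128).
#' @param hidden encoder/decoder hidden width (default 512).
#' @param d_img perceptual embedding dimension (default 64).
#' @param d_k,n_heads cross-attention head dimension / count (defaults 64, 4;
#'   `d_k * n_heads` is fixed to 256 internally for the decoder blocks).
#' @param n_scales number of histology patch scales (default 3).
#' @param grl_coeff gradient reversal coefficient (>= 0, default 1).
#' @param seed integer seed for initialisation.
#' @return object of class `s2ae_model`; a named list of parameter matrices
#'   plus the architecture description under `$arch`.
#' @export
s2ae_model <- function(n_genes, n_types, n_classes = 2L, d_f = 256L,
                       d_s = 128L, hidden = 512L, d_img = 64L, d_k = 64L,
                       n_heads = 4L, n_scales = 3L, grl_coeff = 1,
                       seed = 1) {
  if (grl_coeff < 0) stop_arg("grl_coeff must be >= 0")
  if (d_f %% 4 != 0) stop_arg("d_f must be a multiple of 4 (positional encoding)")
  d_attn <- d_k * n_heads
  sd <- function(tag) derive_seed(seed, tag)
  params <- list(
    gcn = gcn_stack(c(n_genes, n_genes), init = "identity"),
    enc = mlp_params(c(n_genes, hidden, d_f), seed = sd("enc")),
    dec = mlp_params(c(d_f, hidden, n_genes), seed = sd("dec")),
    shared = mlp_params(c(d_f, 128L, d_s), seed = sd("shared")),
    prop_head = mlp_params(c(d_s, n_types), seed = sd("prop")),
    hist_head = mlp_params(c(d_s, n_classes), seed = sd("hist")),
    disc = mlp_params(c(d_f, 64L, 1L), seed = sd("disc")),
    pool_w = with_seed(sd("pool"), {
      lapply(seq_len(n_scales), function(s) stats::rnorm(d_img, 0, 1 / sqrt(d_img)))
    }),
    fuse = mlp_params(c(n_scales * d_img, 128L, d_img), seed = sd("fuse"),
                      scale = 1),
    # decoder conditioning: one positional projection and one attention block
    # per decoder hidden state (widths d_f and hidden)
    pos_proj = list(
      mlp_params(c(d_f, d_f), seed = sd("posproj0"), scale = 0.01)[[1]],
      mlp_params(c(d_f, hidden), seed = sd("posproj1"), scale = 0.01)[[1]]),
    attn = list(
      c(unclass(cross_attention_params(d_f, d_img, d_k, n_heads,
                                       seed = sd("attn0"), scale = 0.05)),
        list(W_O = mlp_params(c(d_attn, d_f), seed = sd("attnO0"),
                              scale = 0.05)[[1]]$W)),
      c(unclass(cross_attention_params(hidden, d_img, d_k, n_heads,
                                       seed = sd("attn1"), scale = 0.05)),
        list(W_O = mlp_params(c(d_attn, hidden), seed = sd("attnO1"),
                              scale = 0.05)[[1]]$W)))
  )
  params$arch <- list(n_genes = n_genes, n_types = n_types,
                      n_classes = n_classes, d_f = d_f, d_s = d_s,
                      hidden = hidden, d_img = d_img, d_k = d_k,
                      n_heads = n_heads, n_scales = n_scales,
                      grl_coeff = grl_coeff, seed = seed,
                      gene_ids = NULL, type_names = NULL)
  class(params) <- "s2ae_model"
  params
}

#' @export
print.s2ae_model <- function(x, ...) {
  a <- x$arch
  cat(sprintf(paste0("s2ae_model: G=%d genes, P1=%d types, P2=%d classes, ",
                     "d_f=%d, d_s=%d, hidden=%d\n"),
              a$n_genes, a$n_types, a$n_classes, a$d_f, a$d_s, a$hidden))
  invisible(x)
}

#' Sinusoidal positional encoding of spot coordinates
#'
#' Coordinates are min-max normalised per axis to `[0, 1]`; each axis then
#' receives interleaved `sin`/`cos` bands at geometrically decreasing
#' frequencies `omega_k = 10000^(-k / K)` (so the base band, `k = 0`, has
#' angular frequency 1). All entries lie in `[-1, 1]` and the map is a
#' deterministic function of the coordinates.
#'
#' @param coords a [spot_coords] data.frame.
#' @param dim even output dimension.
#' @return spots x dim matrix.
#' @export
positional_encode <- function(coords, dim) {
  if (dim %% 2 != 0) stop_arg("dim must be even")
  norm01 <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) rep(0, length(v)) else (v - rng[1]) / diff(rng)
  }
  tx <- norm01(coords$x)
  ty <- norm01(coords$y)
  n_pairs <- dim / 2L
  kx <- ceiling(n_pairs / 2)           # sin/cos pairs for the x axis
  ky <- n_pairs - kx                   # remaining pairs for the y axis
  enc_axis <- function(t, K) {
    if (K == 0) return(matrix(0, length(t), 0))
    omega <- 10000^(-(seq_len(K) - 1) / K)
    out <- matrix(0, length(t), 2 * K)
    for (k in seq_len(K)) {
      out[, 2 * k - 1] <- sin(omega[k] * t)
      out[, 2 * k] <- cos(omega[k] * t)
    }
    out
  }
  cbind(enc_axis(tx, kx), enc_axis(ty, ky))
}

#' Encode expression rows into the latent space
#'
#' Deterministic forward pass through the shared encoder `E`; accepts either
#' raw (simulated) rows or graph-encoded (real) rows, both of width `G`.
#'
#' @param model an [s2ae_model()].
#' @param x spots x G numeric matrix.
#' @return spots x d_f latent matrix.
#' @export
encode_latent <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$arch$n_genes)
    stop_arg("input has ", ncol(x), " columns, encoder expects G = ",
             model$arch$n_genes)
  mlp_forward(x, model$enc)
}

#' Shared feature extraction
#'
#' One parameter set (`F_shared`) applied to latents from either domain.
#'
#' @param model an [s2ae_model()].
#' @param latent spots x d_f matrix.
#' @return spots x d_s matrix.
#' @export
shared_extract <- function(model, latent) {
  latent <- as.matrix(latent)
  if (ncol(latent) != model$arch$d_f)
    stop_arg("latent has ", ncol(latent), " columns, expected d_f = ", model$arch$d_f)
  mlp_forward(latent, model$shared)
}

#' Predict per-spot cell-type proportions from shared features
#'
#' Linear head + row softmax: rows sum to 1 with strictly positive entries.
#'
#' @param model an [s2ae_model()].
#' @param shared spots x d_s matrix.
#' @return a [proportion_matrix].
#' @export
predict_proportions <- function(model, shared) {
  p <- mlp_forward(as.matrix(shared), model$prop_head, final = "softmax")
  proportion_matrix(p, model$arch$type_names %||%
                      paste0("type", seq_len(ncol(p))),
                    rownames(shared))
}

#' Predict per-spot pathology class probabilities from shared features
#'
#' @param model an [s2ae_model()].
#' @param shared spots x d_s matrix.
#' @return spots x P2 row-stochastic matrix.
#' @export
predict_pathology <- function(model, shared) {
  mlp_forward(as.matrix(shared), model$hist_head, final = "softmax")
}

#' Domain probability of latent rows (discriminator forward pass)
#'
#' The forward pass is the discriminator `M` alone -- the gradient reversal
#' layer is the identity forward. The reversal contract (gradients through
#' this operation equal `-grl_coeff` times the unreversed gradients) is
#' honoured by the training graph; see the training functions.
#'
#' @param model an [s2ae_model()].
#' @param latent spots x d_f matrix.
#' @param grl_coeff non-negative reversal coefficient (default the model's).
#' @return numeric vector of per-spot probabilities in `(0, 1)`.
#' @export
grl_discriminate <- function(model, latent, grl_coeff = model$arch$grl_coeff) {
  if (grl_coeff < 0) stop_arg("grl_coeff must be >= 0")
  p <- mlp_forward(as.matrix(latent), model$disc, final = "sigmoid")
  as.vector(clamp_prob(p))
}

#' Conditional decoding of latent rows
#'
#' Mirrored decoder `d_f -> hidden -> G`. On the conditioned (real) branch
#' each decoder hidden state `h` is updated as
#' `h <- h + PosProj(pos)` then `h <- h + W_O(CrossAttn(h, f_perc))` before
#' the MLP sublayer; with `perceptual = NULL` and `pos = NULL` both
#' injections are skipped identically, reducing to the plain decoder used on
#' the simulated branch.
#'
#' @param model an [s2ae_model()].
#' @param latent spots x d_f matrix.
#' @param perceptual optional spots x d_img matrix of per-spot perceptual
#'   embeddings (row-aligned with `latent`).
#' @param pos optional spots x d_f positional encoding matrix (row-aligned).
#' @return spots x G reconstruction.
#' @export
decode_conditional <- function(model, latent, perceptual = NULL, pos = NULL) {
  latent <- as.matrix(latent)
  a <- model$arch
  if (ncol(latent) != a$d_f) stop_arg("latent width != d_f")
  if (!is.null(perceptual) && nrow(as.matrix(perceptual)) != nrow(latent))
    stop_arg("perceptual rows not aligned with latent rows")
  if (!is.null(pos) && nrow(as.matrix(pos)) != nrow(latent))
    stop_arg("positional rows not aligned with latent rows")
  h <- latent
  for (l in 1:2) {
    if (!is.null(pos))
      h <- h + sweep(as.matrix(pos) %*% model$pos_proj[[l]]$W, 2L,
                     model$pos_proj[[l]]$b, `+`)
    if (!is.null(perceptual)) {
      at <- model$attn[[l]]
      ap <- structure(list(W_Q = at$W_Q, W_K = at$W_K, W_V = at$W_V,
                           d_k = at$d_k, n_heads = at$n_heads),
                      class = "cross_attention_params")
      h <- h + cross_modal_attend(h, as.matrix(perceptual), ap,
                                  mode = "paired") %*% at$W_O
    }
    layer <- model$dec[[l]]
    h <- sweep(h %*% layer$W, 2L, layer$b, `+`)
    if (l < 2) h <- relu(h)
  }
  h
}

#' Per-spot perceptual embeddings from a token bank
#'
#' Attention-pools each scale with the model's pooling weights and fuses the
#' scales with the model's fusion MLP.
#'
#' @param model an [s2ae_model()].
#' @param bank a [spot_token_bank()] result.
#' @return spots x d_img matrix of perceptual embeddings.
#' @export
perceptual_embed <- function(model, bank) {
  stopifnot(inherits(bank, "token_bank"))
  n <- length(bank$tokens[[1]])
  out <- matrix(0, n, model$arch$d_img)
  for (i in seq_len(n)) {
    pooled <- lapply(seq_along(bank$scales), function(s)
      attention_pool(bank$tokens[[s]][[i]], model$pool_w[[s]]))
    out[i, ] <- fuse_scales(pooled, model$fuse)
  }
  rownames(out) <- bank$spot_ids
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding every parameter tensor
#' keyed by module path plus the architecture snapshot; the round trip is
#' bit-stable.
#'
#' @param model an [s2ae_model()].
#' @param path target file.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "s2ae_model"))
  m
}
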