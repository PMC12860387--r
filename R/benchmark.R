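#' Run the standard synthetic recovery benchmark
#'
#' End-to-end exercise of the whole pipeline on fully synthetic data with
#' known ground truth: a marker-structured single-cell reference (4 types,
#' 200 genes, 2 000 cells, marker fold 8), 500 pseudo-spots for supervision,
#' a 15 x 15 spot slide with 4 contiguous tinted regions (one dominant cell
#' type each) as the "real" domain, joint training with
#' `lambda = (0.1, 0.1, 0.01)` and the stub image backend, and deconvolution
#' of the slide spots against the planted truth.
#'
#' @param seed integer master seed; all generators and training derive from
#'   it.
#' @param epochs training epochs (default 150).
#' @param batch_size batch size (default 64).
#' @param learning_rate Adam rate (default 1e-3).
#' @param n_spots pseudo-spot count (default 500).
#' @param slide_dim slide grid side (default 15, i.e. 225 real spots).
#' @param use_sce,use_sfe module switches for ablation runs.
#' @param w loss weights (default `loss_weights(0.1, 0.1, 0.01)`).
#' @param verbose print per-epoch losses.
#' @return list of class `recovery_benchmark`: the generated `ref`,
#'   `pseudospots`, `slide`, `real` dataset, the `fit`, predicted
#'   `proportions`, the `report` ([evaluate_folds()] on proportions) and
#'   `argmax_accuracy` (fraction of spots whose predicted dominant type
#'   matches the planted dominant type).
#' @export
run_recovery_benchmark <- function(seed = 7, epochs = 150, batch_size = 64,
                                   learning_rate = 1e-3, n_spots = 500,
                                   slide_dim = 15, use_sce = TRUE,
                                   use_sfe = TRUE,
                                   w = loss_weights(0.1, 0.1, 0.01),
                                   verbose = FALSE) {
  ref <- generate_synthetic_scrna(n_cells = 2000, n_genes = 200, n_types = 4,
                                  marker_fold = 8, base_rate = 1, seed = seed)
  ps <- simulate_pseudospots(ref, pseudospot_config(
    n_spots = n_spots, seed = derive_seed(seed, "pseudospots")))
  slide <- generate_synthetic_slide(slide_dim, slide_dim, spacing_px = 60,
                                    n_regions = 4, image_margin_px = 80,
                                    seed = derive_seed(seed, "slide"))
  real <- simulate_slide_spots(ref, slide, dominant_weight = 0.7,
                               seed = derive_seed(seed, "slide-spots"))
  cfg <- train_config(learning_rate = learning_rate, epochs = epochs,
                      batch_size = batch_size,
                      seed = derive_seed(seed, "train"))
  fit <- s2ae_fit(pseudospot_dataset(ps), real, cfg, w,
                  use_sce = use_sce, use_sfe = use_sfe, verbose = verbose)
  pred <- deconvolve(fit$model, real)
  report <- evaluate_folds(pred, real$proportions, coords = real$coords)
  truth <- unclass(real$proportions)
  acc <- mean(max.col(unclass(pred), ties.method = "first") ==
                max.col(truth, ties.method = "first"))
  structure(list(ref = ref, pseudospots = ps, slide = slide, real = real,
                 fit = fit, proportions = pred, report = report,
                 argmax_accuracy = acc, seed = seed),
            class = "recovery_benchmark")
}

#' @export
print.recovery_benchmark <- function(x, ...) {
  cat(sprintf("recovery_benchmark (seed %d): mean spot PCC %.4f | SSIM %.4f | RMSE %.4f | argmax accuracy %.3f\n",
              x$seed, x$report$pcc_mean, x$report$ssim_mean, x$report$rmse,
              x$argmax_accuracy))
  invisible(x)
}

#' Conditioned reconstruction of real spot expression
#'
#' Runs the real-branch forward pass of a trained model: normalisation,
#' graph encoding, latent encoding, then conditional decoding with the
#' positional encoding and the perceptual embeddings computed from `image`
#' (defaulting to the dataset's own image). Supplying a perturbed image
#' isolates the effect of histology artifacts on the image-dependent output.
#'
#' @param model a trained [s2ae_model()].
#' @param real [st_dataset] with counts and coordinates.
#' @param image optional replacement H x W x 3 image.
#' @param scales,out_size patch protocol (must match training).
#' @return list: `recon` (spots x G matrix), `target` (the normalised real
#'   expression the decoder was trained against).
#' @export
reconstruct_real <- function(model, real, image = real$image,
                             scales = c(150, 100, 50), out_size = 224) {
  stopifnot(inherits(model, "s2ae_model"), inherits(real, "st_dataset"))
  genes <- model$arch$gene_ids
  expr <- spot_matrix(real$expression$values[, genes, drop = FALSE],
                      real$expression$spot_ids, genes,
                      layer = real$expression$layer)
  X <- as_dense(normalize_expression(expr, model$arch$target_sum %||% 1e4)$values)
  enc_in <- X
  if (isTRUE(model$arch$use_sce)) {
    graph <- build_knn_adjacency(real$coords, k = model$arch$graph_k %||% 5)
    enc_in <- gcn_encode(X, graph, model$gcn)
  }
  latent <- encode_latent(model, enc_in)
  pos <- if (isTRUE(model$arch$use_sce))
    positional_encode(real$coords, model$arch$d_f) else NULL
  fperc <- NULL
  if (!is.null(image)) {
    bank <- spot_token_bank(image, real$coords, scales = scales,
                            out_size = out_size, backend = "stub",
                            n_tokens = 16L, dim = model$arch$d_img)
    fperc <- perceptual_embed(model, bank)
  }
  list(recon = decode_conditional(model, latent, perceptual = fperc, pos = pos),
       target = X)
}
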