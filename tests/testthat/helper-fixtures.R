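# Tiny shared fixtures, built in code at test time.

tiny_ref <- function(seed = 11, n_types = 3, n_genes = 40, n_cells = 120) {
  generate_synthetic_scrna(n_cells = n_cells, n_genes = n_genes,
                           n_types = n_types, marker_fold = 6, base_rate = 1,
                           seed = seed)
}

tiny_coords <- function(n = 9, spacing = 10) {
  g <- expand.grid(x = seq_len(ceiling(sqrt(n))), y = seq_len(ceiling(sqrt(n))))
  g <- g[seq_len(n), ]
  spot_coords(paste0("s", seq_len(n)), g$x * spacing, g$y * spacing)
}

random_coords <- function(n, seed) {
  with_seed(seed, spot_coords(paste0("s", seq_len(n)),
                              runif(n, 0, 100), runif(n, 0, 100)))
}

# brute-force directed KNN: for each row the k nearest others, ties by index
brute_knn <- function(xy, k) {
  n <- nrow(xy)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- sqrt(rowSums((xy - matrix(xy[i, ], n, 2, byrow = TRUE))^2))
    d[i] <- Inf
    ord <- order(d, seq_len(n))
    A[i, ord[seq_len(k)]] <- 1
  }
  A
}

# layer-by-layer reference evaluation of an MLP (independent of mlp_forward)
manual_mlp <- function(x, layers, final = "linear") {
  L <- length(layers)
  for (l in seq_len(L)) {
    x <- x %*% layers[[l]]$W
    for (j in seq_len(ncol(x))) x[, j] <- x[, j] + layers[[l]]$b[j]
    if (l < L) x <- pmax(x, 0)
  }
  if (final == "softmax") {
    for (i in seq_len(nrow(x))) {
      e <- exp(x[i, ] - max(x[i, ])); x[i, ] <- e / sum(e)
    }
  } else if (final == "sigmoid") x <- 1 / (1 + exp(-x))
  x
}

# small random slide + matching datasets for fast end-to-end unit tests
tiny_pipeline_data <- function(seed = 5, n_spots = 60, dim = 6, epochs = 0) {
  ref <- tiny_ref(seed)
  ps <- simulate_pseudospots(ref, pseudospot_config(n_spots, seed = seed + 1))
  slide <- generate_synthetic_slide(dim, dim, spacing_px = 40, n_regions = 3,
                                    image_margin_px = 80, seed = seed + 2)
  real <- simulate_slide_spots(ref, slide, seed = seed + 3)
  list(ref = ref, ps = ps, slide = slide, real = real,
       simulated = pseudospot_dataset(ps))
}
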