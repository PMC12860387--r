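#' Wrap a pseudo-spot set as an st_dataset
#'
#' @param ps a `pseudospot_set` from [simulate_pseudospots()].
#' @return an [st_dataset] carrying expression and proportion labels.
#' @export
pseudospot_dataset <- function(ps) {
  stopifnot(inherits(ps, "pseudospot_set"))
  st_dataset(expression = ps$expression, proportions = ps$proportions)
}

#' Subset an st_dataset to a set of spots
#'
#' @param x an [st_dataset].
#' @param idx integer spot indices to keep.
#' @return the subsetted [st_dataset] (image carried over unchanged).
#' @export
st_subset <- function(x, idx) {
  stopifnot(inherits(x, "st_dataset"))
  expr <- spot_matrix(x$expression$values[idx, , drop = FALSE],
                      x$expression$spot_ids[idx], x$expression$gene_ids,
                      layer = x$expression$layer)
  st_dataset(
    expression = expr,
    coords = if (!is.null(x$coords))
      spot_coords(x$coords$spot_id[idx], x$coords$x[idx], x$coords$y[idx]),
    image = x$image,
    proportions = if (!is.null(x$proportions))
      proportion_matrix(unclass(x$proportions)[idx, , drop = FALSE],
                        colnames(x$proportions),
                        rownames(x$proportions)[idx]),
    pathology = if (!is.null(x$pathology)) {
      m <- unclass(x$pathology)[idx, , drop = FALSE]
      class(m) <- c("pathology_labels", class(m))
      m
    })
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-3, the real-data
#'   default; the simulated-only configuration uses 1e-2).
#' @param epochs number of epochs (>= 0).
#' @param batch_size rows per batch for both domains.
#' @param k_folds fold count of the cross-validation protocol (default 10).
#' @param seed integer seed controlling init and batch order.
#' @param optimizer only `"adam"` is provided.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, epochs = 300, batch_size = 400,
                         k_folds = 10, seed = 1, optimizer = "adam") {
  if (epochs < 0) stop_arg("epochs must be >= 0")
  if (k_folds < 2) stop_arg("k_folds must be >= 2")
  if (batch_size < 1) stop_arg("batch_size must be >= 1")
  if (!identical(optimizer, "adam")) stop_arg("only the adam optimizer is provided")
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, k_folds = k_folds, seed = seed,
                 optimizer = optimizer),
            class = "train_config")
}

#' Random k-fold partition of indices
#'
#' Folds are disjoint, cover every index exactly once and differ in size by
#' at most one; deterministic given the seed.
#'
#' @param n number of items.
#' @param K number of folds (`n >= K`).
#' @param seed integer seed.
#' @return list of `K` integer index vectors.
#' @export
kfold_split <- function(n, K, seed = 1) {
  if (n < K) stop_arg("n (", n, ") must be >= K (", K, ")")
  with_seed(seed, {
    perm <- sample.int(n)
    unname(split(perm, rep_len(seq_len(K), n)))
  })
}

# ---- parameter tree <-> flat list ------------------------------------------

param_skip <- c("arch", "dims", "d_k", "n_heads")

flatten_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    if (nm %in% param_skip) next
    child <- x[[nm]]
    key <- if (prefix == "") nm else paste(prefix, nm, sep = "$")
    if (is.numeric(child)) {
      out[[key]] <- child
    } else if (is.list(child)) {
      nms <- names(child) %||% as.character(seq_along(child))
      names(child) <- nms
      out <- c(out, flatten_params(child, key))
    }
  }
  out
}

assign_path <- function(x, path, val) {
  # numeric path components address unnamed list positions
  p <- path[1]
  key <- if (grepl("^[0-9]+$", p) && !p %in% names(x)) as.integer(p) else p
  if (length(path) == 1L) {
    x[[key]] <- val
    return(x)
  }
  x[[key]] <- assign_path(x[[key]], path[-1], val)
  x
}

unflatten_params <- function(model, flat) {
  for (key in names(flat))
    model <- assign_path(model, strsplit(key, "$", fixed = TRUE)[[1]], flat[[key]])
  model
}

# ---- Adam ------------------------------------------------------------------

adam_state <- function(flat) {
  list(m = lapply(flat, function(v) v * 0),
       v = lapply(flat, function(v) v * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(theta, grads, state, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (key in names(grads)) {
    g <- grads[[key]]
    state$m[[key]] <- b1 * state$m[[key]] + (1 - b1) * g
    state$v[[key]] <- b2 * state$v[[key]] + (1 - b2) * g^2
    mhat <- state$m[[key]] / corr1
    vhat <- state$v[[key]] / corr2
    theta[[key]] <- theta[[key]] - lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(theta = theta, state = state)
}

# ---- training graph helpers ------------------------------------------------

# wrap every flat parameter into a tape leaf; returns nodes keyed like theta
make_param_nodes <- function(tape, theta) {
  lapply(theta, function(v) ad_param(tape, v))
}

# view a flat node list as MLP layer node structure for module `name`
node_layers <- function(nodes, name, n_layers) {
  lapply(seq_len(n_layers), function(l)
    list(W = nodes[[paste0(name, "$", l, "$W")]],
         b = nodes[[paste0(name, "$", l, "$b")]]))
}

collect_grads <- function(nodes) {
  grads <- list()
  for (key in names(nodes)) {
    g <- nodes[[key]]$grad
    if (!is.null(g)) {
      v <- nodes[[key]]$val
      if (!is.matrix(v) && is.matrix(g)) g <- as.vector(g)
      grads[[key]] <- g
    }
  }
  grads
}

# conditioned (or plain) decoder on the tape; pos_c / fperc may be NULL
ad_decode <- function(tape, nodes, latent, arch, pos_c = NULL, fperc = NULL) {
  h <- latent
  for (l in 1:2) {
    if (!is.null(pos_c)) {
      proj <- ad_add_bias(tape, ad_mm(tape, pos_c, nodes[[paste0("pos_proj$", l, "$W")]]),
                          nodes[[paste0("pos_proj$", l, "$b")]])
      h <- ad_add(tape, h, proj)
    }
    if (!is.null(fperc)) {
      v <- ad_mm(tape, fperc, nodes[[paste0("attn$", l, "$W_V")]])
      h <- ad_add(tape, h, ad_mm(tape, v, nodes[[paste0("attn$", l, "$W_O")]]))
    }
    h <- ad_add_bias(tape, ad_mm(tape, h, nodes[[paste0("dec$", l, "$W")]]),
                     nodes[[paste0("dec$", l, "$b")]])
    if (l < 2) h <- ad_relu(tape, h)
  }
  h
}

# perceptual embedding of a batch on the tape
ad_perceptual <- function(tape, nodes, bank, idx, n_scales) {
  pooled <- lapply(seq_len(n_scales), function(s)
    ad_attnpool(tape, bank$tokens[[s]][idx], nodes[[paste0("pool_w$", s)]]))
  ad_mlp(tape, ad_cbind(tape, pooled), node_layers(nodes, "fuse", 2L))
}

#' Jointly train the multitask autoencoder
#'
#' Runs end-to-end optimisation of all modules. Each epoch draws shuffled
#' simulated and real batches and alternates them; a simulated batch
#' contributes the deconvolution loss (and the simulated half of the domain
#' matching loss), a real batch contributes reconstruction (conditioned on
#' positional encoding and, when an image is present, the perceptual
#' embeddings), the auxiliary pathology loss when labels are present, and the
#' real half of the matching loss. One Adam step is taken per batch.
#' Gradients reaching the encoder through the discriminator are reversed and
#' scaled by the model's `grl_coeff`.
#'
#' Preprocessing (identical for both domains): gene alignment on the
#' intersection (optionally top-`n_top` most variable genes of the simulated
#' matrix), library-size normalisation to `target_sum` and `log1p`. The real
#' domain is graph-encoded over the full spot graph (transductive); pass
#' `real_train_idx` to restrict which real spots contribute gradients (used
#' by the cross-validation protocol).
#'
#' @param simulated [st_dataset] with counts and `proportions` labels.
#' @param real [st_dataset] with counts and `coords` (plus optional `image`
#'   and `pathology`).
#' @param cfg a [train_config()].
#' @param w a [loss_weights()].
#' @param model optional pre-built [s2ae_model()]; default is initialised
#'   from the data dimensions and `cfg$seed`.
#' @param n_top most-variable-gene cut (default 3000).
#' @param target_sum library-size normalisation target (default 1e4).
#' @param graph_k KNN neighbour count (default 5).
#' @param use_sce logical; `FALSE` bypasses the graph encoder (real
#'   expression goes to the encoder raw).
#' @param use_sfe logical; `FALSE` drops the image conditioning even when an
#'   image is present.
#' @param scales,out_size histology patch protocol (defaults
#'   `c(150, 100, 50)` and 224).
#' @param verbose print per-epoch losses.
#' @param real_train_idx optional integer subset of real spots allowed to
#'   contribute gradients.
#' @return list of class `s2ae_fit`: `model` (trained, with preprocessing
#'   metadata attached), `history` (per-epoch data.frame of the four losses),
#'   `graph`, `bank` (token bank or NULL).
#' @export
s2ae_fit <- function(simulated, real, cfg, w = loss_weights(), model = NULL,
                     n_top = 3000, target_sum = 1e4, graph_k = 5,
                     use_sce = TRUE, use_sfe = TRUE,
                     scales = c(150, 100, 50), out_size = 224,
                     verbose = FALSE, real_train_idx = NULL) {
  stopifnot(inherits(simulated, "st_dataset"), inherits(real, "st_dataset"),
            inherits(cfg, "train_config"), inherits(w, "loss_weights"))
  if (is.null(simulated$proportions))
    stop_arg("simulated dataset must carry proportion labels")
  if (w$lambda1 > 0 && is.null(real$pathology))
    stop_arg("lambda1 > 0 requires pathology labels on the real dataset")
  aligned <- align_genes(simulated$expression, real$expression, n_top = n_top)
  Xs <- as_dense(normalize_expression(aligned$simulated, target_sum)$values)
  Xr <- as_dense(normalize_expression(aligned$real, target_sum)$values)
  G <- ncol(Xs)
  Yprop <- as.matrix(unclass(simulated$proportions))
  P1 <- ncol(Yprop)
  have_image <- use_sfe && !is.null(real$image) && !is.null(real$coords)
  Yhist <- if (!is.null(real$pathology)) as.matrix(unclass(real$pathology)) else NULL
  P2 <- if (!is.null(Yhist)) ncol(Yhist) else 2L

  if (is.null(model))
    model <- s2ae_model(G, P1, P2, seed = derive_seed(cfg$seed, "model-init"))
  if (model$arch$n_genes != G) stop_arg("model gene dimension != aligned gene space")
  arch <- model$arch

  graph <- NULL
  NXr <- Xr  # encoder input for the real domain
  if (use_sce) {
    if (is.null(real$coords)) stop_arg("use_sce requires real coordinates")
    graph <- build_knn_adjacency(real$coords, k = graph_k)
    NXr <- graph$normalized %*% Xr  # constant part of the GCN forward
  }
  # positional conditioning is part of the spatial-context module, so the
  # no-SCE ablation drops both the graph encoder and the positional injection
  pos <- if (use_sce && !is.null(real$coords))
    positional_encode(real$coords, arch$d_f) else NULL
  bank <- if (have_image)
    spot_token_bank(real$image, real$coords, scales = scales,
                    out_size = out_size, backend = "stub",
                    n_tokens = 16L, dim = arch$d_img)
  else NULL

  theta <- flatten_params(model)
  opt <- adam_state(theta)
  S1 <- nrow(Xs); S2 <- nrow(Xr)
  train_r <- real_train_idx %||% seq_len(S2)
  history <- data.frame(epoch = integer(0), L_deconv = numeric(0),
                        L_hist = numeric(0), L_recon = numeric(0),
                        L_match = numeric(0))
  if (cfg$epochs == 0) {
    model <- attach_fit_meta(model, aligned, target_sum, graph_k, use_sce,
                             colnames(Yprop))
    return(structure(list(model = model, history = history, graph = graph,
                          bank = bank), class = "s2ae_fit"))
  }

  with_seed(derive_seed(cfg$seed, "train-loop"), {
    for (epoch in seq_len(cfg$epochs)) {
      sim_order <- sample(S1)
      real_order <- sample(train_r)
      sim_batches <- split(sim_order, ceiling(seq_along(sim_order) / cfg$batch_size))
      real_batches <- split(real_order, ceiling(seq_along(real_order) / cfg$batch_size))
      # alternate the two domains, longer stream absorbs the tail
      sched <- interleave_batches(length(sim_batches), length(real_batches))
      acc <- c(deconv = 0, hist = 0, recon = 0, match = 0)
      cnt <- c(deconv = 0, hist = 0, recon = 0, match = 0)

      for (step in seq_len(nrow(sched))) {
        domain <- sched$domain[step]
        bidx <- if (domain == "sim") sim_batches[[sched$which[step]]]
                else real_batches[[sched$which[step]]]
        tape <- ad_tape()
        nodes <- make_param_nodes(tape, theta)
        terms <- list(); tw <- numeric(0)

        if (domain == "sim") {
          x <- ad_const(tape, Xs[bidx, , drop = FALSE])
          # the GCN feature transform is shared across domains; without
          # coordinates the graph is self-loops only, so propagation reduces
          # to relu(X W) -- one feature map, two key sets of neighbours
          if (use_sce)
            x <- ad_relu(tape, ad_mm(tape, x, nodes[["gcn$weights$1"]]))
          latent <- ad_mlp(tape, x, node_layers(nodes, "enc", 2L))
          shared <- ad_mlp(tape, latent, node_layers(nodes, "shared", 2L))
          logits <- ad_mlp(tape, shared, node_layers(nodes, "prop_head", 1L))
          l_dec <- ad_softmax_ce(tape, logits, Yprop[bidx, , drop = FALSE])
          terms <- c(terms, list(l_dec)); tw <- c(tw, 1)
          acc["deconv"] <- acc["deconv"] + as.numeric(l_dec$val) / length(bidx)
          cnt["deconv"] <- cnt["deconv"] + 1
          if (w$lambda3 > 0) {
            rev_lat <- ad_grl(tape, latent, arch$grl_coeff)
            zl <- ad_mlp(tape, rev_lat, node_layers(nodes, "disc", 2L))
            l_m <- ad_sigmoid_bce(tape, zl, rep(0, length(bidx)))
            terms <- c(terms, list(l_m)); tw <- c(tw, w$lambda3)
            acc["match"] <- acc["match"] + as.numeric(l_m$val)
            cnt["match"] <- cnt["match"] + 1
          }
        } else {
          enc_in <- if (use_sce) {
            NX <- ad_const(tape, NXr)
            H <- ad_relu(tape, ad_mm(tape, NX, nodes[["gcn$weights$1"]]))
            ad_rows(tape, H, bidx)
          } else {
            ad_const(tape, Xr[bidx, , drop = FALSE])
          }
          latent <- ad_mlp(tape, enc_in, node_layers(nodes, "enc", 2L))
          if (w$lambda2 > 0) {
            pos_c <- if (!is.null(pos)) ad_const(tape, pos[bidx, , drop = FALSE]) else NULL
            fperc <- if (have_image) ad_perceptual(tape, nodes, bank, bidx,
                                                   arch$n_scales) else NULL
            recon <- ad_decode(tape, nodes, latent, arch, pos_c, fperc)
            l_rec <- ad_mse(tape, recon, Xr[bidx, , drop = FALSE], "mean")
            terms <- c(terms, list(l_rec)); tw <- c(tw, w$lambda2)
            acc["recon"] <- acc["recon"] + as.numeric(l_rec$val)
            cnt["recon"] <- cnt["recon"] + 1
          }
          if (w$lambda1 > 0) {
            shared <- ad_mlp(tape, latent, node_layers(nodes, "shared", 2L))
            hl <- ad_mlp(tape, shared, node_layers(nodes, "hist_head", 1L))
            l_h <- ad_softmax_ce(tape, hl, Yhist[bidx, , drop = FALSE])
            terms <- c(terms, list(l_h)); tw <- c(tw, w$lambda1)
            acc["hist"] <- acc["hist"] + as.numeric(l_h$val) / length(bidx)
            cnt["hist"] <- cnt["hist"] + 1
          }
          if (w$lambda3 > 0) {
            rev_lat <- ad_grl(tape, latent, arch$grl_coeff)
            zl <- ad_mlp(tape, rev_lat, node_layers(nodes, "disc", 2L))
            l_m <- ad_sigmoid_bce(tape, zl, rep(1, length(bidx)))
            terms <- c(terms, list(l_m)); tw <- c(tw, w$lambda3)
            acc["match"] <- acc["match"] + as.numeric(l_m$val)
            cnt["match"] <- cnt["match"] + 1
          }
        }
        if (length(terms) == 0) next
        total <- ad_wsum(tape, terms, tw)
        ad_backward(tape, total)
        grads <- collect_grads(nodes)
        upd <- adam_step(theta, grads, opt, cfg$learning_rate)
        theta <- upd$theta; opt <- upd$state
      }
      avg <- ifelse(cnt > 0, acc / pmax(cnt, 1), NA_real_)
      history <- rbind(history, data.frame(
        epoch = epoch, L_deconv = avg["deconv"], L_hist = avg["hist"],
        L_recon = avg["recon"], L_match = avg["match"], row.names = NULL))
      if (verbose)
        message(sprintf("epoch %3d | deconv %.4f | hist %s | recon %s | match %s",
                        epoch, avg["deconv"], format(avg["hist"], digits = 4),
                        format(avg["recon"], digits = 4),
                        format(avg["match"], digits = 4)))
    }
  })
  model <- unflatten_params(model, theta)
  model <- attach_fit_meta(model, aligned, target_sum, graph_k, use_sce,
                           colnames(Yprop))
  structure(list(model = model, history = history, graph = graph, bank = bank),
            class = "s2ae_fit")
}

interleave_batches <- function(n_sim, n_real) {
  sched <- data.frame(domain = character(0), which = integer(0))
  i <- 1L; j <- 1L
  while (i <= n_sim || j <= n_real) {
    if (i <= n_sim) { sched <- rbind(sched, data.frame(domain = "sim", which = i)); i <- i + 1L }
    if (j <= n_real) { sched <- rbind(sched, data.frame(domain = "real", which = j)); j <- j + 1L }
  }
  sched
}

attach_fit_meta <- function(model, aligned, target_sum, graph_k, use_sce,
                            type_names) {
  model$arch$gene_ids <- aligned$simulated$gene_ids
  model$arch$target_sum <- target_sum
  model$arch$graph_k <- graph_k
  model$arch$use_sce <- use_sce
  model$arch$type_names <- type_names
  model
}

#' @export
print.s2ae_fit <- function(x, ...) {
  cat(sprintf("s2ae_fit: %d epochs trained\n", nrow(x$history)))
  print(x$model)
  invisible(x)
}

#' Deconvolve real spots into cell-type proportions
#'
#' Inference path: normalise, graph-encode over the spot KNN graph (when the
#' model was trained with the graph encoder), then encoder -> shared
#' extractor -> proportion head. Rows land on the simplex by construction.
#'
#' @param model a trained [s2ae_model()] (from [s2ae_fit()]).
#' @param real [st_dataset] with counts (and coordinates if the model uses
#'   the graph encoder).
#' @return a [proportion_matrix] with the real spot ids as row names.
#' @export
deconvolve <- function(model, real) {
  stopifnot(inherits(model, "s2ae_model"), inherits(real, "st_dataset"))
  genes <- model$arch$gene_ids
  if (is.null(genes)) stop_arg("model has not been trained (no gene space attached)")
  missing <- setdiff(genes, real$expression$gene_ids)
  if (length(missing) > 0)
    stop_arg("real data lacks ", length(missing), " model genes: ",
             paste(head(missing, 5), collapse = ", "))
  expr <- spot_matrix(real$expression$values[, genes, drop = FALSE],
                      real$expression$spot_ids, genes,
                      layer = real$expression$layer)
  X <- if (expr$layer == "counts")
    as_dense(normalize_expression(expr, model$arch$target_sum %||% 1e4)$values)
  else as_dense(expr$values)
  if (isTRUE(model$arch$use_sce)) {
    if (is.null(real$coords)) stop_arg("model uses the graph encoder; coordinates required")
    graph <- build_knn_adjacency(real$coords, k = model$arch$graph_k %||% 5)
    X <- gcn_encode(X, graph, model$gcn)
  }
  latent <- encode_latent(model, X)
  shared <- shared_extract(model, latent)
  p <- predict_proportions(model, shared)
  rownames(p) <- real$expression$spot_ids
  p
}

#' K-fold cross-validated deconvolution benchmark
#'
#' Real spots are partitioned into `cfg$k_folds` folds; for each fold the
#' model is trained from scratch with the held-out spots contributing no
#' gradient, the held-out spots are predicted once, and the metrics are
#' computed on the concatenation of all fold predictions. The spot graph is
#' kept whole by default (transductive); `inductive_folds = TRUE` rebuilds
#' the graph from the training spots only and held-out spots are predicted
#' with the full-graph encoding at inference.
#'
#' @param simulated,real,cfg,w,... as in [s2ae_fit()].
#' @param truth matrix of true values for evaluation (defaults to
#'   `real$proportions`).
#' @param inductive_folds logical (default `FALSE`, transductive).
#' @return list: `report` ([evaluate_folds()] result), `predictions`
#'   (per-fold list), `folds`.
#' @export
s2ae_cross_validate <- function(simulated, real, cfg, w = loss_weights(),
                                truth = real$proportions,
                                inductive_folds = FALSE, ...) {
  S2 <- nrow(real$expression$values)
  folds <- kfold_split(S2, cfg$k_folds, seed = derive_seed(cfg$seed, "folds"))
  preds <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    hold <- folds[[f]]
    train_idx <- setdiff(seq_len(S2), hold)
    fit <- if (inductive_folds) {
      # rebuild graph/tokens from the training spots only
      s2ae_fit(simulated, st_subset(real, train_idx), cfg, w, ...)
    } else {
      s2ae_fit(simulated, real, cfg, w, real_train_idx = train_idx, ...)
    }
    p <- deconvolve(fit$model, real)
    preds[[f]] <- p[hold, , drop = FALSE]
  }
  report <- if (!is.null(truth))
    evaluate_folds(preds, truth, coords = real$coords)
  else NULL
  list(report = report, predictions = preds, folds = folds)
}
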