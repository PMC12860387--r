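# Minimal tape-based reverse-mode automatic differentiation over dense
# matrices. Nodes are environments recorded on a tape in creation order;
# backward() walks the tape in reverse, accumulating gradients. Only the
# operations the multitask autoencoder needs are provided. Values are plain
# numeric matrices (scalars are 1x1).

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_record <- function(tape, val, bwd = NULL, track = TRUE) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$bwd <- bwd
  nd$track <- track
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_acc <- function(nd, g) {
  if (!nd$track) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# constants never accumulate gradients
ad_const <- function(tape, x) ad_record(tape, x, track = FALSE)

# leaf parameter (matrix or numeric vector)
ad_param <- function(tape, x) ad_record(tape, x, track = TRUE)

ad_backward <- function(tape, root) {
  root$grad <- if (is.matrix(root$val)) matrix(1, 1, 1) else 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bwd)) nd$bwd(nd$grad)
  }
  invisible(NULL)
}

ad_mm <- function(tape, a, b) {
  val <- a$val %*% b$val
  ad_record(tape, val, bwd = function(g) {
    if (a$track) ad_acc(a, g %*% t(b$val))
    if (b$track) ad_acc(b, t(a$val) %*% g)
  }, track = a$track || b$track)
}

ad_add <- function(tape, a, b) {
  ad_record(tape, a$val + b$val, bwd = function(g) {
    ad_acc(a, g); ad_acc(b, g)
  }, track = a$track || b$track)
}

# add a bias (numeric vector) to every row
ad_add_bias <- function(tape, a, b) {
  ad_record(tape, sweep(a$val, 2L, b$val, `+`), bwd = function(g) {
    ad_acc(a, g)
    ad_acc(b, colSums(g))
  }, track = a$track || b$track)
}

ad_relu <- function(tape, a) {
  mask <- a$val > 0
  ad_record(tape, a$val * mask, bwd = function(g) ad_acc(a, g * mask),
            track = a$track)
}

ad_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$val))
  ad_record(tape, s, bwd = function(g) ad_acc(a, g * s * (1 - s)),
            track = a$track)
}

ad_softmax_rows <- function(tape, a) {
  p <- softmax_rows(a$val)
  ad_record(tape, p, bwd = function(g) {
    ad_acc(a, p * (g - rowSums(g * p)))
  }, track = a$track)
}

ad_scale <- function(tape, a, k) {
  ad_record(tape, k * a$val, bwd = function(g) ad_acc(a, k * g),
            track = a$track)
}

# gradient reversal layer: identity forward, -coeff * gradient backward
ad_grl <- function(tape, a, coeff) {
  ad_record(tape, a$val, bwd = function(g) ad_acc(a, -coeff * g),
            track = a$track)
}

ad_rows <- function(tape, a, idx) {
  ad_record(tape, a$val[idx, , drop = FALSE], bwd = function(g) {
    full <- matrix(0, nrow(a$val), ncol(a$val))
    full[idx, ] <- full[idx, ] + g
    ad_acc(a, full)
  }, track = a$track)
}

ad_cbind <- function(tape, parts) {
  widths <- vapply(parts, function(p) ncol(p$val), integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  ad_record(tape, do.call(cbind, lapply(parts, `[[`, "val")), bwd = function(g) {
    for (j in seq_along(parts))
      ad_acc(parts[[j]], g[, starts[j]:ends[j], drop = FALSE])
  }, track = any(vapply(parts, `[[`, logical(1), "track")))
}

# categorical cross-entropy, summed over all rows: -sum(Y * log(clamp(p)))
ad_ce_sum <- function(tape, p, Y, eps = 1e-12) {
  pc <- pmax(p$val, eps)
  val <- -sum(Y * log(pc))
  ad_record(tape, val, bwd = function(g) {
    ad_acc(p, -as.numeric(g) * Y / pc)
  }, track = p$track)
}

# fused softmax + categorical cross-entropy on logits: numerically stable,
# with the exact gradient P - Y (no clamp saturation)
ad_softmax_ce <- function(tape, logits, Y) {
  z <- logits$val
  zmax <- apply(z, 1L, max)
  lse <- log(rowSums(exp(z - zmax))) + zmax
  logp <- z - lse
  P <- exp(logp)
  val <- -sum(Y * logp)
  ad_record(tape, val, bwd = function(g) {
    ad_acc(logits, as.numeric(g) * (P * rowSums(Y) - Y))
  }, track = logits$track)
}

# fused sigmoid + binary cross-entropy on logits, averaged over rows;
# gradient (sigma(z) - c) / B
ad_sigmoid_bce <- function(tape, logits, cvec) {
  z <- as.vector(logits$val)
  B <- length(z)
  # stable log(1 + exp(-|z|)) formulation
  val <- sum(pmax(z, 0) - z * cvec + log1p(exp(-abs(z)))) / B
  s <- 1 / (1 + exp(-z))
  ad_record(tape, val, bwd = function(g) {
    ad_acc(logits, matrix(as.numeric(g) * (s - cvec) / B, B, 1))
  }, track = logits$track)
}

# mean or summed squared error against a constant target
ad_mse <- function(tape, a, target, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  diff <- a$val - target
  n <- if (reduction == "mean") length(diff) else 1
  val <- sum(diff^2) / n
  ad_record(tape, val, bwd = function(g) {
    ad_acc(a, as.numeric(g) * 2 * diff / n)
  }, track = a$track)
}

# binary cross-entropy of probabilities p (column) against indicators c,
# averaged over the rows: -(1/B) sum [c log p + (1-c) log(1-p)]
ad_bce <- function(tape, p, cvec, eps = 1e-12) {
  pc <- pmin(pmax(p$val, eps), 1 - eps)
  B <- length(pc)
  val <- -sum(cvec * log(pc) + (1 - cvec) * log(1 - pc)) / B
  ad_record(tape, val, bwd = function(g) {
    ad_acc(p, as.numeric(g) * (-(cvec / pc) + (1 - cvec) / (1 - pc)) / B)
  }, track = p$track)
}

# weighted sum of scalar nodes: sum_i w_i * s_i
ad_wsum <- function(tape, nodes, weights) {
  val <- sum(mapply(function(nd, w) w * as.numeric(nd$val), nodes, weights))
  ad_record(tape, val, bwd = function(g) {
    for (j in seq_along(nodes)) ad_acc(nodes[[j]], as.numeric(g) * weights[j])
  }, track = any(vapply(nodes, `[[`, logical(1), "track")))
}

# batched self-attention pooling over constant token matrices with a
# learnable pooling weight vector w: per spot b,
#   s_b = T_b w / sqrt(d); alpha_b = softmax(s_b); out_b = alpha_b^T T_b
ad_attnpool <- function(tape, tokens, w) {
  d <- length(w$val)
  B <- length(tokens)
  sq <- sqrt(d)
  alphas <- vector("list", B)
  out <- matrix(0, B, d)
  for (b in seq_len(B)) {
    s <- as.vector(tokens[[b]] %*% w$val) / sq
    a <- exp(s - max(s)); a <- a / sum(a)
    alphas[[b]] <- a
    out[b, ] <- crossprod(tokens[[b]], a)
  }
  ad_record(tape, out, bwd = function(g) {
    dw <- numeric(d)
    for (b in seq_len(B)) {
      gb <- g[b, ]
      da <- as.vector(tokens[[b]] %*% gb)
      a <- alphas[[b]]
      ds <- a * (da - sum(da * a))
      dw <- dw + as.vector(crossprod(tokens[[b]], ds)) / sq
    }
    ad_acc(w, dw)
  }, track = w$track)
}

# forward an MLP given ad-node layer parameters: list(list(W=, b=), ...)
ad_mlp <- function(tape, x, layer_nodes, final = c("linear", "relu", "softmax", "sigmoid")) {
  final <- match.arg(final)
  L <- length(layer_nodes)
  for (l in seq_len(L)) {
    x <- ad_add_bias(tape, ad_mm(tape, x, layer_nodes[[l]]$W), layer_nodes[[l]]$b)
    if (l < L) x <- ad_relu(tape, x)
  }
  switch(final,
         linear = x,
         relu = ad_relu(tape, x),
         softmax = ad_softmax_rows(tape, x),
         sigmoid = ad_sigmoid(tape, x))
}
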