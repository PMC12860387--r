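small_model <- function(seed = 3) {
  s2ae_model(n_genes = 20, n_types = 3, n_classes = 2, d_f = 16, d_s = 8,
             hidden = 24, d_img = 6, d_k = 4, n_heads = 2, seed = seed)
}

test_that("the encoder is a deterministic MLP with the expected identities", {
  m <- small_model()
  # zero input with zero biases gives a zero latent
  m0 <- m
  for (l in 1:2) m0$enc[[l]]$b <- m0$enc[[l]]$b * 0
  expect_equal(encode_latent(m0, matrix(0, 4, 20)), matrix(0, 4, 16))

  with_seed(1, X <- matrix(rnorm(3 * 20), 3, 20))
  lat <- encode_latent(m, X)
  # duplicate rows give duplicate latents
  lat2 <- encode_latent(m, X[c(1, 1, 2), ])
  expect_equal(lat2[1, ], lat2[2, ])
  # manual layer-by-layer oracle
  expect_lt(max(abs(lat - manual_mlp(X, m$enc))), 1e-6)
  expect_error(encode_latent(m, matrix(0, 2, 7)), "expects G")
})

test_that("positional encoding is sinusoidal over normalised coordinates", {
  co <- spot_coords(c("a", "b", "c"), c(0, 5, 10), c(0, 0, 10))
  pe <- positional_encode(co, dim = 16)
  expect_equal(dim(pe), c(3, 16))
  expect_true(all(pe >= -1 & pe <= 1))
  # normalised coordinate 0: all sin bands 0, all cos bands 1
  expect_true(all(abs(pe[1, seq(1, 16, 2)]) < 1e-12))
  expect_true(all(abs(pe[1, seq(2, 16, 2)] - 1) < 1e-12))
  # identical coordinates, identical encodings
  co2 <- spot_coords(c("a", "b"), c(3, 3), c(4, 4))
  pe2 <- positional_encode(co2, 8)
  expect_equal(pe2[1, ], pe2[2, ])
  # base band at normalised x = 0.5 is sin(0.5) / cos(0.5)
  pe3 <- positional_encode(spot_coords(letters[1:3], c(0, 5, 10), c(0, 1, 2)), 8)
  expect_equal(pe3[2, 1], sin(0.5))
  expect_equal(pe3[2, 2], cos(0.5))
  expect_error(positional_encode(co, 7), "even")
})

test_that("the unconditioned decoder matches a manual forward oracle", {
  m <- small_model(5)
  with_seed(2, lat <- matrix(rnorm(4 * 16), 4, 16))
  out <- decode_conditional(m, lat)
  expect_equal(dim(out), c(4, 20))
  expect_lt(max(abs(out - manual_mlp(lat, m$dec))), 1e-6)
})

test_that("zero-value attention projections reduce to the unconditioned decode", {
  m <- small_model(6)
  for (l in 1:2) m$attn[[l]]$W_V <- m$attn[[l]]$W_V * 0
  with_seed(3, {
    lat <- matrix(rnorm(5 * 16), 5, 16)
    fperc <- matrix(rnorm(5 * 6), 5, 6)
  })
  expect_equal(decode_conditional(m, lat, perceptual = fperc),
               decode_conditional(m, lat))
  # non-zero conditioning changes the output
  m2 <- small_model(6)
  expect_false(isTRUE(all.equal(decode_conditional(m2, lat, perceptual = fperc),
                                decode_conditional(m2, lat))))
  expect_error(decode_conditional(m2, lat, perceptual = fperc[1:2, ]),
               "aligned")
})

test_that("positional injection is an additive learnable projection", {
  m <- small_model(7)
  co <- tiny_coords(5)
  pos <- positional_encode(co, 16)
  with_seed(4, lat <- matrix(rnorm(5 * 16), 5, 16))
  out <- decode_conditional(m, lat, pos = pos)
  # zeroing the projections recovers the plain decode
  m0 <- m
  for (l in 1:2) m0$pos_proj[[l]]$W <- m0$pos_proj[[l]]$W * 0
  expect_equal(decode_conditional(m0, lat, pos = pos),
               decode_conditional(m, lat))
  expect_false(isTRUE(all.equal(out, decode_conditional(m, lat))))
})

test_that("prediction heads are row-softmax with the standard identities", {
  m <- small_model(8)
  # zero logits -> uniform rows
  m0 <- m
  m0$prop_head[[1]]$W <- m0$prop_head[[1]]$W * 0
  m0$prop_head[[1]]$b <- m0$prop_head[[1]]$b * 0
  with_seed(5, sh <- matrix(rnorm(4 * 8), 4, 8))
  expect_equal(unname(unclass(predict_proportions(m0, sh))),
               matrix(1 / 3, 4, 3))
  # shift invariance of the softmax: adding a constant to all logits
  m1 <- m; m1$prop_head[[1]]$b <- m1$prop_head[[1]]$b + 5
  expect_equal(unclass(predict_proportions(m1, sh)),
               unclass(predict_proportions(m, sh)), tolerance = 1e-12)
  # random logits match a direct softmax evaluation
  logits <- manual_mlp(sh, m$prop_head)
  direct <- exp(logits - apply(logits, 1, max))
  direct <- direct / rowSums(direct)
  expect_lt(max(abs(unclass(predict_proportions(m, sh)) - direct)), 1e-7)
  # pathology head shares the same structure
  ph <- predict_pathology(m, sh)
  expect_true(all(abs(rowSums(ph) - 1) < 1e-9))
  expect_true(all(ph > 0 & ph < 1))
})

test_that("the discriminator forward pass is GRL-invariant and strictly inside (0,1)", {
  m <- small_model(9)
  with_seed(6, lat <- matrix(rnorm(10 * 16), 10, 16))
  p0 <- grl_discriminate(m, lat, grl_coeff = 0)
  p1 <- grl_discriminate(m, lat, grl_coeff = 1)
  expect_identical(p0, p1)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_error(grl_discriminate(m, lat, grl_coeff = -1), "grl_coeff")
})

test_that("gradients through the reversal layer equal minus coeff times the plain gradients", {
  m <- small_model(10)
  with_seed(7, lat <- matrix(rnorm(10 * 16), 10, 16))
  cvec <- rep(c(1, 0), 5)
  bce_fwd <- function(latmat) {
    p <- grl_discriminate(m, latmat)
    -mean(cvec * log(p) + (1 - cvec) * log(1 - p))
  }
  # finite-difference gradient of the unreversed loss at a few entries
  probe <- rbind(c(1, 1), c(3, 7), c(10, 16), c(5, 2))
  for (coeff in c(0.5, 1, 2)) {
    tape <- spotmix:::ad_tape()
    lat_nd <- spotmix:::ad_param(tape, lat)
    rev_nd <- spotmix:::ad_grl(tape, lat_nd, coeff)
    layer_nodes <- lapply(m$disc, function(l)
      list(W = spotmix:::ad_const(tape, l$W), b = spotmix:::ad_const(tape, l$b)))
    p_nd <- spotmix:::ad_mlp(tape, rev_nd, layer_nodes, final = "sigmoid")
    loss <- spotmix:::ad_bce(tape, p_nd, cvec)
    spotmix:::ad_backward(tape, loss)
    for (r in seq_len(nrow(probe))) {
      i <- probe[r, 1]; j <- probe[r, 2]
      eps <- 1e-5
      lp <- lat; lp[i, j] <- lp[i, j] + eps
      lm <- lat; lm[i, j] <- lm[i, j] - eps
      fd <- (bce_fwd(lp) - bce_fwd(lm)) / (2 * eps)
      expect_lt(abs(lat_nd$grad[i, j] - (-coeff * fd)), 1e-4)
    }
  }
})

test_that("checkpoints round-trip bit-stably", {
  m <- small_model(11)
  m$arch$gene_ids <- paste0("g", 1:20)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_identical(load_model(path), m)
})
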