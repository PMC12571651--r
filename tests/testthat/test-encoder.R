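# the encoder is the frozen-backbone + adapter stack used by train_loop();
# these tests pin its forward pass to the exported adapter operations and
# its hand-derived backward pass to finite differences

ns <- asNamespace("radalign")

test_that("encoder block forward equals the exported Transformer-Adapt ops", {
  enc <- build_encoder("image", h = 8, depth = 1, d = 2, input_dim = 6,
                       max_tokens = 16, seed = 2)
  bp <- enc$params$blocks$b1
  set.seed(1)
  X <- matrix(rnorm(5 * 8), 5, 8)
  got <- ns$block_forward_cached(X, bp, keep_cache = TRUE)
  # recompute via the public operation contract
  K <- nrow(X)
  M <- X + matrix(drop(colMeans(X) %*% bp$mix), K, 8, byrow = TRUE)
  r <- pmax(M %*% bp$ffn1$W + matrix(bp$ffn1$b, K, 16, byrow = TRUE), 0) %*%
    bp$ffn2$W + matrix(bp$ffn2$b, K, 8, byrow = TRUE)
  h_l <- M + r
  want <- transformer_adapt_layer(layer_state(h_l, r), bp$la, bp$ta,
                                  gain = bp$ln$gain, shift = bp$ln$shift)
  expect_equal(got$out, want, tolerance = 1e-12)
})

test_that("encoder forward applies the reversible adapter at the embeddings", {
  enc <- build_encoder("image", h = 8, depth = 1, d = 2, input_dim = 6,
                       max_tokens = 16, seed = 2)
  X <- matrix(rnorm(3 * 6), 3, 6)
  emb <- X %*% enc$params$embed$W +
    matrix(enc$params$embed$b, 3, 8, byrow = TRUE) +
    enc$params$pos[1:3, ]
  fwd <- encoder_forward(enc, X, keep_cache = TRUE)
  # invert the cached coupling output back to the embeddings
  rev_out <- cbind(fwd$cache$rev$o1,
                   fwd$cache$rev$e2 +
                     ns$bottleneck_branch(fwd$cache$rev$o1,
                                          list(D = enc$params$rev$D_G,
                                               U = enc$params$rev$U_G)))
  expect_equal(reversible_inverse(rev_out, enc$params$rev), emb,
               tolerance = 1e-9)
})

test_that("full-pipeline adapter gradients match finite differences", {
  model <- toy_model(seed = 3)
  set.seed(42)
  inputs <- list(frontal = matrix(rnorm(5 * 256), 5, 256),
                 lateral = matrix(rnorm(4 * 256), 4, 256),
                 txt_ids = c(5L, 9L, 33L, 2L, 60L))
  loss_fn <- function(m) {
    e <- ns$encode_pair_cached(m, inputs, n_locals = 3)
    total_loss(e$img, e$txt, lambda1 = 0.8)$total
  }
  enc <- ns$encode_pair_cached(model, inputs, n_locals = 3, keep_cache = TRUE)
  gg <- global_alignment_loss_grad(enc$img$global_vec, enc$txt$global_vec)
  gl <- ns$local_alignment_loss_grad(enc$img$locals, enc$txt$locals)
  grads <- ns$pair_backward(model, enc, gg$d_img, gg$d_txt,
                            0.8 * gl$d_img, 0.8 * gl$d_txt)
  flat <- ns$model_flat_params(model)
  eps <- 1e-6
  probe <- c("img/rev/D_F/W", "img/blocks/b1/la/D/W", "img/blocks/b2/ta/U/W",
             "img/blocks/b1/ln/gain", "txt/rev/U_G/b", "txt/blocks/b2/ln/shift",
             "txt/blocks/b1/ta/D/b", "txt/blocks/b2/la/U/W")
  set.seed(1)
  for (nm in probe) {
    p <- flat[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      up <- p; up[i] <- up[i] + eps
      dn <- p; dn[i] <- dn[i] - eps
      num <- (loss_fn(ns$set_flat_param(model, nm, up)) -
                loss_fn(ns$set_flat_param(model, nm, dn))) / (2 * eps)
      expect_lt(abs(num - grads[[nm]][i]) / max(1, abs(num)), 1e-5)
    }
  }
})

test_that("contrastive-objective gradients match finite differences", {
  model <- toy_model(seed = 4)
  set.seed(2)
  ins <- lapply(1:3, function(b)
    list(frontal = matrix(rnorm(4 * 256), 4, 256), lateral = NULL,
         txt_ids = sample(1:63, 6)))
  closs <- function(m) {
    IG <- do.call(rbind, lapply(ins, function(x)
      ns$encode_pair_cached(m, x, n_locals = 2)$img$global_vec))
    TG <- do.call(rbind, lapply(ins, function(x)
      ns$encode_pair_cached(m, x, n_locals = 2)$txt$global_vec))
    batch_contrastive_loss(IG, TG, 0.5)
  }
  encs <- lapply(ins, function(x)
    ns$encode_pair_cached(model, x, n_locals = 2, keep_cache = TRUE))
  IG <- do.call(rbind, lapply(encs, function(e) e$img$global_vec))
  TG <- do.call(rbind, lapply(encs, function(e) e$txt$global_vec))
  cg <- ns$batch_contrastive_loss_grad(IG, TG, 0.5)
  grads <- NULL
  for (b in 1:3) {
    g <- ns$pair_backward(model, encs[[b]], cg$d_img[b, ], cg$d_txt[b, ])
    grads <- if (is.null(grads)) g else ns$flat_add(grads, g)
  }
  flat <- ns$model_flat_params(model)
  eps <- 1e-6
  set.seed(3)
  for (nm in c("img/rev/D_G/W", "img/blocks/b2/ta/U/W",
               "txt/blocks/b1/la/D/W", "img/blocks/b2/ln/gain")) {
    p <- flat[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      up <- p; up[i] <- up[i] + eps
      dn <- p; dn[i] <- dn[i] - eps
      num <- (closs(ns$set_flat_param(model, nm, up)) -
                closs(ns$set_flat_param(model, nm, dn))) / (2 * eps)
      expect_lt(abs(num - grads[[nm]][i]) / max(1, abs(num)), 1e-5)
    }
  }
})

test_that("text encoder rejects out-of-range ids and over-long sequences", {
  enc <- build_encoder("text", h = 8, depth = 1, d = 2, vocab_size = 64,
                       max_tokens = 4, seed = 1)
  expect_error(encoder_forward(enc, c(1L, 64L)), "out of range")
  expect_error(encoder_forward(enc, rep(1L, 5)), "exceeds max_tokens")
})
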