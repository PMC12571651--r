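# Toy frozen encoder backbones with trainable adapters.
#
# Each encoder embeds its tokens (image patches through an affine map,
# text ids through an embedding table), adds position embeddings, applies
# one reversible adapter row-wise, then `depth` blocks of:
#   mixing   M   = X + 1 (colMeans(X) W_mix)        (global token mixing)
#   FFN      r_l = ReLU(M W1 + b1) W2 + b2          (feed-forward residual)
#   hidden   h_l = M + r_l                          (layer output)
#   adapters X'  = LN(TA(LA(h_l, r_l), r_l))        (Transformer-Adapt)
# The backbone (embed/pos/mix/FFN) is frozen; the adapter families
# (rev, la, ta, ln) are the trainable surface. Gradients are derived by
# hand so no autodiff framework is required; every backward pass is
# checked against finite differences in the test suite.

#' Build one toy encoder
#'
#' @param modality `"image"` (affine patch embedding of `input_dim`) or
#'   `"text"` (embedding table of `vocab_size` rows; id 0 = PAD is dropped
#'   before encoding).
#' @param h hidden dimension (divisible by 4).
#' @param depth number of blocks.
#' @param d adapter bottleneck dimension.
#' @param input_dim patch vector length (image modality).
#' @param vocab_size vocabulary size (text modality).
#' @param max_tokens maximum sequence length (position table size).
#' @param ffn_mult FFN expansion factor.
#' @param use_bias adapters carry biases.
#' @param seed initialization seed.
#' @return Object of class `radalign_encoder`.
#' @export
build_encoder <- function(modality = c("image", "text"), h = 32L, depth = 2L,
                          d = 8L, input_dim = 256L, vocab_size = 512L,
                          max_tokens = 512L, ffn_mult = 2L, use_bias = TRUE,
                          seed = 1L) {
  modality <- match.arg(modality)
  h <- as.integer(h); depth <- as.integer(depth); d <- as.integer(d)
  stopifnot(h %% 4L == 0L, depth >= 1L, d >= 1L, d < h)
  mh <- h * as.integer(ffn_mult)
  params <- with_seed(mix_seed(seed, modality, "backbone"), {
    p <- list()
    p$embed <- if (modality == "image") {
      e <- affine_new(input_dim, h, TRUE)
      e$W[] <- rnorm(length(e$W), sd = sqrt(2 / input_dim)); e
    } else {
      matrix(rnorm(vocab_size * h, sd = 0.5), vocab_size, h)
    }
    p$pos <- matrix(rnorm(max_tokens * h, sd = 0.1), max_tokens, h)
    p$blocks <- lapply(seq_len(depth), function(l) {
      W1 <- affine_new(h, mh, TRUE); W2 <- affine_new(mh, h, TRUE)
      W1$W[] <- rnorm(length(W1$W), sd = sqrt(2 / h))
      W2$W[] <- rnorm(length(W2$W), sd = sqrt(1 / mh))
      list(mix = matrix(rnorm(h * h, sd = sqrt(1 / h)), h, h),
           ffn1 = W1, ffn2 = W2)
    })
    p
  })
  names(params$blocks) <- paste0("b", seq_len(depth))
  # trainable adapter families
  params$rev <- he_init(reversible_adapter(h, use_bias),
                        mix_seed(seed, modality, "rev"))
  for (l in seq_len(depth)) {
    blk <- names(params$blocks)[l]
    params$blocks[[blk]]$la <- he_init(
      bottleneck_adapter(h, d, "language", use_bias),
      mix_seed(seed, modality, "la", l))
    params$blocks[[blk]]$ta <- he_init(
      bottleneck_adapter(h, d, "task", use_bias),
      mix_seed(seed, modality, "ta", l))
    params$blocks[[blk]]$ln <- list(gain = rep(1, h), shift = rep(0, h))
  }
  structure(list(modality = modality, h = h, depth = depth, d = d,
                 input_dim = input_dim, vocab_size = vocab_size,
                 max_tokens = max_tokens, mh = mh, use_bias = use_bias,
                 params = params),
            class = "radalign_encoder")
}

ln_eps <- 1e-6

# forward pass over K tokens; input: K x input_dim matrix (image) or
# integer id vector with pads already removed (text)
encoder_forward <- function(enc, input, keep_cache = FALSE) {
  p <- enc$params
  if (enc$modality == "image") {
    X0 <- affine_apply(input, p$embed)
  } else {
    ids <- as.integer(input)
    if (any(ids < 1L | ids >= enc$vocab_size))
      stop("token id out of range [1, vocab_size)", call. = FALSE)
    X0 <- p$embed[ids + 1L, , drop = FALSE]  # row 1 reserved for PAD (id 0)
  }
  K <- nrow(X0)
  if (K > enc$max_tokens)
    stop("sequence of ", K, " tokens exceeds max_tokens ", enc$max_tokens,
         call. = FALSE)
  X <- X0 + p$pos[seq_len(K), , drop = FALSE]
  rev_cache <- NULL
  fwd <- rev_forward_cached(X, p$rev)
  X <- fwd$out
  if (keep_cache) rev_cache <- fwd$cache
  blocks <- vector("list", enc$depth)
  for (l in seq_len(enc$depth)) {
    bp <- p$blocks[[l]]
    res <- block_forward_cached(X, bp, keep_cache)
    X <- res$out
    if (keep_cache) blocks[[l]] <- res$cache
  }
  list(tokens = X,
       cache = if (keep_cache) list(rev = rev_cache, blocks = blocks,
                                    K = K) else NULL)
}

rev_forward_cached <- function(X, rv) {
  half <- rv$h %/% 2L
  e1 <- X[, seq_len(half), drop = FALSE]
  e2 <- X[, half + seq_len(half), drop = FALSE]
  zF <- affine_apply(e2, rv$D_F)
  o1 <- affine_apply(relu(zF), rv$U_F) + e1
  zG <- affine_apply(o1, rv$D_G)
  o2 <- affine_apply(relu(zG), rv$U_G) + e2
  list(out = cbind(o1, o2),
       cache = list(e2 = e2, zF = zF, o1 = o1, zG = zG))
}

block_forward_cached <- function(X, bp, keep_cache = FALSE) {
  K <- nrow(X)
  ctx <- colMeans(X) %*% bp$mix                     # 1 x h
  M <- X + rep_row(drop(ctx), K)
  z1 <- affine_apply(M, bp$ffn1)
  r <- affine_apply(relu(z1), bp$ffn2)
  h_l <- M + r
  z_la <- affine_apply(h_l, bp$la$D)
  la_out <- affine_apply(relu(z_la), bp$la$U) + r
  z_ta <- affine_apply(la_out, bp$ta$D)
  ta_out <- affine_apply(relu(z_ta), bp$ta$U) + r
  mu <- rowMeans(ta_out)
  cen <- ta_out - mu
  sig <- sqrt(rowMeans(cen^2) + ln_eps)
  xhat <- cen / sig
  out <- xhat * rep_row(bp$ln$gain, K) + rep_row(bp$ln$shift, K)
  list(out = out,
       cache = if (keep_cache)
         list(X = X, M = M, z1 = z1, h_l = h_l, z_la = z_la,
              la_out = la_out, z_ta = z_ta, xhat = xhat, sig = sig) else NULL)
}

zero_like_affine <- function(a) {
  list(W = a$W * 0, b = if (!is.null(a$b)) a$b * 0 else NULL)
}

# backward through one bottleneck branch out = ReLU(A D + bD) U + bU
# given dOut; returns input gradient and parameter gradients
bottleneck_backward <- function(A, z, params, dOut) {
  a <- relu(z)
  dU_W <- t(a) %*% dOut
  dU_b <- if (!is.null(params$U$b)) colSums(dOut) else NULL
  dz <- (dOut %*% t(params$U$W)) * (z > 0)
  dD_W <- t(A) %*% dz
  dD_b <- if (!is.null(params$D$b)) colSums(dz) else NULL
  list(dA = dz %*% t(params$D$W),
       grads = list(D = list(W = dD_W, b = dD_b),
                    U = list(W = dU_W, b = dU_b)))
}

# backward through a block given dY (gradient of the block output);
# returns dX and adapter-family gradients (la, ta, ln)
block_backward <- function(bp, cache, dY) {
  K <- nrow(dY)
  gain_m <- rep_row(bp$ln$gain, K)
  dgain <- colSums(dY * cache$xhat)
  dshift <- colSums(dY)
  dxhat <- dY * gain_m
  dta_out <- (dxhat - rowMeans(dxhat) -
                cache$xhat * rowMeans(dxhat * cache$xhat)) / cache$sig
  ta_b <- bottleneck_backward(cache$la_out, cache$z_ta, bp$ta, dta_out)
  dla_out <- ta_b$dA
  dr <- dta_out                                   # TA residual path
  la_b <- bottleneck_backward(cache$h_l, cache$z_la, bp$la, dla_out)
  dh_l <- la_b$dA
  dr <- dr + dla_out                              # LA residual path
  dM <- dh_l
  dr <- dr + dh_l                                 # h_l = M + r
  # frozen FFN
  da1 <- dr %*% t(bp$ffn2$W)
  dz1 <- da1 * (cache$z1 > 0)
  dM <- dM + dz1 %*% t(bp$ffn1$W)
  # frozen mixing: M = X + 1 (colMeans(X) W_mix)
  dctx <- colSums(dM) %*% t(bp$mix)               # 1 x h
  dX <- dM + rep_row(drop(dctx) / K, K)
  list(dX = dX,
       grads = list(la = la_b$grads, ta = ta_b$grads,
                    ln = list(gain = dgain, shift = dshift)))
}

rev_backward <- function(rv, cache, dOut) {
  half <- rv$h %/% 2L
  do1 <- dOut[, seq_len(half), drop = FALSE]
  do2 <- dOut[, half + seq_len(half), drop = FALSE]
  gb <- bottleneck_backward(cache$o1, cache$zG,
                            list(D = rv$D_G, U = rv$U_G), do2)
  do1_tot <- do1 + gb$dA
  de1 <- do1_tot
  fb <- bottleneck_backward(cache$e2, cache$zF,
                            list(D = rv$D_F, U = rv$U_F), do1_tot)
  de2 <- do2 + fb$dA
  list(dX = cbind(de1, de2),
       grads = list(D_F = fb$grads$D, U_F = fb$grads$U,
                    D_G = gb$grads$D, U_G = gb$grads$U))
}

# full encoder backward: dTokens is the gradient w.r.t. the final token
# matrix; returns nested adapter gradients mirroring the parameter tree
encoder_backward <- function(enc, cache, dTokens) {
  p <- enc$params
  dX <- dTokens
  grads <- list(blocks = stats::setNames(vector("list", enc$depth),
                                         names(p$blocks)))
  for (l in rev(seq_len(enc$depth))) {
    bb <- block_backward(p$blocks[[l]], cache$blocks[[l]], dX)
    dX <- bb$dX
    grads$blocks[[l]] <- bb$grads
  }
  rb <- rev_backward(p$rev, cache$rev, dX)
  grads$rev <- rb$grads
  grads
}
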