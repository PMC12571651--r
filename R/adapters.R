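#' Adapter configuration
#'
#' Bundles the hyperparameters shared by the adapter stack: the encoder
#' hidden dimension `h`, the bottleneck down-projection dimension `d`, the
#' local-alignment loss weight `lambda1` and the image patch masking rate.
#' Defaults follow the published hyperparameter table (h = 768, d = 64,
#' lambda1 = 0.8, 75% masking).
#'
#' The reversible adapter splits the hidden vector into two halves and
#' projects each half to a quarter of `h`, so `h` must be divisible by 4.
#'
#' @param h hidden dimension (positive integer, divisible by 4).
#' @param d bottleneck dimension (positive integer, `d < h`).
#' @param use_bias whether affine maps carry bias terms.
#' @param lambda1 nonnegative weight of the local alignment loss.
#' @param mask_rate patch masking fraction in `[0, 1)`.
#' @return An object of class `adapter_config`.
#' @export
#' @examples
#' cfg <- adapter_config(h = 8, d = 2)
#' cfg$lambda1
adapter_config <- function(h = 768L, d = 64L, use_bias = TRUE,
                           lambda1 = 0.8, mask_rate = 0.75) {
  h <- as.integer(h); d <- as.integer(d)
  if (h <= 0L || h %% 4L != 0L)
    stop("h must be a positive integer divisible by 4, got ", h, call. = FALSE)
  if (d <= 0L || d >= h)
    stop("d must satisfy 0 < d < h, got d=", d, " h=", h, call. = FALSE)
  if (lambda1 < 0) stop("lambda1 must be nonnegative", call. = FALSE)
  if (mask_rate < 0 || mask_rate >= 1)
    stop("mask_rate must lie in [0, 1), got ", mask_rate, call. = FALSE)
  structure(list(h = h, d = d, use_bias = isTRUE(use_bias),
                 lambda1 = lambda1, mask_rate = mask_rate),
            class = "adapter_config")
}

# ---- affine map primitive (input_dim -> output_dim), weights stored in x out
affine_new <- function(in_dim, out_dim, use_bias = TRUE) {
  list(W = matrix(0, in_dim, out_dim),
       b = if (use_bias) numeric(out_dim) else NULL)
}

affine_apply <- function(X, a) {
  if (ncol(X) != nrow(a$W))
    stop_shape("affine input", nrow(a$W), ncol(X))
  Y <- X %*% a$W
  if (!is.null(a$b)) Y <- Y + rep_row(a$b, nrow(X))
  Y
}

#' Reversible adapter parameters
#'
#' Allocates the four affine maps of a coupling-structured invertible
#' adapter. The input vector of dimension `h` is split into halves
#' `e1, e2`; two bottleneck nonlinearities `F(x) = U_F ReLU(D_F x)` and
#' `G(x) = U_G ReLU(D_G x)` act on half-vectors, each projecting
#' `h/2 -> h/4 -> h/2`. Weights are allocated at zero; use [he_init()].
#'
#' @param h hidden dimension, divisible by 4.
#' @param use_bias include bias terms (zero-initialized).
#' @return Object of class `reversible_adapter`.
#' @seealso [reversible_forward()], [reversible_inverse()]
#' @export
reversible_adapter <- function(h, use_bias = TRUE) {
  h <- as.integer(h)
  if (h %% 4L != 0L || h <= 0L)
    stop("h must be positive and divisible by 4, got ", h, call. = FALSE)
  half <- h %/% 2L; quarter <- h %/% 4L
  structure(list(h = h, use_bias = isTRUE(use_bias),
                 D_F = affine_new(half, quarter, use_bias),
                 U_F = affine_new(quarter, half, use_bias),
                 D_G = affine_new(half, quarter, use_bias),
                 U_G = affine_new(quarter, half, use_bias)),
            class = "reversible_adapter")
}

#' Bottleneck adapter parameters
#'
#' A residual bottleneck adapter `U ReLU(D x) + r` with down-projection
#' `D: h -> d` and up-projection `U: d -> h`. The `role` distinguishes the
#' language adapter (acting on the layer hidden state) from the task
#' adapter (stacked on the language adapter's output).
#'
#' @param h hidden dimension.
#' @param d bottleneck dimension, `d < h`.
#' @param role `"language"` or `"task"`.
#' @param use_bias include bias terms.
#' @return Object of class `bottleneck_adapter`.
#' @export
bottleneck_adapter <- function(h, d, role = c("language", "task"),
                               use_bias = TRUE) {
  role <- match.arg(role)
  h <- as.integer(h); d <- as.integer(d)
  if (d <= 0L || d >= h) stop("need 0 < d < h", call. = FALSE)
  structure(list(h = h, d = d, role = role, use_bias = isTRUE(use_bias),
                 D = affine_new(h, d, use_bias),
                 U = affine_new(d, h, use_bias)),
            class = "bottleneck_adapter")
}

#' He (Kaiming) initialization of adapter weights
#'
#' Draws every weight entry of the adapter's affine maps from
#' `N(0, 2/fan_in)` (the variance-preserving scheme for ReLU networks,
#' `fan_in` = input dimension of the map) and sets all biases to zero.
#' Deterministic for a fixed seed; the caller's RNG state is untouched.
#'
#' @param params a [reversible_adapter()] or [bottleneck_adapter()] object.
#' @param seed integer seed.
#' @return The same object with initialized weights.
#' @export
he_init <- function(params, seed) UseMethod("he_init")

he_init_affine <- function(a) {
  fan_in <- nrow(a$W)
  a$W[] <- rnorm(length(a$W), sd = sqrt(2 / fan_in))
  if (!is.null(a$b)) a$b[] <- 0
  a
}

#' @export
he_init.reversible_adapter <- function(params, seed) {
  with_seed(seed, {
    for (nm in c("D_F", "U_F", "D_G", "U_G"))
      params[[nm]] <- he_init_affine(params[[nm]])
  })
  params
}

#' @export
he_init.bottleneck_adapter <- function(params, seed) {
  with_seed(seed, {
    params$D <- he_init_affine(params$D)
    params$U <- he_init_affine(params$U)
  })
  params
}

# shared bottleneck branch: U(ReLU(D x))
bottleneck_branch <- function(X, params) {
  affine_apply(relu(affine_apply(X, params$D)), params$U)
}

#' Reversible adapter forward pass
#'
#' Splits the input embedding into halves `e1` (first `h/2` coordinates)
#' and `e2` (last `h/2`), then applies the additive coupling
#' `o1 = F(e2) + e1`, `o2 = G(o1) + e2` and returns the concatenation
#' `[o1, o2]`. The map is exactly invertible by [reversible_inverse()].
#'
#' @param e numeric vector of length `h`, or a `K x h` matrix of row
#'   embeddings (applied row-wise).
#' @param params a [reversible_adapter()].
#' @return Same shape as `e`.
#' @export
#' @examples
#' ra <- he_init(reversible_adapter(8), seed = 1)
#' e <- rnorm(8)
#' max(abs(reversible_inverse(reversible_forward(e, ra), ra) - e))
reversible_forward <- function(e, params) {
  stopifnot(inherits(params, "reversible_adapter"))
  vec <- !is.matrix(e)
  E <- as_row_matrix(e)
  h <- params$h
  if (ncol(E) != h) stop_shape("reversible_forward input", h, ncol(E))
  half <- h %/% 2L
  e1 <- E[, seq_len(half), drop = FALSE]
  e2 <- E[, half + seq_len(half), drop = FALSE]
  o1 <- bottleneck_branch(e2, list(D = params$D_F, U = params$U_F)) + e1
  o2 <- bottleneck_branch(o1, list(D = params$D_G, U = params$U_G)) + e2
  out <- cbind(o1, o2)
  if (vec) drop(out) else out
}

#' Reversible adapter inverse pass
#'
#' Exact closed-form inverse of [reversible_forward()]:
#' `e2 = o2 - G(o1)`, `e1 = o1 - F(e2)`.
#'
#' @param o numeric vector of length `h` or `K x h` matrix.
#' @param params a [reversible_adapter()] (same parameters as the forward).
#' @return Same shape as `o`.
#' @export
reversible_inverse <- function(o, params) {
  stopifnot(inherits(params, "reversible_adapter"))
  vec <- !is.matrix(o)
  O <- as_row_matrix(o)
  h <- params$h
  if (ncol(O) != h) stop_shape("reversible_inverse input", h, ncol(O))
  half <- h %/% 2L
  o1 <- O[, seq_len(half), drop = FALSE]
  o2 <- O[, half + seq_len(half), drop = FALSE]
  e2 <- o2 - bottleneck_branch(o1, list(D = params$D_G, U = params$U_G))
  e1 <- o1 - bottleneck_branch(e2, list(D = params$D_F, U = params$U_F))
  out <- cbind(e1, e2)
  if (vec) drop(out) else out
}

#' Hidden/residual state of one encoder layer
#'
#' Pairs the layer output (`hidden`) with the feed-forward residual
#' (`residual`); the adapter stack consumes both.
#'
#' @param hidden numeric vector (or `K x h` matrix) of layer outputs.
#' @param residual numeric vector/matrix of the same shape.
#' @return Object of class `layer_state`.
#' @export
layer_state <- function(hidden, residual) {
  if (length(hidden) != length(residual) ||
      (is.matrix(hidden) != is.matrix(residual)))
    stop("hidden and residual must have identical shapes", call. = FALSE)
  if (is.matrix(hidden) && !all(dim(hidden) == dim(residual)))
    stop_shape("layer_state residual", dim(hidden), dim(residual))
  structure(list(hidden = hidden, residual = residual), class = "layer_state")
}

#' Language adapter application
#'
#' Computes `U ReLU(D hidden) + residual`: the bottleneck branch acts on
#' the layer hidden state and the feed-forward residual is added back, so
#' a zero up-projection leaves the residual path untouched.
#'
#' @param state a [layer_state()].
#' @param params a [bottleneck_adapter()] with `role = "language"`.
#' @return Vector/matrix of dimension `h`.
#' @export
language_adapter_apply <- function(state, params) {
  stopifnot(inherits(state, "layer_state"),
            inherits(params, "bottleneck_adapter"))
  if (params$role != "language")
    stop("expected a language-role adapter, got role '", params$role, "'",
         call. = FALSE)
  vec <- !is.matrix(state$hidden)
  H <- as_row_matrix(state$hidden)
  R <- as_row_matrix(state$residual)
  out <- bottleneck_branch(H, params) + R
  if (vec) drop(out) else out
}

#' Task adapter application
#'
#' Stacked on the language adapter: `U ReLU(D la_out) + residual`, where
#' `residual` is the same feed-forward residual the language adapter used.
#'
#' @param la_out language-adapter output (vector or `K x h` matrix).
#' @param residual feed-forward residual of the same shape.
#' @param params a [bottleneck_adapter()] with `role = "task"`.
#' @return Vector/matrix of dimension `h`.
#' @export
task_adapter_apply <- function(la_out, residual, params) {
  stopifnot(inherits(params, "bottleneck_adapter"))
  if (params$role != "task")
    stop("expected a task-role adapter, got role '", params$role, "'",
         call. = FALSE)
  if (length(la_out) != length(residual))
    stop("la_out and residual must have identical shapes", call. = FALSE)
  vec <- !is.matrix(la_out)
  out <- bottleneck_branch(as_row_matrix(la_out), params) +
    as_row_matrix(residual)
  if (vec) drop(out) else out
}

#' Layer normalization
#'
#' Normalizes each row over its `h` coordinates to zero mean and unit
#' variance (population variance, small `eps` for stability), then applies
#' the trainable `gain` and `shift`.
#'
#' @param x numeric vector or `K x h` matrix.
#' @param gain length-`h` gain (default all ones).
#' @param shift length-`h` shift (default all zeros).
#' @param eps stabilizer added to the variance.
#' @return Same shape as `x`.
#' @export
layer_norm <- function(x, gain = NULL, shift = NULL, eps = 1e-6) {
  vec <- !is.matrix(x)
  X <- as_row_matrix(x)
  h <- ncol(X)
  if (h < 2L) stop("layer_norm needs h >= 2, got ", h, call. = FALSE)
  gain <- gain %||% rep(1, h)
  shift <- shift %||% rep(0, h)
  mu <- rowMeans(X)
  cen <- X - mu
  sig <- sqrt(rowMeans(cen^2) + eps)
  out <- (cen / sig) * rep_row(gain, nrow(X)) + rep_row(shift, nrow(X))
  if (vec) drop(out) else out
}

#' Transformer-Adapt layer
#'
#' The adapter stack of one transformer layer: the language adapter acts
#' on the hidden state, the task adapter on the language adapter's output
#' (both with the feed-forward residual added back), and the result passes
#' through one layer normalization whose gain/shift count as trainable
#' adapter parameters.
#'
#' @param state a [layer_state()].
#' @param lang language-role [bottleneck_adapter()].
#' @param task task-role [bottleneck_adapter()].
#' @param gain,shift layer-norm parameters (defaults: ones / zeros).
#' @return Vector/matrix of dimension `h`.
#' @export
transformer_adapt_layer <- function(state, lang, task,
                                    gain = NULL, shift = NULL) {
  h <- if (is.matrix(state$hidden)) ncol(state$hidden) else length(state$hidden)
  if (h < 2L) stop("transformer_adapt_layer needs h >= 2", call. = FALSE)
  la <- language_adapter_apply(state, lang)
  ta <- task_adapter_apply(la, state$residual, task)
  layer_norm(ta, gain = gain, shift = shift)
}
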