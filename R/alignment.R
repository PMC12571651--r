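#' Modality embedding container
#'
#' One modality's global vector together with its `n` local region
#' vectors.
#'
#' @param global_vec length-`h` numeric vector; must not be all-zero.
#' @param locals `n x h` matrix of region vectors (`n >= 1`).
#' @param modality `"image"` or `"text"`.
#' @return Object of class `modal_embedding`.
#' @export
modal_embedding <- function(global_vec, locals, modality = c("image", "text")) {
  modality <- match.arg(modality)
  locals <- as_row_matrix(locals)
  if (anyNA(global_vec) || anyNA(locals))
    stop("embeddings must not contain NA", call. = FALSE)
  if (nrow(locals) < 1L) stop("need at least one local region", call. = FALSE)
  if (ncol(locals) != length(global_vec))
    stop_shape("locals", length(global_vec), ncol(locals))
  structure(list(global_vec = as.numeric(global_vec), locals = locals,
                 modality = modality), class = "modal_embedding")
}

# pool K tokens (K x h) into n contiguous near-equal groups (n x h means);
# returns the group index of each token as an attribute for backward passes
pool_contiguous <- function(tokens, n) {
  K <- nrow(tokens)
  n <- min(as.integer(n), K)
  if (n < 1L) stop("need at least one pooling group", call. = FALSE)
  groups <- as.integer(ceiling(seq_len(K) * n / K))
  out <- matrix(0, n, ncol(tokens))
  for (g in seq_len(n))
    out[g, ] <- colMeans(tokens[groups == g, , drop = FALSE])
  attr(out, "groups") <- groups
  out
}

#' Aggregate encoded view tokens into a multiview image embedding
#'
#' The global vector is the mean over all visible tokens of both views;
#' the local vectors pool the concatenated (frontal then lateral) token
#' sequence into `n_locals` contiguous groups by mean. The lateral view
#' may be absent (single-view ablation mode).
#'
#' @param frontal_tokens `K1 x h` matrix of encoded frontal-view tokens.
#' @param lateral_tokens optional `K2 x h` matrix for the lateral view.
#' @param n_locals number of local regions; default
#'   `min(K1 + K2, 49)`.
#' @return A [modal_embedding()] with `modality = "image"`.
#' @export
aggregate_multiview <- function(frontal_tokens, lateral_tokens = NULL,
                                n_locals = NULL) {
  frontal_tokens <- as_row_matrix(frontal_tokens)
  if (nrow(frontal_tokens) < 1L)
    stop("frontal view contributes no tokens", call. = FALSE)
  all_tok <- if (is.null(lateral_tokens)) frontal_tokens else {
    lateral_tokens <- as_row_matrix(lateral_tokens)
    if (ncol(lateral_tokens) != ncol(frontal_tokens))
      stop_shape("lateral tokens", ncol(frontal_tokens), ncol(lateral_tokens))
    rbind(frontal_tokens, lateral_tokens)
  }
  n_locals <- n_locals %||% min(nrow(all_tok), 49L)
  modal_embedding(colMeans(all_tok), pool_contiguous(all_tok, n_locals),
                  modality = "image")
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  sum(a * b) / (na * nb)
}

check_nonzero <- function(v, what) {
  if (sqrt(sum(v^2)) == 0)
    stop(what, " embedding has zero norm", call. = FALSE)
}

#' Global alignment loss
#'
#' One minus the cosine similarity between the whole-image and
#' whole-report embeddings; 0 for identical directions, 1 for orthogonal,
#' 2 for antiparallel. Scale-invariant in each argument.
#'
#' @param v_img,v_txt nonzero numeric vectors of equal length.
#' @return Scalar in `[0, 2]`.
#' @export
global_alignment_loss <- function(v_img, v_txt) {
  check_nonzero(v_img, "image"); check_nonzero(v_txt, "text")
  if (length(v_img) != length(v_txt))
    stop_shape("text embedding", length(v_img), length(v_txt))
  1 - cosine_sim(v_img, v_txt)
}

#' Analytic gradient of the global alignment loss
#'
#' @inheritParams global_alignment_loss
#' @return List with `d_img` and `d_txt`, the gradients of
#'   `global_alignment_loss(v_img, v_txt)` with respect to each argument.
#' @export
global_alignment_loss_grad <- function(v_img, v_txt) {
  check_nonzero(v_img, "image"); check_nonzero(v_txt, "text")
  na <- sqrt(sum(v_img^2)); nb <- sqrt(sum(v_txt^2))
  cs <- sum(v_img * v_txt) / (na * nb)
  # d(1 - cos)/da = -(b/(|a||b|) - cos * a/|a|^2)
  list(d_img = -(v_txt / (na * nb) - cs * v_img / na^2),
       d_txt = -(v_img / (na * nb) - cs * v_txt / nb^2))
}

#' Local alignment loss
#'
#' Mean over `n` index-paired regions of one minus the per-region cosine
#' similarity.
#'
#' @param img_locals,txt_locals `n x h` matrices of region vectors; every
#'   row must be nonzero and `n` must agree.
#' @return Scalar in `[0, 2]`.
#' @export
local_alignment_loss <- function(img_locals, txt_locals) {
  img_locals <- as_row_matrix(img_locals)
  txt_locals <- as_row_matrix(txt_locals)
  n <- nrow(img_locals)
  if (nrow(txt_locals) != n)
    stop(sprintf("region count mismatch: image has %d, text has %d",
                 n, nrow(txt_locals)), call. = FALSE)
  terms <- vapply(seq_len(n), function(i) {
    a <- img_locals[i, ]; b <- txt_locals[i, ]
    if (sum(a^2) == 0 || sum(b^2) == 0)
      stop("zero-norm region vector at index ", i, call. = FALSE)
    1 - cosine_sim(a, b)
  }, numeric(1))
  mean(terms)
}

# gradients of local_alignment_loss w.r.t. both region matrices
local_alignment_loss_grad <- function(img_locals, txt_locals) {
  img_locals <- as_row_matrix(img_locals)
  txt_locals <- as_row_matrix(txt_locals)
  n <- nrow(img_locals)
  d_img <- img_locals * 0; d_txt <- txt_locals * 0
  for (i in seq_len(n)) {
    g <- global_alignment_loss_grad(img_locals[i, ], txt_locals[i, ])
    d_img[i, ] <- g$d_img / n
    d_txt[i, ] <- g$d_txt / n
  }
  list(d_img = d_img, d_txt = d_txt)
}

#' Total alignment loss
#'
#' `L = L_global + lambda1 * L_local`, reported with its components.
#'
#' @param img,txt [modal_embedding()] objects with matching shapes.
#' @param lambda1 local-loss weight (default 0.8).
#' @return Object of class `loss_breakdown` with fields `global_term`,
#'   `local_term`, `total`, `lambda1`; `total` satisfies the exact
#'   identity `global_term + lambda1 * local_term`.
#' @export
total_loss <- function(img, txt, lambda1 = 0.8) {
  stopifnot(inherits(img, "modal_embedding"), inherits(txt, "modal_embedding"))
  g <- global_alignment_loss(img$global_vec, txt$global_vec)
  l <- local_alignment_loss(img$locals, txt$locals)
  structure(list(global_term = g, local_term = l,
                 total = g + lambda1 * l, lambda1 = lambda1),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("alignment loss: total %.6f = global %.6f + %.3g * local %.6f\n",
              x$total, x$global_term, x$lambda1, x$local_term))
  invisible(x)
}

row_normalize <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) stop("zero-norm row in embedding batch", call. = FALSE)
  list(N = X / nrm, norms = nrm)
}

softmax_rows <- function(S) {
  E <- exp(S - apply(S, 1, max))
  E / rowSums(E)
}

#' Symmetric in-batch contrastive loss
#'
#' Optional training objective (not part of the positives-only alignment
#' loss): symmetric cross-entropy over the `B x B` cosine-similarity
#' matrix of a batch, with matched image/text pairs on the diagonal.
#' Provided so that toy retrieval training has negative pairs and cannot
#' collapse; off by default in [train_config()].
#'
#' @param img_globals,txt_globals `B x h` matrices of global embeddings,
#'   `B >= 2`.
#' @param temperature softmax temperature (> 0).
#' @return Scalar loss; `log(B)` when all similarities are equal.
#' @export
batch_contrastive_loss <- function(img_globals, txt_globals,
                                   temperature = 0.1) {
  img_globals <- as_row_matrix(img_globals)
  txt_globals <- as_row_matrix(txt_globals)
  B <- nrow(img_globals)
  if (B < 2L) stop("contrastive loss needs a batch of >= 2 pairs",
                   call. = FALSE)
  if (!all(dim(img_globals) == dim(txt_globals)))
    stop_shape("txt_globals", dim(img_globals), dim(txt_globals))
  Ni <- row_normalize(img_globals)$N
  Nt <- row_normalize(txt_globals)$N
  S <- (Ni %*% t(Nt)) / temperature
  mr <- apply(S, 1, max); mc <- apply(S, 2, max)
  lse_r <- log(rowSums(exp(S - mr))) + mr
  lse_c <- log(colSums(exp(sweep(S, 2, mc)))) + mc
  d <- diag(S)
  (mean(lse_r - d) + mean(lse_c - d)) / 2
}

# loss + gradients w.r.t. the raw (unnormalized) global embeddings
batch_contrastive_loss_grad <- function(img_globals, txt_globals,
                                        temperature = 0.1) {
  B <- nrow(img_globals)
  ri <- row_normalize(img_globals); rt <- row_normalize(txt_globals)
  Ni <- ri$N; Nt <- rt$N
  S <- (Ni %*% t(Nt)) / temperature
  Pr <- softmax_rows(S)
  Pc <- t(softmax_rows(t(S)))
  I <- diag(B)
  dS <- ((Pr - I) / B + (Pc - I) / B) / 2
  dNi <- (dS %*% Nt) / temperature
  dNt <- (t(dS) %*% Ni) / temperature
  # back through row normalization: dz = (dn - n (n . dn)) / |z|
  unnorm <- function(dN, N, norms) (dN - N * rowSums(N * dN)) / norms
  list(loss = batch_contrastive_loss(img_globals, txt_globals, temperature),
       d_img = unnorm(dNi, Ni, ri$norms),
       d_txt = unnorm(dNt, Nt, rt$norms))
}
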