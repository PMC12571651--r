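#' Rank candidates by cosine similarity to a query
#'
#' Produces a full ordering of the candidate set by descending cosine
#' similarity, with floating-point ties broken by ascending candidate
#' index so rankings are reproducible.
#'
#' @param query nonzero numeric vector.
#' @param candidates `M x h` matrix of nonzero candidate vectors.
#' @param relevant optional logical vector (length `M`) marking which
#'   candidates are relevant to the query.
#' @param query_id optional identifier.
#' @return Object of class `retrieval_result`: `ranked_ids` (1-based
#'   candidate indices), `scores` (non-increasing), `relevant` (aligned to
#'   `ranked_ids`, or `NULL`), `query_id`.
#' @export
rank_by_cosine <- function(query, candidates, relevant = NULL,
                           query_id = NA) {
  candidates <- as_row_matrix(candidates)
  check_nonzero(query, "query")
  nrm <- sqrt(rowSums(candidates^2))
  if (any(nrm == 0))
    stop("zero-norm candidate at index ", which(nrm == 0)[1], call. = FALSE)
  if (ncol(candidates) != length(query))
    stop_shape("candidates", length(query), ncol(candidates))
  scores <- drop(candidates %*% query) / (nrm * sqrt(sum(query^2)))
  ord <- order(-scores, seq_along(scores))
  structure(list(query_id = query_id, ranked_ids = ord,
                 scores = scores[ord],
                 relevant = if (is.null(relevant)) NULL else
                   as.logical(relevant)[ord]),
            class = "retrieval_result")
}

#' Precision at k
#'
#' Proportion of relevant candidates among the top `k` of a ranking.
#'
#' @param result a `retrieval_result` with relevance labels, or a plain
#'   logical vector already in rank order.
#' @param k cutoff, `1 <= k <=` number of ranked candidates.
#' @return Fraction in `[0, 1]`.
#' @export
precision_at_k <- function(result, k) {
  rel <- if (inherits(result, "retrieval_result")) result$relevant else
    as.logical(result)
  if (is.null(rel)) stop("ranking carries no relevance labels", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > length(rel))
    stop(sprintf("k = %d outside [1, %d]", k, length(rel)), call. = FALSE)
  sum(rel[seq_len(k)]) / k
}

#' Threshold classification metrics: accuracy, F1, AUC
#'
#' Accuracy and F1 are computed at `threshold` (predicted positive iff
#' `score >= threshold`); AUC uses the rank-statistic (Mann-Whitney)
#' formulation with midranks for ties, which equals trapezoidal ROC
#' integration. With a single class present the AUC is undefined and
#' returned as `NA` with `auc_defined = FALSE`.
#'
#' @param labels logical (or 0/1) true labels.
#' @param scores numeric scores, same length.
#' @param threshold decision threshold.
#' @return List with `acc`, `f1`, `auc`, `auc_defined`.
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.logical(labels)
  if (length(labels) != length(scores) || length(labels) < 2L)
    stop("labels and scores must have equal length >= 2", call. = FALSE)
  pred <- scores >= threshold
  acc <- mean(pred == labels)
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    auc <- NA_real_; defined <- FALSE
  } else {
    r <- rank(scores)  # midranks for ties
    auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    defined <- TRUE
  }
  list(acc = acc, f1 = f1, auc = auc, auc_defined = defined)
}

#' Zero-shot classification by class-prompt similarity
#'
#' Assigns the class whose prompt embedding has the highest cosine
#' similarity to the image's global embedding; ties resolve to the lowest
#' class index.
#'
#' @param image_emb a [modal_embedding()] or bare global vector.
#' @param class_prompts `C x h` matrix of prompt embeddings, `C >= 2`,
#'   all rows nonzero.
#' @return List with `class` (1-based index) and `scores` (length `C`
#'   cosine similarities).
#' @export
zero_shot_classify <- function(image_emb, class_prompts) {
  v <- if (inherits(image_emb, "modal_embedding")) image_emb$global_vec
  else image_emb
  class_prompts <- as_row_matrix(class_prompts)
  if (nrow(class_prompts) < 2L)
    stop("need at least two class prompts", call. = FALSE)
  nrm <- sqrt(rowSums(class_prompts^2))
  if (any(nrm == 0))
    stop("degenerate (zero) prompt at index ", which(nrm == 0)[1],
         call. = FALSE)
  check_nonzero(v, "image")
  scores <- drop(class_prompts %*% v) / (nrm * sqrt(sum(v^2)))
  list(class = which.max(scores), scores = scores)
}

#' Class-structured retrieval evaluation
#'
#' Ranks each query against a candidate pool and averages P@k over
#' queries, with a candidate counted relevant iff it shares the query's
#' class label (the k-class x n-per-class protocol shape).
#'
#' @param query_embs `Q x h` query embeddings.
#' @param cand_embs `M x h` candidate embeddings.
#' @param query_classes,cand_classes class labels.
#' @param ks precision cutoffs.
#' @param exclude_self set `TRUE` for same-modality retrieval where query
#'   i is candidate i and must not match itself.
#' @return Named numeric vector of mean P@k values (names `"P@k"`).
#' @export
evaluate_retrieval <- function(query_embs, cand_embs, query_classes,
                               cand_classes, ks = c(5, 10, 50),
                               exclude_self = FALSE) {
  query_embs <- as_row_matrix(query_embs)
  cand_embs <- as_row_matrix(cand_embs)
  Q <- nrow(query_embs)
  acc <- matrix(0, Q, length(ks))
  for (q in seq_len(Q)) {
    keep <- if (exclude_self) setdiff(seq_len(nrow(cand_embs)), q)
    else seq_len(nrow(cand_embs))
    res <- rank_by_cosine(query_embs[q, ], cand_embs[keep, , drop = FALSE],
                          relevant = cand_classes[keep] == query_classes[q])
    acc[q, ] <- vapply(ks, function(k) precision_at_k(res, k), numeric(1))
  }
  stats::setNames(colMeans(acc), paste0("P@", ks))
}

#' Mean P@k of a uniform random ranker on a class-balanced pool
#'
#' Monte-Carlo simulation of the chance-level retrieval baseline: for each
#' query a uniformly random ranking of a balanced `n_classes x n_per_class`
#' candidate pool is drawn and P@k measured against same-class relevance.
#' The expectation is `1/n_classes` (e.g. 12.5% for 8 classes, 20% for 5).
#'
#' @param n_classes number of classes.
#' @param n_per_class candidates per class.
#' @param k precision cutoff.
#' @param n_queries number of simulated queries.
#' @param seed RNG seed.
#' @return Mean P@k over the simulated queries.
#' @export
random_ranker_baseline <- function(n_classes = 8L, n_per_class = 200L,
                                   k = 5L, n_queries = 1000L, seed = 1L) {
  M <- n_classes * n_per_class
  classes <- rep(seq_len(n_classes), each = n_per_class)
  with_seed(seed, {
    mean(vapply(seq_len(n_queries), function(q) {
      qc <- sample.int(n_classes, 1L)
      perm <- sample.int(M)               # uniformly random ranking
      precision_at_k((classes[perm] == qc), k)
    }, numeric(1)))
  })
}
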