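# shared fixtures; everything is generated in code, nothing is stored

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# CPU-sized model profile used across training tests
toy_model <- function(h = 8L, depth = 2L, d = 2L, seed = 11L,
                      max_img_tokens = 32L, max_txt_tokens = 64L,
                      vocab_size = 64L) {
  alignment_model(h = h, depth = depth, d = d, patch_dim = 256L,
                  vocab_size = vocab_size, max_img_tokens = max_img_tokens,
                  max_txt_tokens = max_txt_tokens, seed = seed)
}

# small 2-class synthetic dataset at 64x64 (16 patches/view, 4 visible at 75%)
tiny_prep <- function() {
  cached("tiny_prep", {
    spec <- synthetic_spec(n_classes = 2, n_per_class = 4, image_side = 64,
                           seed = 5)
    prepare_training_set(generate_dataset(spec)$records,
                         vocab_size = 64L)
  })
}

# random nonzero vector
rvec <- function(h) stats::rnorm(h)

# brute-force AUC oracle: pairwise concordance counting with ties as 1/2
auc_pairs <- function(labels, scores) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# trapezoidal ROC-integration AUC oracle (tie-free scores)
auc_trapezoid <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- as.logical(labels)[ord]
  tpr <- c(0, cumsum(lab) / sum(lab))
  fpr <- c(0, cumsum(!lab) / sum(!lab))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# all permutations of 1..n (row-wise)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}
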