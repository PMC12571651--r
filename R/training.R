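#' Dual-encoder alignment model
#'
#' An image encoder and a text encoder sharing one adapter geometry, plus
#' the pooling configuration. The backbones are small frozen encoders
#' (the full-scale configuration uses `h = 768`, `d = 64`; tests use a
#' CPU-sized profile).
#'
#' @param h hidden dimension (divisible by 4, default 32 desk profile).
#' @param depth blocks per encoder.
#' @param d adapter bottleneck dimension.
#' @param patch_dim flattened patch length (`16^2 = 256` by default).
#' @param vocab_size text vocabulary size.
#' @param max_img_tokens,max_txt_tokens position-table sizes.
#' @param n_locals number of local regions used for the local loss;
#'   `NULL` = per-record default `min(visible image tokens, text tokens, 49)`.
#' @param use_bias adapters carry biases.
#' @param seed initialization seed.
#' @return Object of class `alignment_model`.
#' @export
alignment_model <- function(h = 32L, depth = 2L, d = 8L, patch_dim = 256L,
                            vocab_size = 512L, max_img_tokens = 512L,
                            max_txt_tokens = 128L, n_locals = NULL,
                            use_bias = TRUE, seed = 1L) {
  structure(list(
    img = build_encoder("image", h = h, depth = depth, d = d,
                        input_dim = patch_dim, max_tokens = max_img_tokens,
                        use_bias = use_bias, seed = mix_seed(seed, "img")),
    txt = build_encoder("text", h = h, depth = depth, d = d,
                        vocab_size = vocab_size, max_tokens = max_txt_tokens,
                        use_bias = use_bias, seed = mix_seed(seed, "txt")),
    h = as.integer(h), depth = as.integer(depth), d = as.integer(d),
    patch_dim = as.integer(patch_dim), vocab_size = as.integer(vocab_size),
    n_locals = n_locals, seed = as.integer(seed)),
    class = "alignment_model")
}

# ---- parameter tree <-> flat named-array list -------------------------------

# weights/biases are doubles; integer scalars (h, d, ...) are config, not params
is_param_leaf <- function(x) is.double(x) && !is.list(x)

flatten_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    item <- x[[nm]]
    path <- if (nzchar(prefix)) paste0(prefix, "/", nm) else nm
    if (is_param_leaf(item)) out[[path]] <- item
    else if (is.list(item)) out <- c(out, flatten_params(item, path))
    # scalars/config fields inside param objects are skipped
  }
  out
}

model_flat_params <- function(model) {
  c(flatten_params(model$img$params, "img"),
    flatten_params(model$txt$params, "txt"))
}

# first path segment picks the encoder; the rest index into its $params tree
set_flat_param <- function(model, path, value) {
  segs <- strsplit(path, "/", fixed = TRUE)[[1]]
  model[[segs[1]]]$params[[segs[-1]]] <- value
  model
}

model_set_flat <- function(model, flat) {
  for (path in names(flat)) model <- set_flat_param(model, path, flat[[path]])
  model
}

param_family <- function(path) {
  segs <- strsplit(path, "/", fixed = TRUE)[[1]]
  fam <- intersect(segs, c("rev", "la", "ta", "ln"))
  if (length(fam)) fam[1] else "backbone"
}

#' Partition model parameters into trainable and frozen sets
#'
#' In `"pretrain"` mode every adapter family (reversible adapter,
#' language adapter, task adapter, layer-norm gain/shift) is trainable
#' and the encoder backbones stay frozen. In `"downstream"` mode only the
#' task adapters and their layer norms are updated.
#'
#' @param model an [alignment_model()].
#' @param mode `"pretrain"` or `"downstream"`.
#' @return Object of class `parameter_partition`: `trainable` and
#'   `frozen` (named flat parameter lists) and `counts` with
#'   `trainable`, `total` and `fraction = trainable/total`.
#' @export
partition_parameters <- function(model, mode = c("pretrain", "downstream")) {
  mode <- match.arg(mode)
  flat <- model_flat_params(model)
  fams <- vapply(names(flat), param_family, character(1))
  keep <- switch(mode,
                 pretrain = c("rev", "la", "ta", "ln"),
                 downstream = c("ta", "ln"))
  trainable <- flat[fams %in% keep]
  frozen <- flat[!(fams %in% keep)]
  if (length(trainable) == 0L)
    stop("partition left no trainable parameters", call. = FALSE)
  n_tr <- sum(vapply(trainable, length, numeric(1)))
  n_all <- sum(vapply(flat, length, numeric(1)))
  structure(list(trainable = trainable, frozen = frozen, mode = mode,
                 counts = list(trainable = n_tr, total = n_all,
                               fraction = n_tr / n_all)),
            class = "parameter_partition")
}

#' @export
print.parameter_partition <- function(x, ...) {
  cat(sprintf("parameter partition (%s): %d trainable / %d total (%.2f%%)\n",
              x$mode, x$counts$trainable, x$counts$total,
              100 * x$counts$fraction))
  invisible(x)
}

#' Training configuration
#'
#' Defaults follow the published hyperparameter table: AdamW, batch 32,
#' language-adapter learning rate 5e-5, task-adapter rate 1e-4, weight
#' decay 1e-4. The reversible adapter trains at the language rate; layer
#' norms train at the task rate (they travel with the task adapter).
#' `lr_scale` uniformly rescales both rates for desk-scale toy profiles.
#'
#' @param batch_size batch size.
#' @param lr_language_adapter,lr_task_adapter per-group learning rates.
#' @param weight_decay decoupled weight decay on all trainable params.
#' @param steps number of optimizer steps.
#' @param seed RNG seed controlling batching and per-epoch masks.
#' @param objective `"paper"` (positives-only global+local alignment) or
#'   `"contrastive"` (opt-in symmetric in-batch objective).
#' @param mode partition mode, see [partition_parameters()].
#' @param lambda1 local-loss weight.
#' @param temperature contrastive temperature.
#' @param mask_rate patch masking rate.
#' @param lr_scale multiplier on both learning rates (default 1).
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, lr_language_adapter = 5e-5,
                         lr_task_adapter = 1e-4, weight_decay = 1e-4,
                         steps = 100L, seed = 1L,
                         objective = c("paper", "contrastive"),
                         mode = c("pretrain", "downstream"),
                         lambda1 = 0.8, temperature = 0.1,
                         mask_rate = 0.75, lr_scale = 1) {
  objective <- match.arg(objective); mode <- match.arg(mode)
  stopifnot(batch_size >= 1, lr_language_adapter >= 0, lr_task_adapter >= 0,
            weight_decay >= 0, steps >= 0, lr_scale >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 lr_language_adapter = lr_language_adapter * lr_scale,
                 lr_task_adapter = lr_task_adapter * lr_scale,
                 weight_decay = weight_decay, steps = as.integer(steps),
                 seed = as.integer(seed), objective = objective, mode = mode,
                 lambda1 = lambda1, temperature = temperature,
                 mask_rate = mask_rate),
            class = "train_config")
}

# ---- AdamW ------------------------------------------------------------------

adamw_init <- function(trainable) {
  list(t = 0L,
       m = lapply(trainable, function(p) p * 0),
       v = lapply(trainable, function(p) p * 0))
}

lr_for_path <- function(path, config) {
  if (param_family(path) %in% c("ta", "ln")) config$lr_task_adapter
  else config$lr_language_adapter
}

adamw_step <- function(params, grads, state, config,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    lr <- lr_for_path(nm, config)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps) -
      lr * config$weight_decay * params[[nm]]
  }
  list(params = params, state = state)
}

# ---- record encoding --------------------------------------------------------

# inputs: list(frontal = K1 x patch_dim, lateral = K2 x patch_dim | NULL,
#              txt_ids = integer vector of non-pad ids)
encode_pair_cached <- function(model, inputs, n_locals = NULL,
                               keep_cache = FALSE) {
  ff <- encoder_forward(model$img, inputs$frontal, keep_cache)
  fl <- if (!is.null(inputs$lateral))
    encoder_forward(model$img, inputs$lateral, keep_cache)
  ft <- encoder_forward(model$txt, inputs$txt_ids, keep_cache)
  K_img <- nrow(ff$tokens) + if (is.null(fl)) 0L else nrow(fl$tokens)
  n <- n_locals %||% model$n_locals %||%
    min(K_img, nrow(ft$tokens), 49L)
  img <- aggregate_multiview(ff$tokens,
                             if (is.null(fl)) NULL else fl$tokens,
                             n_locals = n)
  txt_locals <- pool_contiguous(ft$tokens, n)
  txt <- modal_embedding(colMeans(ft$tokens), txt_locals, "text")
  list(img = img, txt = txt, n = n,
       caches = if (keep_cache)
         list(frontal = ff$cache, lateral = if (is.null(fl)) NULL else fl$cache,
              txt = ft$cache,
              K = list(f = nrow(ff$tokens),
                       l = if (is.null(fl)) 0L else nrow(fl$tokens),
                       t = nrow(ft$tokens)),
              groups_img = attr(img$locals, "groups"),
              groups_txt = attr(txt_locals, "groups")) else NULL)
}

# distribute pooling gradients back onto tokens
pool_backward <- function(K, d_global, d_locals, groups) {
  dT <- rep_row(d_global / K, K)
  if (!is.null(d_locals)) {
    for (g in seq_len(nrow(d_locals))) {
      idx <- which(groups == g)
      dT[idx, ] <- dT[idx, ] + rep_row(d_locals[g, ] / length(idx),
                                       length(idx))
    }
  }
  dT
}

# backward from embedding-space gradients into flat adapter gradients
pair_backward <- function(model, enc, d_img_global, d_txt_global,
                          d_img_locals = NULL, d_txt_locals = NULL) {
  Kf <- enc$caches$K$f; Kl <- enc$caches$K$l; Kt <- enc$caches$K$t
  dAll <- pool_backward(Kf + Kl, d_img_global, d_img_locals,
                        enc$caches$groups_img)
  dTf <- dAll[seq_len(Kf), , drop = FALSE]
  gi <- encoder_backward(model$img, enc$caches$frontal, dTf)
  flat <- flatten_params(gi, "img")
  if (Kl > 0L) {
    dTl <- dAll[Kf + seq_len(Kl), , drop = FALSE]
    gl <- flatten_params(encoder_backward(model$img, enc$caches$lateral, dTl),
                         "img")
    flat <- flat_add(flat, gl)
  }
  dTt <- pool_backward(Kt, d_txt_global, d_txt_locals, enc$caches$groups_txt)
  gt <- flatten_params(encoder_backward(model$txt, enc$caches$txt, dTt), "txt")
  c(flat, gt)
}

flat_add <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else
    a[[nm]] + b[[nm]]
  a
}

flat_scale <- function(a, s) lapply(a, function(x) x * s)

# ---- dataset preparation ----------------------------------------------------

#' Preprocess a record list into training tensors
#'
#' Applies the image pipeline (HU windowing if needed, patchify) and the
#' text pipeline (section extraction, tokenization, 128-token
#' pad/truncate) to every record. Patch intensities are scaled to
#' `[0, 1]`. Masking is NOT applied here: masks are resampled per epoch
#' inside [train_loop()] via [mask_seed_for()].
#'
#' @param records list of `view_pair` records (see [generate_dataset()]).
#' @param patch_side patch side in pixels.
#' @param max_len token sequence length.
#' @param vocab_size tokenizer vocabulary size.
#' @return List of per-record lists: `grid_frontal`, `grid_lateral`,
#'   `txt_ids` (non-pad ids), `record_id`, `class_id`.
#' @export
prepare_training_set <- function(records, patch_side = 16L, max_len = 128L,
                                 vocab_size = 512L) {
  lapply(records, function(rec) {
    norm_grid <- function(rg) {
      if (is.null(rg)) return(NULL)
      px <- if (rg$units == "HU") window_normalize(rg)$pixels else rg$pixels
      g <- patchify(px, patch_side)
      g$patches <- g$patches / 255
      g
    }
    prep <- prepare_report(rec$report, record_id = rec$record_id,
                           max_len = max_len, vocab_size = vocab_size)
    ids <- prep$sequence$ids[seq_len(max(prep$sequence$length, 1L))]
    ids <- ids[ids != prep$sequence$pad_id]
    if (length(ids) == 0L)
      stop("record ", rec$record_id, " has an empty report", call. = FALSE)
    list(grid_frontal = norm_grid(rec$frontal),
         grid_lateral = norm_grid(rec$lateral),
         txt_ids = ids, record_id = rec$record_id,
         class_id = rec$class_id %||% NA_integer_)
  })
}

masked_inputs <- function(prep, config, epoch) {
  vis <- function(grid, view) {
    if (is.null(grid)) return(NULL)
    m <- sample_mask(nrow(grid$patches), config$mask_rate,
                     mask_seed_for(config$seed, prep$record_id, view, epoch))
    apply_mask(grid, m)$visible_patches
  }
  list(frontal = vis(prep$grid_frontal, "frontal"),
       lateral = vis(prep$grid_lateral, "lateral"),
       txt_ids = prep$txt_ids)
}

# ---- training loop ----------------------------------------------------------

#' Desk-scale training loop
#'
#' Optimizes the trainable adapter partition with AdamW over a prepared
#' dataset, with per-group learning rates, per-epoch mask resampling, and
#' JSONL-style metric rows. Backbone parameters are never touched. Fully
#' reproducible for a fixed `config$seed`; aborts with a diagnostic if
#' the loss turns non-finite.
#'
#' @param dataset output of [prepare_training_set()].
#' @param model an [alignment_model()].
#' @param config a [train_config()].
#' @param metrics_path optional path to append JSONL metric lines to.
#' @return List: updated `model`, `metrics` data.frame (step, epoch,
#'   loss and, for the paper objective, global/local components),
#'   `partition`.
#' @export
train_loop <- function(dataset, model, config, metrics_path = NULL) {
  stopifnot(length(dataset) >= 1L)
  part <- partition_parameters(model, config$mode)
  params <- part$trainable
  state <- adamw_init(params)
  N <- length(dataset)
  B <- min(config$batch_size, N)
  rows <- vector("list", config$steps)
  order_rng <- mix_seed(config$seed, "batching")
  for (step in seq_len(config$steps)) {
    epoch <- ((step - 1L) * B) %/% N + 1L
    batch_idx <- with_seed(mix_seed(order_rng, step), sample.int(N, B))
    encs <- lapply(batch_idx, function(i)
      encode_pair_cached(model, masked_inputs(dataset[[i]], config, epoch),
                         keep_cache = TRUE))
    grads <- NULL
    if (config$objective == "contrastive") {
      IG <- do.call(rbind, lapply(encs, function(e) e$img$global_vec))
      TG <- do.call(rbind, lapply(encs, function(e) e$txt$global_vec))
      cg <- batch_contrastive_loss_grad(IG, TG, config$temperature)
      loss <- cg$loss; gterm <- NA_real_; lterm <- NA_real_
      for (b in seq_len(B)) {
        g <- pair_backward(model, encs[[b]], cg$d_img[b, ], cg$d_txt[b, ])
        grads <- if (is.null(grads)) g else flat_add(grads, g)
      }
    } else {
      loss <- 0; gterm <- 0; lterm <- 0
      for (b in seq_len(B)) {
        e <- encs[[b]]
        lb <- total_loss(e$img, e$txt, lambda1 = config$lambda1)
        loss <- loss + lb$total / B
        gterm <- gterm + lb$global_term / B
        lterm <- lterm + lb$local_term / B
        gg <- global_alignment_loss_grad(e$img$global_vec, e$txt$global_vec)
        gl <- local_alignment_loss_grad(e$img$locals, e$txt$locals)
        g <- pair_backward(model, e,
                           gg$d_img / B, gg$d_txt / B,
                           config$lambda1 * gl$d_img / B,
                           config$lambda1 * gl$d_txt / B)
        grads <- if (is.null(grads)) g else flat_add(grads, g)
      }
    }
    if (!is.finite(loss))
      stop(sprintf("training diverged at step %d (loss = %s)", step, loss),
           call. = FALSE)
    upd <- adamw_step(params, grads, state, config)
    params <- upd$params; state <- upd$state
    model <- model_set_flat(model, params)
    rows[[step]] <- data.frame(step = step, epoch = epoch, loss = loss,
                               global = gterm, local = lterm)
  }
  metrics <- do.call(rbind, rows) %||%
    data.frame(step = integer(), epoch = integer(), loss = numeric(),
               global = numeric(), local = numeric())
  if (!is.null(metrics_path) && nrow(metrics) > 0) {
    con <- file(metrics_path, "a"); on.exit(close(con))
    for (i in seq_len(nrow(metrics)))
      writeLines(jsonlite::toJSON(as.list(metrics[i, ]), auto_unbox = TRUE,
                                  na = "null", digits = NA), con)
  }
  list(model = model, metrics = metrics, partition = part)
}

#' Embed a prepared dataset with a model
#'
#' Deterministic evaluation-time embedding: masks are drawn once per
#' record from `seed` (epoch 0), no caches are kept.
#'
#' @param model an [alignment_model()].
#' @param dataset output of [prepare_training_set()].
#' @param config a [train_config()] (mask rate + seed are used).
#' @return List with `img_globals` and `txt_globals` (`N x h` matrices)
#'   and `classes`.
#' @export
embed_dataset <- function(model, dataset, config = train_config()) {
  embs <- lapply(dataset, function(prep)
    encode_pair_cached(model, masked_inputs(prep, config, epoch = 0L)))
  list(img_globals = do.call(rbind, lapply(embs, function(e) e$img$global_vec)),
       txt_globals = do.call(rbind, lapply(embs, function(e) e$txt$global_vec)),
       classes = vapply(dataset, function(p) as.integer(p$class_id),
                        integer(1)))
}

# ---- checkpoints ------------------------------------------------------------

#' Save / load adapter checkpoints
#'
#' Checkpoints are a directory of named flat arrays, one TSV per array,
#' plus a JSON manifest recording `h`, `d`, `use_bias` and every array's
#' shape. Loading validates shapes against the target model.
#'
#' @param model an [alignment_model()].
#' @param path checkpoint directory (created if needed).
#' @param trainable_only save only the trainable partition of `mode`.
#' @param mode partition mode used when `trainable_only`.
#' @return `checkpoint_save`: the path, invisibly. `checkpoint_load`: the
#'   model with loaded parameters.
#' @name checkpoint
#' @export
checkpoint_save <- function(model, path, trainable_only = TRUE,
                            mode = "pretrain") {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  flat <- if (trainable_only) partition_parameters(model, mode)$trainable
  else model_flat_params(model)
  shapes <- lapply(flat, function(p) if (is.matrix(p)) dim(p) else length(p))
  manifest <- list(h = model$h, d = model$d,
                   use_bias = model$img$use_bias,
                   roles = names(flat), shapes = shapes)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(flat)) {
    p <- flat[[nm]]
    fn <- file.path(path, paste0(gsub("/", "__", nm), ".tsv"))
    M <- if (is.matrix(p)) p else matrix(p, nrow = 1)
    utils::write.table(M, fn, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' @rdname checkpoint
#' @export
checkpoint_load <- function(model, path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  if (manifest$h != model$h || manifest$d != model$d)
    stop(sprintf("checkpoint geometry (h=%s, d=%s) does not match model (h=%d, d=%d)",
                 manifest$h, manifest$d, model$h, model$d), call. = FALSE)
  flat <- model_flat_params(model)
  loaded <- list()
  for (nm in manifest$roles) {
    fn <- file.path(path, paste0(gsub("/", "__", nm), ".tsv"))
    M <- as.matrix(utils::read.table(fn, sep = "\t", header = FALSE))
    dimnames(M) <- NULL
    cur <- flat[[nm]]
    if (is.null(cur))
      stop("checkpoint contains unknown parameter '", nm, "'", call. = FALSE)
    if (is.matrix(cur)) {
      if (!all(dim(cur) == dim(M)))
        stop_shape(paste0("checkpoint array ", nm), dim(cur), dim(M))
      loaded[[nm]] <- M
    } else {
      v <- as.numeric(M)
      if (length(v) != length(cur))
        stop_shape(paste0("checkpoint array ", nm), length(cur), length(v))
      loaded[[nm]] <- v
    }
  }
  model_set_flat(model, loaded)
}
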