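ns <- asNamespace("radalign")

# explicit parameter census for the toy geometry, independent of the
# implementation's bookkeeping
census <- function(h, d, depth, patch_dim, vocab, max_img, max_txt,
                   mh = 2 * h) {
  rev_adapter <- 4 * (h / 2 * h / 4) + 2 * (h / 4) + 2 * (h / 2)  # W + biases
  bottleneck <- (h * d + d) + (d * h + h)
  ln <- 2 * h
  per_block_adapters <- 2 * bottleneck + ln
  per_block_backbone <- h * h + (h * mh + mh) + (mh * h + h)
  img_backbone <- (patch_dim * h + h) + max_img * h +
    depth * per_block_backbone
  txt_backbone <- vocab * h + max_txt * h + depth * per_block_backbone
  adapters_one_encoder <- rev_adapter + depth * per_block_adapters
  list(trainable_pretrain = 2 * adapters_one_encoder,
       trainable_downstream = 2 * depth * (bottleneck + ln),
       total = img_backbone + txt_backbone + 2 * adapters_one_encoder)
}

test_that("partition counts match a hand census on the h=8/d=2 toy model", {
  model <- toy_model(h = 8, depth = 2, d = 2)
  want <- census(8, 2, 2, patch_dim = 256, vocab = 64,
                 max_img = 32, max_txt = 64, mh = 16)
  pre <- partition_parameters(model, "pretrain")
  expect_equal(pre$counts$trainable, want$trainable_pretrain)
  expect_equal(pre$counts$total, want$total)
  expect_equal(pre$counts$fraction, want$trainable_pretrain / want$total)
  down <- partition_parameters(model, "downstream")
  expect_equal(down$counts$trainable, want$trainable_downstream)
  # downstream trainable set: only task adapters and layer norms
  fams <- unique(vapply(names(down$trainable), ns$param_family, character(1)))
  expect_setequal(fams, c("ta", "ln"))
  expect_error(partition_parameters(model, "everything"), "arg")
})

test_that("parameter-efficiency fraction is monotone in d", {
  fr <- vapply(c(1L, 2L, 3L), function(d)
    partition_parameters(toy_model(h = 8, d = d), "pretrain")$counts$fraction,
    numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("zero learning rate leaves parameters bit-identical", {
  model <- toy_model()
  cfg <- train_config(batch_size = 4, steps = 3, seed = 1,
                      lr_language_adapter = 0, lr_task_adapter = 0,
                      weight_decay = 0)
  fit <- train_loop(tiny_prep(), model, cfg)
  expect_identical(ns$model_flat_params(fit$model),
                   ns$model_flat_params(model))
})

test_that("downstream mode freezes everything except task adapters + norms", {
  model <- toy_model()
  cfg <- train_config(batch_size = 4, steps = 10, seed = 2,
                      mode = "downstream", lr_scale = 100)
  fit <- train_loop(tiny_prep(), model, cfg)
  before <- ns$model_flat_params(model)
  after <- ns$model_flat_params(fit$model)
  fams <- vapply(names(before), ns$param_family, character(1))
  frozen <- names(before)[!(fams %in% c("ta", "ln"))]
  for (nm in frozen) expect_identical(after[[nm]], before[[nm]])
  # gradient reaches the task adapters: they must have moved
  ta_names <- names(before)[fams == "ta"]
  moved <- vapply(ta_names, function(nm)
    max(abs(after[[nm]] - before[[nm]])), numeric(1))
  expect_gt(max(moved), 0)
})

test_that("pretrain mode trains language adapters but never the backbone", {
  model <- toy_model()
  cfg <- train_config(batch_size = 4, steps = 5, seed = 3, lr_scale = 100)
  fit <- train_loop(tiny_prep(), model, cfg)
  before <- ns$model_flat_params(model)
  after <- ns$model_flat_params(fit$model)
  fams <- vapply(names(before), ns$param_family, character(1))
  for (nm in names(before)[fams == "backbone"])
    expect_identical(after[[nm]], before[[nm]])
  la_moved <- vapply(names(before)[fams == "la"], function(nm)
    max(abs(after[[nm]] - before[[nm]])), numeric(1))
  expect_gt(max(la_moved), 0)
})

test_that("per-group learning rates are honoured on a one-parameter probe", {
  model <- toy_model()
  cfg <- train_config(lr_language_adapter = 1e-3, lr_task_adapter = 7e-3,
                      weight_decay = 0)
  params <- list(`img/blocks/b1/la/D/W` = matrix(1, 1, 1),
                 `img/blocks/b1/ta/D/W` = matrix(1, 1, 1))
  grads <- list(`img/blocks/b1/la/D/W` = matrix(2, 1, 1),
                `img/blocks/b1/ta/D/W` = matrix(2, 1, 1))
  st <- ns$adamw_init(params)
  upd <- ns$adamw_step(params, grads, st, cfg)
  # first Adam step moves by exactly lr * g/|g| (bias-corrected)
  expect_equal(1 - upd$params[[1]][1], 1e-3 * (2 / (2 + 1e-8)))
  expect_equal(1 - upd$params[[2]][1], 7e-3 * (2 / (2 + 1e-8)))
})

test_that("training is deterministic per seed and logs a sane trajectory", {
  model <- toy_model()
  cfg <- train_config(batch_size = 4, steps = 8, seed = 9, lr_scale = 100,
                      objective = "contrastive")
  f1 <- train_loop(tiny_prep(), model, cfg)
  f2 <- train_loop(tiny_prep(), model, cfg)
  expect_identical(f1$metrics$loss, f2$metrics$loss)
  expect_identical(ns$model_flat_params(f1$model),
                   ns$model_flat_params(f2$model))
  expect_equal(nrow(f1$metrics), 8L)
  expect_true(all(is.finite(f1$metrics$loss)))
})

test_that("paper objective decreases in moving average on the fixture", {
  model <- toy_model()
  cfg <- train_config(batch_size = 8, steps = 30, seed = 4, lr_scale = 100,
                      objective = "paper")
  fit <- train_loop(tiny_prep(), model, cfg)
  expect_lt(mean(tail(fit$metrics$loss, 10)), mean(head(fit$metrics$loss, 10)))
  # loss components satisfy the exact identity at every logged step
  expect_equal(fit$metrics$loss,
               fit$metrics$global + 0.8 * fit$metrics$local)
})

test_that("metrics can be streamed as JSONL", {
  fn <- tempfile(fileext = ".jsonl")
  cfg <- train_config(batch_size = 4, steps = 2, seed = 1)
  train_loop(tiny_prep(), toy_model(), cfg, metrics_path = fn)
  lines <- readLines(fn)
  expect_length(lines, 2L)
  row <- jsonlite::fromJSON(lines[1])
  expect_named(row, c("step", "epoch", "loss", "global", "local"),
               ignore.order = TRUE)
})

test_that("checkpoints round-trip and validate geometry", {
  model <- toy_model()
  dir <- tempfile("ckpt")
  checkpoint_save(model, dir, trainable_only = TRUE, mode = "pretrain")
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # perturb, then restore
  flat <- ns$model_flat_params(model)
  nm <- "img/blocks/b1/ta/D/W"
  pert <- ns$set_flat_param(model, nm, flat[[nm]] + 1)
  restored <- checkpoint_load(pert, dir)
  expect_equal(ns$model_flat_params(restored)[[nm]], flat[[nm]])
  wrong <- toy_model(h = 12, d = 3)
  expect_error(checkpoint_load(wrong, dir), "geometry")
})

test_that("prepare_training_set yields grids and non-pad token ids", {
  prep <- tiny_prep()
  expect_length(prep, 8L)
  p1 <- prep[[1]]
  expect_equal(nrow(p1$grid_frontal$patches), 16L)  # 64/16 squared
  expect_true(all(p1$grid_frontal$patches >= 0 & p1$grid_frontal$patches <= 1))
  expect_true(length(p1$txt_ids) > 0 && all(p1$txt_ids != 0L))
})
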