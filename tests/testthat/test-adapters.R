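test_that("adapter_config validates its invariants", {
  cfg <- adapter_config()
  expect_equal(cfg$h, 768L)
  expect_equal(cfg$d, 64L)
  expect_equal(cfg$lambda1, 0.8)
  expect_equal(cfg$mask_rate, 0.75)
  expect_error(adapter_config(h = 6), "divisible by 4")
  expect_error(adapter_config(h = 8, d = 8), "d < h")
  expect_error(adapter_config(lambda1 = -1), "nonnegative")
  expect_error(adapter_config(mask_rate = 1), "\\[0, 1\\)")
})

test_that("he_init is seed-deterministic, zero-bias, with 2/fan_in variance", {
  ra1 <- he_init(reversible_adapter(768), seed = 42)
  ra2 <- he_init(reversible_adapter(768), seed = 42)
  expect_identical(ra1, ra2)
  ra3 <- he_init(reversible_adapter(768), seed = 43)
  expect_false(identical(ra1$D_F$W, ra3$D_F$W))

  for (nm in c("D_F", "U_F", "D_G", "U_G"))
    expect_true(all(ra1[[nm]]$b == 0))

  # fan_in = 384 for both down-projections: 147456 draws >= 1e5
  draws <- c(ra1$D_F$W, ra1$D_G$W)
  expect_gte(length(draws), 1e5)
  v_target <- 2 / 384
  se <- v_target * sqrt(2 / (length(draws) - 1))
  expect_lt(abs(var(draws) - v_target), 3 * se)

  ba <- he_init(bottleneck_adapter(768, 64, "language"), seed = 1)
  expect_true(all(ba$D$b == 0) && all(ba$U$b == 0))
  # up-projection fan_in is d
  se_u <- (2 / 64) * sqrt(2 / (length(ba$U$W) - 1))
  expect_lt(abs(var(c(ba$U$W)) - 2 / 64), 3 * se_u)
})

test_that("reversible adapter: identity at zero weights, hand-worked h=4 case", {
  ra0 <- reversible_adapter(8)
  e <- rnorm(8)
  expect_equal(reversible_forward(e, ra0), e)
  expect_equal(reversible_inverse(e, ra0), e)

  # h = 4, no biases: D maps (x1,x2) -> x1+x2, U maps s -> (s,s)
  ra <- reversible_adapter(4, use_bias = FALSE)
  ra$D_F$W <- matrix(c(1, 1), 2, 1); ra$U_F$W <- matrix(c(1, 1), 1, 2)
  ra$D_G$W <- matrix(c(1, 1), 2, 1); ra$U_G$W <- matrix(c(1, 1), 1, 2)
  e <- c(1, 2, 3, 4)
  # F((3,4)) = (7,7); o1 = (8,9); G(o1) = (17,17); o2 = (20,21)
  o <- reversible_forward(e, ra)
  expect_equal(o, c(8, 9, 20, 21))
  expect_equal(reversible_inverse(o, ra), e)
})

test_that("round trip inverse(forward(e)) = e at h in {4, 8, 768}", {
  for (h in c(4L, 8L, 768L)) {
    ra <- he_init(reversible_adapter(h), seed = h)
    set.seed(h + 1)
    E <- matrix(rnorm(1000 * h), 1000, h)
    err <- max(abs(reversible_inverse(reversible_forward(E, ra), ra) - E))
    expect_lt(err, 1e-10)
    # forward o inverse symmetry as well
    err2 <- max(abs(reversible_forward(reversible_inverse(E, ra), ra) - E))
    expect_lt(err2, 1e-10)
  }
})

test_that("reversible forward is injective on random batches", {
  ra <- he_init(reversible_adapter(8), seed = 2)
  set.seed(3)
  E <- matrix(rnorm(1e4 * 8), 1e4, 8)
  O <- reversible_forward(E, ra)
  expect_equal(nrow(unique(round(O, 12))), 1e4)
})

test_that("reversible ops reject dimension mismatches with diagnostics", {
  ra <- he_init(reversible_adapter(8), seed = 1)
  expect_error(reversible_forward(rnorm(6), ra), "expected 8, got 6")
  expect_error(reversible_inverse(rnorm(10), ra), "expected 8, got 10")
})

test_that("language adapter: zero-branch pass-through and hand arithmetic", {
  la <- bottleneck_adapter(2, 1, "language", use_bias = FALSE)
  st <- layer_state(hidden = c(3, 1), residual = c(0.5, 0.5))
  # U = 0: output = residual exactly
  expect_identical(language_adapter_apply(st, la), c(0.5, 0.5))
  # negative pre-activation: ReLU kills the branch
  la$D$W <- matrix(c(-1, -1), 2, 1); la$U$W <- matrix(c(5, 5), 1, 2)
  expect_identical(language_adapter_apply(st, la), c(0.5, 0.5))
  # D = [1, -1], U = [2, 0]^T: ReLU(2)=2 -> (4,0) + residual
  la$D$W <- matrix(c(1, -1), 2, 1); la$U$W <- matrix(c(2, 0), 1, 2)
  expect_equal(language_adapter_apply(st, la), c(4.5, 0.5))
  expect_error(language_adapter_apply(st, bottleneck_adapter(2, 1, "task")),
               "language-role")
})

test_that("task adapter mirrors the bottleneck arithmetic on la_out", {
  ta <- bottleneck_adapter(2, 1, "task", use_bias = FALSE)
  expect_identical(task_adapter_apply(c(3, 1), c(0.5, 0.5), ta), c(0.5, 0.5))
  ta$D$W <- matrix(c(1, -1), 2, 1); ta$U$W <- matrix(c(2, 0), 1, 2)
  expect_equal(task_adapter_apply(c(3, 1), c(0.5, 0.5), ta), c(4.5, 0.5))
  expect_error(task_adapter_apply(c(1, 2), c(1, 2),
                                  bottleneck_adapter(2, 1, "language")),
               "task-role")
})

test_that("transformer_adapt_layer reduces to layer_norm(residual) with zero adapters", {
  h <- 8
  lang <- bottleneck_adapter(h, 2, "language")
  task <- bottleneck_adapter(h, 2, "task")
  r <- rnorm(h)
  st <- layer_state(hidden = rnorm(h), residual = r)
  expect_equal(transformer_adapt_layer(st, lang, task), layer_norm(r))
})

test_that("layer_norm output has mean 0 / variance 1 before gain and shift", {
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(16) * 10^runif(1, -1, 2)
    y <- layer_norm(x)
    expect_lt(abs(mean(y)), 1e-10)
    expect_lt(abs(mean(y^2) - 1), 1e-3)  # population variance up to eps
  }
  expect_error(layer_norm(3), "h >= 2")
})

test_that("zero up-projections make every adapter op a residual pass-through", {
  set.seed(4)
  for (i in 1:50) {
    h <- sample(c(4, 8, 16), 1)
    ra <- he_init(reversible_adapter(h), seed = i)
    ra$U_F$W[] <- 0; ra$U_F$b[] <- 0; ra$U_G$W[] <- 0; ra$U_G$b[] <- 0
    e <- rnorm(h)
    expect_equal(reversible_forward(e, ra), e)
    la <- he_init(bottleneck_adapter(h, 2, "language"), seed = i)
    la$U$W[] <- 0; la$U$b[] <- 0
    r <- rnorm(h)
    expect_identical(language_adapter_apply(layer_state(rnorm(h), r), la), r)
  }
})
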