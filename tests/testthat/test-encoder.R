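sfns <- asNamespace("scaleformer")

test_that("LPU residual collapses to identity with zero projection", {
  set.seed(11)
  m <- lpu(4, 4, downsample = FALSE)
  m$proj$w$v[] <- 0; m$proj$b$v[] <- 0
  x <- array(rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 2))
  expect_identical(lpu_forward(x, m), x)
})

test_that("downsampling LPU halves the spatial size", {
  m <- lpu(4, 6, downsample = TRUE)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  expect_equal(dim(lpu_forward(x, m)), c(4, 4, 6))
})

test_that("LPU matches a hand-rolled sequential evaluation", {
  set.seed(12)
  m <- lpu(1, 1, downsample = FALSE, expand = 2)
  x3 <- array(rnorm(4), c(2, 2, 1))
  # oracle: Norm -> 1x1 expand (+BN, gelu) -> DW 3x3 (+BN, gelu) -> SE ->
  #         1x1 shrink, plus identity skip
  g <- function(p) as.numeric(p$v)
  y <- naive_bn_single(x3, g(m$norm$gamma), g(m$norm$beta))
  y <- naive_proj(y, m$expandp)
  y <- naive_gelu(naive_bn_single(y, g(m$bn1$gamma), g(m$bn1$beta)))
  dw <- array(0, c(3, 3, dim(y)[3], dim(y)[3]))
  for (c in seq_len(dim(y)[3])) dw[, , c, c] <- m$dw$w$v[, , c]
  y <- naive_conv2d(y, dw, g(m$dw$b), stride = 1, pad = 1)
  y <- naive_gelu(naive_bn_single(y, g(m$bn2$gamma), g(m$bn2$beta)))
  pooled <- apply(y, 3, mean)
  h <- naive_gelu(m$se$fc1$W$v %*% pooled + g(m$se$fc1$b))
  sgate <- 1 / (1 + exp(-(m$se$fc2$W$v %*% h + g(m$se$fc2$b))))
  for (c in seq_len(dim(y)[3])) y[, , c] <- y[, , c] * sgate[c]
  ref <- x3 + naive_proj(y, m$proj)
  expect_equal(lpu_forward(x3, m), ref, tolerance = 1e-6)
})

test_that("LPU with circular padding is translation-equivariant", {
  set.seed(13)
  m <- lpu(3, 3, downsample = FALSE, pad_mode = "circular")
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  shift1 <- function(a) a[c(8, 1:7), , , drop = FALSE]
  y <- lpu_forward(x, m)
  y_shifted <- lpu_forward(shift1(x), m)
  expect_equal(y_shifted, shift1(y), tolerance = 1e-5)
})

test_that("FFN is a pointwise two-layer map preserving shape", {
  m <- ffn(3, ratio = 2)
  x <- array(rnorm(5 * 7 * 3), c(5, 7, 3))
  expect_equal(dim(ffn_forward(x, m)), dim(x))
  for (p in sfns$sf_parameters(m)) p$v[] <- 0
  expect_true(all(ffn_forward(x, m) == 0))
  # seeded case against a hand computation
  set.seed(14)
  m2 <- ffn(2, ratio = 2)
  x2 <- array(rnorm(4), c(1, 2, 2))  # 1x2 map, 2 channels
  W1 <- matrix(m2$fc1$w$v, 2, 4); b1 <- as.numeric(m2$fc1$b$v)
  W2 <- matrix(m2$fc2$w$v, 4, 2); b2 <- as.numeric(m2$fc2$b$v)
  ref <- x2
  for (i in 1:1) for (j in 1:2) {
    h <- naive_gelu(as.numeric(x2[i, j, ] %*% W1) + b1)
    ref[i, j, ] <- as.numeric(h %*% W2) + b2
  }
  expect_equal(ffn_forward(x2, m2), ref, tolerance = 1e-10)
})

test_that("MSEAU equals its four explicit pre-norm residual sub-steps", {
  set.seed(15)
  m <- mseau(4, c(1, 2), isa_groups = 2, ffn_ratio = 2)
  x <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  ln <- function(lnm, a) {
    out <- a
    for (i in seq_len(dim(a)[1])) for (j in seq_len(dim(a)[2])) {
      v <- a[i, j, ]
      mu <- mean(v); va <- mean(v^2) - mu^2
      out[i, j, ] <- as.numeric(lnm$gamma$v) * (v - mu) / sqrt(va + 1e-5) +
        as.numeric(lnm$beta$v)
    }
    out
  }
  y <- x + gmsa_forward(ln(m$ln1, x), m$gmsa)
  y <- y + ffn_forward(ln(m$ln2, y), m$ffn1)
  y <- y + isa_forward(ln(m$ln3, y), m$isa)
  y <- y + ffn_forward(ln(m$ln4, y), m$ffn2)
  expect_equal(mseau_forward(x, m), y, tolerance = 1e-6)
})

test_that("zero-weight MSEAU is the identity (pure residual)", {
  m <- mseau(4, c(1, 2), isa_groups = 2, ffn_ratio = 2)
  for (p in sfns$sf_parameters(m)) p$v[] <- 0
  x <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  expect_equal(mseau_forward(x, m), x, tolerance = 1e-12)
})

test_that("MSEAU output is finite and shape-stable across seeds", {
  m <- mseau(4, c(1, 2), isa_groups = 2, ffn_ratio = 2)
  for (s in 1:20) {
    set.seed(s)
    x <- array(rnorm(4 * 4 * 4, sd = 2), c(4, 4, 4))
    out <- mseau_forward(x, m)
    expect_equal(dim(out), dim(x))
    expect_true(all(is.finite(out)))
  }
})

test_that("encoder emits the 56/28/14/7 pyramid at 224 input", {
  set.seed(16)
  enc <- encoder(input_size = 224L, in_channels = 1L,
                 channels = c(8L, 8L, 8L, 8L), depths = c(1L, 1L, 1L, 1L),
                 ffn_ratio = 2L, lpu_expand = 2L)
  x <- array(rnorm(224 * 224), c(224, 224, 1))
  pyr <- encoder_forward(x, enc, train = TRUE)
  expect_equal(vapply(pyr, function(p) dim(p)[1], numeric(1)),
               c(stride4 = 56, stride8 = 28, stride16 = 14, stride32 = 7))
  # the default scale plan divides every stage resolution at 224
  res <- c(56, 28, 14, 7)
  scales <- list(c(1, 2, 4, 7), c(1, 2, 4, 7), c(1, 7), c(1, 7))
  for (i in 1:4) expect_true(all(res[i] %% scales[[i]] == 0))
})

test_that("encoder emits the 64/32/16/8 pyramid at 256 input", {
  enc <- encoder(input_size = 256L, in_channels = 1L,
                 channels = c(8L, 8L, 8L, 8L), depths = c(1L, 1L, 1L, 1L),
                 ffn_ratio = 2L, lpu_expand = 2L)
  x <- array(rnorm(256 * 256), c(256, 256, 1))
  pyr <- encoder_forward(x, enc, train = TRUE)
  expect_equal(unname(vapply(pyr, function(p) dim(p)[1], numeric(1))),
               c(64, 32, 16, 8))
})

test_that("encoder rejects inputs not divisible by 32", {
  expect_error(encoder(input_size = 100L), "divisible by 32")
  enc <- encoder(input_size = 64L, channels = c(8L, 8L, 8L, 8L),
                 depths = c(1L, 1L, 1L, 1L), ffn_ratio = 2L, lpu_expand = 2L)
  expect_error(encoder_forward(array(0, c(60, 60, 1)), enc),
               "divisible by 32; resize")
})

test_that("every parameter receives gradient after one optimization step", {
  # 64-pixel input keeps stage 4 at 2x2: every attention path stays active
  m <- scaleformer(input_size = 64L, in_channels = 1L, num_classes = 3L,
                   stage_channels = c(8L, 8L, 8L, 8L),
                   stage_depths = c(1L, 1L, 1L, 1L),
                   ffn_ratio = 2L, lpu_expand = 2L, seed = 5)
  spec <- scene_spec(seed = 5L)
  ds <- generate_dataset(spec, 4)
  ba <- sfns$batch_arrays(ds, 1:2)
  bundle <- sfns$model_forward_t(m, sfns$new_tensor(ba$x), TRUE)
  loss <- sfns$total_loss_t(bundle, ba$y, loss_config())
  params <- sfns$sf_parameters(m)
  sfns$zero_grads(params)
  sfns$sf_backward(loss)
  grad_norms <- vapply(params, function(p) {
    if (is.null(p$grad)) 0 else sqrt(sum(p$grad^2))
  }, numeric(1))
  expect_true(all(grad_norms > 0),
              info = paste("dead:", paste(names(params)[grad_norms == 0],
                                          collapse = ", ")))
})
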