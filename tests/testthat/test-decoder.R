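sfns <- asNamespace("scaleformer")

test_that("CPB gates are sigmoid-bounded and zero fusion collapses to enc", {
  set.seed(21)
  m <- cpb(4)
  enc <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  dec <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  # internal gate is a sigmoid: out - enc = gate * x', bounded by |x'|
  m0 <- cpb(4)
  m0$fuse$w$v[] <- 0; m0$fuse$b$v[] <- 0
  expect_equal(cpb_forward(enc, dec, m0), enc, tolerance = 1e-12)
  expect_error(cpb_forward(enc, array(0, c(2, 2, 4)), m), "spatial mismatch")
})

test_that("CPB matches its step-by-step oracle", {
  set.seed(22)
  m <- cpb(2)
  enc <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  dec <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  cat2 <- array(c(enc, dec), c(3, 3, 4))
  pooled <- apply(cat2, 3, mean)
  h <- naive_gelu(m$se$fc1$W$v %*% pooled + as.numeric(m$se$fc1$b$v))
  sg <- 1 / (1 + exp(-(m$se$fc2$W$v %*% h + as.numeric(m$se$fc2$b$v))))
  se_out <- cat2
  for (c in 1:4) se_out[, , c] <- cat2[, , c] * sg[c]
  xp <- naive_conv2d(se_out, m$fuse$w$v, as.numeric(m$fuse$b$v), 1, 1)
  gate <- 1 / (1 + exp(-naive_conv2d(dec, m$gate$w$v,
                                     as.numeric(m$gate$b$v), 1, 1)))
  ref <- enc + gate * xp
  expect_equal(cpb_forward(enc, dec, m), ref, tolerance = 1e-6)
})

test_that("Inception equals the concatenation of its branches", {
  set.seed(23)
  m <- inception(4)
  x <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  out <- inception_forward(x, m)
  expect_equal(dim(out), dim(x))
  # branch decomposition with direct-loop convolutions
  b1 <- naive_proj(x, m$b1)
  b3 <- naive_conv2d(x, m$b3$w$v, as.numeric(m$b3$b$v), 1, 1)
  b5 <- naive_conv2d(naive_conv2d(x, m$b5a$w$v, as.numeric(m$b5a$b$v), 1, 1),
                     m$b5b$w$v, as.numeric(m$b5b$b$v), 1, 1)
  padded <- array(0, c(7, 7, 4)); padded[2:6, 2:6, ] <- x
  pooled <- array(0, c(5, 5, 4))
  for (i in 1:5) for (j in 1:5) for (c in 1:4) {
    pooled[i, j, c] <- mean(padded[i:(i + 2), j:(j + 2), c])
  }
  bp <- naive_proj(pooled, m$bp)
  ref <- naive_proj(array(c(b1, b3, b5, bp), c(5, 5, 4)), m$proj)
  expect_equal(out, ref, tolerance = 1e-6)
  for (p in sfns$sf_parameters(m)) p$v[] <- 0
  expect_true(all(inception_forward(x, m) == 0))
  expect_error(inception(6), "divisible by 4")
})

test_that("CSA multipliers are bounded and spatially constant on uniform input", {
  set.seed(24)
  m <- csa(4)
  # uniform map: the spatial attention statistics are constant, so each
  # channel of the output is spatially constant
  x <- array(rep(c(0.3, -1, 2, 0.5), each = 25), c(5, 5, 4))
  out <- csa_forward(x, m)
  for (c in 1:4) expect_lt(diff(range(out[, , c])), 1e-12)
  # sequential oracle: SE channel gate then mean/max spatial gate with
  # replicate-padded 7x7 conv
  x2 <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  pooled <- apply(x2, 3, mean)
  h <- naive_gelu(m$ca$fc1$W$v %*% pooled + as.numeric(m$ca$fc1$b$v))
  cg <- 1 / (1 + exp(-(m$ca$fc2$W$v %*% h + as.numeric(m$ca$fc2$b$v))))
  y <- x2
  for (c in 1:4) y[, , c] <- x2[, , c] * cg[c]
  stats <- array(0, c(4, 4, 2))
  stats[, , 1] <- apply(y, c(1, 2), mean)
  stats[, , 2] <- apply(y, c(1, 2), max)
  padded <- array(0, c(10, 10, 2))
  for (i in 1:10) for (j in 1:10) {
    padded[i, j, ] <- stats[min(max(i - 3, 1), 4), min(max(j - 3, 1), 4), ]
  }
  sgate <- 1 / (1 + exp(-naive_conv2d(padded, m$sa$w$v,
                                      as.numeric(m$sa$b$v), 1, 0)))
  ref <- y
  for (c in 1:4) ref[, , c] <- y[, , c] * sgate[, , 1]
  expect_equal(csa_forward(x2, m), ref, tolerance = 1e-6)
  expect_true(all(cg > 0 & cg < 1) && all(sgate > 0 & sgate < 1))
})

test_that("stems produce cascaded full and half resolution features", {
  set.seed(25)
  m <- stems(1, 4)
  img <- array(rnorm(8 * 8), c(8, 8, 1))
  fs <- stem_features(img, m)
  expect_equal(dim(fs$f_full)[1:2], c(8, 8))
  expect_equal(dim(fs$f_half)[1:2], c(4, 4))
  # f_half is computed from f_full, not from the raw image: changing conv1
  # must change f_half too
  m$c1$w$v[] <- m$c1$w$v * 2
  fs2 <- stem_features(img, m)
  expect_gt(max(abs(fs2$f_half - fs$f_half)), 1e-8)
  # oracle for the first block
  ref_full <- naive_conv2d(img, m$c1$w$v, as.numeric(m$c1$b$v), 1, 1)
  ref_full <- pmax(naive_bn_single(ref_full, as.numeric(m$bn1$gamma$v),
                                   as.numeric(m$bn1$beta$v)), 0)
  expect_equal(fs2$f_full, ref_full, tolerance = 1e-6)
})

test_that("simple fusion upsamples, concatenates and projects", {
  set.seed(26)
  m <- simple_fusion_block(2, 3, 4)
  high <- array(rnorm(2 * 2 * 2), c(2, 2, 2))
  low <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  out <- simple_fusion(high, low, m)
  expect_equal(dim(out), c(4, 4, 4))
  for (p in sfns$sf_parameters(m)) p$v[] <- 0
  out0 <- simple_fusion(high, low, m)
  expect_true(all(out0 == 0))
  expect_error(simple_fusion(high, array(0, c(3, 3, 3)), m), "not 2x")
})

test_that("decoder emits full-resolution main logits and strided aux maps", {
  set.seed(27)
  model <- scaleformer(input_size = 224L, in_channels = 1L, num_classes = 9L,
                       stage_channels = c(8L, 8L, 8L, 8L),
                       stage_depths = c(1L, 1L, 1L, 1L),
                       ffn_ratio = 2L, lpu_expand = 2L)
  img <- array(rnorm(224 * 224), c(224, 224, 1))
  bundle <- model_forward(model, img, train = TRUE)
  expect_equal(dim(bundle$main), c(224, 224, 9))
  expect_equal(dim(bundle$aux8)[1:2], c(28, 28))
  expect_equal(dim(bundle$aux16)[1:2], c(14, 14))
  expect_equal(dim(bundle$aux32)[1:2], c(7, 7))
  expect_true(all(vapply(bundle, function(b) all(is.finite(b)), logical(1))))
  expect_true(all(vapply(bundle, function(b) dim(b)[3] == 9, logical(1))))
})

test_that("aux heads are leaves: zeroing them leaves main logits unchanged", {
  set.seed(28)
  model <- tiny_model(seed = 3)
  img <- array(rnorm(32 * 32), c(32, 32, 1))
  before <- model_forward(model, img, train = FALSE)
  model$decoder$aux8$w$v[] <- 0
  model$decoder$aux16$w$v[] <- 0
  model$decoder$aux32$w$v[] <- 0
  after <- model_forward(model, img, train = FALSE)
  expect_identical(after$main, before$main)
  expect_true(all(after$aux8 == 0))
})
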