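test_that("split_channels partitions and round-trips exactly", {
  set.seed(1)
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  parts <- split_channels(x, c(4, 4))
  expect_length(parts, 2)
  expect_equal(dim(parts[[1]]), c(4, 4, 4))
  recombined <- array(0, dim(x))
  recombined[, , 1:4] <- parts[[1]]
  recombined[, , 5:8] <- parts[[2]]
  expect_identical(recombined, x)            # bit-exact round trip
  expect_identical(split_channels(x, 8)[[1]], x)
  expect_error(split_channels(x, c(3, 3)), "sum to 6.*8 channels")
})

test_that("tokenize pools patches by their mean, in row-major order", {
  m <- matrix(1:16, 4, 4, byrow = TRUE)
  expect_equal(as.numeric(tokenize(m, 2)), c(3.5, 5.5, 11.5, 13.5))
  # s = 1: the global spatial mean, per channel
  x <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  expect_equal(as.numeric(tokenize(x, 1)),
               apply(x, 3, mean), tolerance = 1e-12)
  # H = W = s: the pixels themselves, row-major
  expect_equal(as.numeric(tokenize(m, 4)), as.numeric(t(m)))
  expect_error(tokenize(m, 0), "positive")
  expect_error(tokenize(m, 5), "exceeds")
})

test_that("tokenize edge-pads non-divisible maps before pooling", {
  m <- matrix(1:15, 3, 5, byrow = TRUE)  # 3x5, s = 2 -> pad to 4x6
  tok <- tokenize(m, 2)
  ref <- naive_pool_tokens(m, 2)
  expect_equal(as.numeric(tok), ref, tolerance = 1e-12)
})

test_that("detokenize inverts tokenize on patch-constant maps", {
  blocks <- rbind(cbind(matrix(2, 2, 2), matrix(7, 2, 2)),
                  cbind(matrix(-1, 2, 2), matrix(4, 2, 2)))
  x <- array(blocks, c(4, 4, 1))
  expect_equal(detokenize(tokenize(x, 2), 2, 4, 4), x, tolerance = 1e-12)
  # s = 1 broadcasts a constant
  expect_equal(detokenize(matrix(3.2, 1, 1), 1, 5, 7),
               array(3.2, c(5, 7, 1)))
  out <- detokenize(matrix(c(3.5, 5.5, 11.5, 13.5), 4, 1), 2, 4, 4)
  expect_equal(out[, , 1], blocks * 0 +
                 rbind(cbind(matrix(3.5, 2, 2), matrix(5.5, 2, 2)),
                       cbind(matrix(11.5, 2, 2), matrix(13.5, 2, 2))))
  expect_error(detokenize(matrix(1, 3, 1), 2, 4, 4), "expected 4 tokens")
})

test_that("scaled dot attention follows the softmax(QK'/sqrt(d))V formula", {
  # N = 1: weight is exactly 1, output equals V
  q <- matrix(0.3, 1, 2); k <- matrix(-2, 1, 2); v <- matrix(c(5, -1), 1, 2)
  expect_equal(scaled_dot_attention(q, k, v), v)
  # zero keys: uniform weights, rows equal the mean of V
  set.seed(2)
  q <- matrix(rnorm(8), 4, 2); v <- matrix(rnorm(8), 4, 2)
  out <- scaled_dot_attention(q, matrix(0, 4, 2), v)
  expect_equal(out, matrix(colMeans(v), 4, 2, byrow = TRUE),
               tolerance = 1e-12)
  # hand-computed softmax with the sqrt(d) scale folded into K
  out <- scaled_dot_attention(matrix(c(1, 1), 2, 1),
                              matrix(c(0, log(3)), 2, 1),
                              matrix(c(0, 1), 2, 1))
  expect_equal(as.numeric(out), c(0.75, 0.75), tolerance = 1e-12)
  expect_error(scaled_dot_attention(q, q, v, heads = 3), "divisible")
})

test_that("attention weights are convex: rows sum to 1 across seeded trials", {
  for (trial in 1:100) {
    set.seed(trial)
    N <- sample(2:6, 1)
    q <- matrix(rnorm(N * N, sd = 3), N, N)
    k <- matrix(rnorm(N * N, sd = 3), N, N)
    # V = identity exposes the weight matrix itself
    w <- scaled_dot_attention(q, k, diag(N))
    expect_true(all(abs(rowSums(w) - 1) < 1e-6))
    expect_true(all(w >= 0))
  }
})

test_that("gmsa_forward matches the brute-force composition on a grid", {
  for (H in c(4, 8)) for (G in c(1, 2, 4)) for (s in c(1, 2, 4)) {
    if (s > H) next
    set.seed(100 * H + 10 * G + s)
    C <- 8L
    scales <- rep(s, G)
    if (G > 1) scales[1] <- 1L   # mix scales where there is room
    m <- gmsa(C, scales)
    x <- array(rnorm(H * H * C), c(H, H, C))
    expect_equal(gmsa_forward(x, m), naive_gmsa(x, m), tolerance = 1e-5,
                 label = sprintf("H=%d G=%d s=%d", H, G, s))
  }
})

test_that("gmsa_forward validates channels and scales informatively", {
  m <- gmsa(8, c(1, 2))
  x <- array(rnorm(4 * 4 * 6), c(4, 4, 6))
  expect_error(gmsa_forward(x, m), "6 channels.*expects 8")
  m7 <- gmsa(8, c(1, 7))
  x4 <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  expect_error(gmsa_forward(x4, m7), "s=7 exceeds the 4x4")
})

test_that("zero projections collapse GMSA to the zero map", {
  m <- gmsa(8, c(1, 2))
  for (p in asNamespace("scaleformer")$sf_parameters(m)) p$v[] <- 0
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  out <- gmsa_forward(x, m)
  expect_equal(dim(out), dim(x))
  expect_true(all(out == 0))
})

test_that("G=1, s=1 collapses to projected global mean broadcast", {
  set.seed(9)
  m <- gmsa(4, 1L)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  out <- gmsa_forward(x, m)
  gmean <- apply(x, 3, mean)
  Wv <- matrix(m$groups[[1]]$v$w$v, 4, 4)
  Wo <- matrix(m$groups[[1]]$o$w$v, 4, 4)
  tok <- as.numeric(gmean %*% Wv) + as.numeric(m$groups[[1]]$v$b$v)
  ref_pix <- as.numeric(tok %*% Wo) + as.numeric(m$groups[[1]]$o$b$v)
  for (c in 1:4) {
    expect_true(all(abs(out[, , c] - ref_pix[c]) < 1e-6))
  }
})

test_that("measured attention-score multiplies scale as s^4", {
  d <- 8L
  macs <- vapply(c(2L, 4L, 8L), function(s) {
    m <- gmsa(d, s, heads_per_group = 1L)
    x <- array(rnorm(8 * 8 * d), c(8, 8, d))
    sf_reset_counters()
    gmsa_forward(x, m)
    sf_counters()$attn_macs
  }, numeric(1))
  fit <- stats::lm(log(macs) ~ log(c(2, 4, 8)))
  expect_equal(unname(coef(fit)[2]), 4, tolerance = 0.01)
  # equal widths, s = 2 vs s = 4: cost ratio exactly (4/2)^4
  expect_equal(macs[2] / macs[1], 16)
})

test_that("gmsa_cost reports token counts and the s^4 d cost law", {
  m <- gmsa(8, c(1, 2, 4, 7), group_widths = c(2, 2, 2, 2))
  rep <- gmsa_cost(m, stage_resolution = 56)
  expect_equal(rep$groups$tokens, c(1, 4, 16, 49))
  expect_equal(rep$groups$attn_macs / 2, c(1, 16, 256, 2401))
  expect_equal(rep$total_macs, sum(c(1, 16, 256, 2401) * 2))
  expect_true(all(rep$scale_fits))
  # single group s = 1: one token, cost proportional to d
  r1 <- gmsa_cost(list(scales = 1L, group_widths = 16L))
  expect_equal(r1$groups$tokens, 1)
  expect_equal(r1$groups$attn_macs, 16)
  js <- gmsa_cost(m, json = TRUE)
  expect_true(jsonlite::validate(js))
})
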