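test_that("dice loss hits its closed-form anchors", {
  # perfect overlap -> 0 (eps-tolerant)
  y <- array(0, c(4, 4, 1)); y[1:2, 1:2, 1] <- 1
  expect_lt(dice_loss(y, y), 1e-5)
  # disjoint crisp masks -> ~1
  p <- array(0, c(4, 4, 1)); p[3:4, 3:4, 1] <- 1
  expect_gt(dice_loss(p, y), 1 - 1e-4)
  # |int| = 2, |p| = |y| = 4 -> 1 - 4/8 = 0.5
  p2 <- array(0, c(4, 4, 1)); p2[1:2, 2:3, 1] <- 1
  y2 <- array(0, c(4, 4, 1)); y2[1:2, 1:2, 1] <- 1
  expect_equal(dice_loss(p2, y2), 0.5, tolerance = 1e-5)
  expect_error(dice_loss(p2, array(0, c(2, 2, 1))), "shapes differ")
})

test_that("dice loss is bounded and monotone in added true positives", {
  # brute force over all 2^9 predictions on a 3x3 grid, fixed target
  target <- matrix(c(1, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3)
  yt <- array(target, c(3, 3, 1))
  for (code in 0:511) {
    bits <- as.integer(intToBits(code)[1:9])
    pred <- matrix(bits, 3, 3)
    pa <- array(pred, c(3, 3, 1))
    l0 <- dice_loss(pa, yt)
    expect_gte(l0, 0); expect_lte(l0, 1)
    # add one currently-missed true-positive pixel, if any
    missed <- which(target == 1 & pred == 0)
    if (length(missed)) {
      pred2 <- pred; pred2[missed[1]] <- 1
      expect_lte(dice_loss(array(pred2, c(3, 3, 1)), yt), l0 + 1e-12)
    }
  }
})

test_that("combined loss is the stated CE/Dice weighting", {
  cfg <- loss_config()
  expect_equal(cfg$ce_weight, 0.3)
  expect_equal(cfg$dice_weight, 0.7)
  # weight arithmetic on constructed components
  expect_equal(0.3 * 1 + 0.7 * 0, 0.3)
  set.seed(31)
  logits <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  target <- matrix(sample(0:2, 16, TRUE), 4, 4)
  cl <- combined_loss(logits, target, cfg)
  expect_equal(as.numeric(cl),
               0.3 * attr(cl, "ce") + 0.7 * attr(cl, "dice"),
               tolerance = 1e-12)
  # the parts themselves decompose: pure-CE and pure-Dice configs
  ce_only <- combined_loss(logits, target, loss_config(1, 0))
  dice_only <- combined_loss(logits, target, loss_config(0, 1))
  expect_equal(as.numeric(cl),
               0.3 * as.numeric(ce_only) + 0.7 * as.numeric(dice_only),
               tolerance = 1e-12)
})

test_that("branch weights are 0.7/0.1/0.1/0.1 and sum to one", {
  cfg <- loss_config()
  expect_equal(cfg$branch_weights, c(0.7, 0.1, 0.1, 0.1))
  expect_equal(sum(cfg$branch_weights), 1)
  expect_error(loss_config(branch_weights = c(0.5, 0.1, 0.1, 0.1)),
               "sum to 1")
})

test_that("total loss equals the hand-weighted branch sum", {
  set.seed(32)
  K <- 3
  bundle <- list(
    main = array(rnorm(16 * 16 * K), c(16, 16, K)),
    aux8 = array(rnorm(2 * 2 * K), c(2, 2, K)),
    aux16 = array(rnorm(1 * 1 * K), c(1, 1, K)),
    aux32 = array(rnorm(1 * 1 * K), c(1, 1, K)))
  target <- matrix(sample(0:(K - 1), 256, TRUE), 16, 16)
  cfg <- loss_config()
  tl <- total_loss(bundle, target, cfg)
  br <- attr(tl, "branches")
  expect_equal(as.numeric(tl), sum(cfg$branch_weights * br),
               tolerance = 1e-12)
  # each branch equals combined_loss of the upsampled logits
  sfns <- asNamespace("scaleformer")
  up <- sfns$tval(sfns$op_bilinear(sfns$new_tensor(
    array(bundle$aux8, c(2, 2, K, 1))), 16L, 16L))
  expect_equal(br[2], as.numeric(combined_loss(array(up, c(16, 16, K)),
                                               target, cfg)),
               tolerance = 1e-12)
  # aux disabled: total is exactly the main combined loss
  cfg1 <- loss_config(branch_weights = c(1, 0, 0, 0))
  t1 <- total_loss(list(main = bundle$main), target, cfg1)
  expect_equal(as.numeric(t1),
               as.numeric(combined_loss(bundle$main, target, cfg1)),
               tolerance = 1e-12)
  # equal branch losses: total equals the common value (weights sum to 1)
  same <- list(main = bundle$main, aux8 = bundle$main,
               aux16 = bundle$main, aux32 = bundle$main)
  ts <- total_loss(same, target, cfg)
  expect_equal(as.numeric(ts), br[1], tolerance = 1e-12)
  # missing aux with positive aux weights is an error
  expect_error(total_loss(list(main = bundle$main), target, cfg),
               "auxiliary branches missing")
})

test_that("losses vanish only in the perfect-prediction limit", {
  target <- matrix(c(0, 1, 1, 0), 2, 2)
  good <- array(0, c(2, 2, 2))
  good[, , 1] <- (target == 0) * 50 - 25
  good[, , 2] <- (target == 1) * 50 - 25
  cl <- combined_loss(good, target)
  expect_lt(as.numeric(cl), 1e-4)
  bad <- -good
  expect_gt(as.numeric(combined_loss(bad, target)), 0.5)
})
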