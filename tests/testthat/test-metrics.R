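test_that("Dice percentage matches the set formula and is symmetric", {
  a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L
  expect_equal(unname(dsc(a, a)), 100)
  b <- matrix(0L, 4, 4); b[3:4, 3:4] <- 1L
  expect_equal(unname(dsc(a, b)), 0)
  # |int| = 2, |P| = |G| = 4 -> 50
  p <- matrix(0L, 4, 4); p[1:2, 2:3] <- 1L
  g <- matrix(0L, 4, 4); g[1:2, 1:2] <- 1L
  expect_equal(unname(dsc(p, g)), 50)
  expect_equal(dsc(p, g), dsc(g, p))
  # empty-vs-empty class scores 100
  e <- matrix(0L, 4, 4)
  expect_equal(unname(dsc(e, e, classes = 2)), 100)
  set.seed(41)
  for (i in 1:20) {
    x <- matrix(sample(0:2, 36, TRUE), 6, 6)
    y <- matrix(sample(0:2, 36, TRUE), 6, 6)
    expect_equal(dsc(x, y), dsc(y, x))
  }
})

test_that("HD95 anchors: identity and single-pixel distance", {
  m <- matrix(0L, 8, 8); m[2:5, 3:6] <- 1L
  expect_equal(hd95(m, m), 0)
  a <- matrix(0L, 8, 8); a[1, 1] <- 1L
  b <- matrix(0L, 8, 8); b[4, 5] <- 1L
  expect_equal(hd95(a, b), 5)       # 3-4-5 triangle
  expect_equal(hd95(a, b, spacing = c(2, 2)), 10)
})

test_that("HD95 equals the exhaustive boundary oracle on random masks", {
  for (seed in 1:50) {
    set.seed(seed)
    a <- matrix(0L, 16, 16)
    b <- matrix(0L, 16, 16)
    # random blobby masks: a few rectangles each
    for (r in 1:3) {
      i <- sample(1:12, 1); j <- sample(1:12, 1)
      a[i:(i + sample(1:4, 1)), j:(j + sample(1:4, 1))] <- 1L
      i <- sample(1:12, 1); j <- sample(1:12, 1)
      b[i:(i + sample(1:4, 1)), j:(j + sample(1:4, 1))] <- 1L
    }
    expect_equal(hd95(a, b), naive_hd(a, b), tolerance = 1e-12)
    # HD95 never exceeds the full Hausdorff distance
    expect_lte(hd95(a, b), hd95(a, b, probs = 1))
    expect_equal(hd95(a, b, probs = 1), naive_hd(a, b, 1),
                 tolerance = 1e-12)
  }
})

test_that("empty masks yield the flagged worst-case sentinel, never 0", {
  gt <- matrix(0L, 10, 10); gt[3:5, 3:5] <- 1L
  empty <- matrix(0L, 10, 10)
  out <- hd95(empty, gt)
  expect_equal(as.numeric(out), sqrt(200))
  expect_true(isTRUE(attr(out, "empty_mask")))
})

test_that("confusion metrics follow the TP/FP/TN/FN definitions", {
  g <- matrix(0L, 4, 4); g[1, 1:3] <- 1L
  p <- g
  expect_equal(confusion_metrics(p, g),
               c(miou = 1, acc = 1, sen = 1, spe = 1))
  # all-background prediction with non-empty ground truth: Sen = 0
  expect_equal(unname(confusion_metrics(matrix(0L, 4, 4), g)[["sen"]]), 0)
  # hand counts: TP=2, FP=1, FN=1, TN=12
  g2 <- matrix(0L, 4, 4); g2[1, 1:3] <- 1L
  p2 <- matrix(0L, 4, 4); p2[1, 1:2] <- 1L; p2[2, 1] <- 1L
  cm <- confusion_metrics(p2, g2)
  expect_equal(unname(cm[["sen"]]), 2 / 3)
  expect_equal(unname(cm[["spe"]]), 12 / 13)
  expect_equal(unname(cm[["acc"]]), 14 / 16)
  expect_equal(unname(cm[["miou"]]), mean(c(2 / 4, 12 / 14)))
  # zero denominators are NA, not 0
  allfg <- matrix(1L, 2, 2)
  expect_true(is.na(confusion_metrics(allfg, allfg)[["spe"]]))
})

test_that("paired t-test matches the closed form and edge policies", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(1.1, 2.2, 2.9, 4.3, 5.1)
  r <- paired_t_test(a, b)
  ref <- naive_paired_t(a, b)
  expect_equal(r$t, ref$t, tolerance = 1e-10)
  expect_equal(r$p, ref$p, tolerance = 1e-10)
  # CI from the textbook formula
  expect_equal(unname(r$ci_a["lower"]),
               mean(a) - qt(0.975, 4) * sd(a) / sqrt(5), tolerance = 1e-12)
  # identical scores: t = 0, p = 1, not significant
  r0 <- paired_t_test(a, a)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_false(r0$significant)
  # swapping the arguments flips only the sign of t
  r_swap <- paired_t_test(b, a)
  expect_equal(r_swap$t, -r$t, tolerance = 1e-12)
  expect_equal(r_swap$p, r$p, tolerance = 1e-12)
  expect_error(paired_t_test(1, 1), "at least 2")
  expect_error(paired_t_test(a, b[1:3]), "unequal")
})

test_that("a t of 2.4532 over 808 paired cases is flagged significant", {
  # construct per-case differences with exact sample mean and sd so the
  # paired statistic reproduces a t = 2.4532 comparison over 808 cases
  set.seed(42)
  n <- 808
  d <- as.numeric(scale(rnorm(n)))          # mean 0, sd 1 exactly
  d <- d * 0.02 + 2.4532 * 0.02 / sqrt(n)   # sd 0.02, t = 2.4532
  base <- rnorm(n, 0.88, 0.01)
  r <- paired_t_test(base + d, base)
  expect_equal(r$t, 2.4532, tolerance = 1e-10)
  expect_equal(round(r$p, 4), 0.0144)   # agreement at the printed precision
  expect_true(r$significant)
})

test_that("ttest_table assembles a comparison report", {
  set.seed(43)
  ref <- rnorm(20, 0.9, 0.02)
  comp <- list(modelA = ref - 0.01 + rnorm(20, 0, 0.004),
               modelB = ref - 0.02 + rnorm(20, 0, 0.004))
  tb <- ttest_table(ref, comp, reference_name = "ours")
  expect_equal(nrow(tb), 3)
  expect_equal(tb$method, c("modelA", "modelB", "ours"))
  expect_true(all(c("t", "p", "significant", "ci_lower", "ci_upper")
                  %in% names(tb)))
  expect_true(all(tb$ci_lower <= tb$ci_upper))
  expect_true(is.na(tb$t[3]))
})
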