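# Evaluation metrics: per-class Dice similarity (percent), 95th-percentile
# Hausdorff distance over boundary point sets, confusion-matrix rates, and
# the paired t-test with 95% confidence intervals used for model comparison.

#' Dice similarity coefficient (percent)
#'
#' `2 |P & G| / (|P| + |G|) * 100` per class. A class empty in both masks is
#' scored 100 (perfect agreement on absence).
#'
#' @param pred_mask,gt_mask Integer label matrices of equal shape.
#' @param classes Classes to score; default: every non-background label
#'   present in either mask (class 1 if none).
#' @return Named numeric vector of per-class Dice percentages.
#' @export
dsc <- function(pred_mask, gt_mask, classes = NULL) {
  if (!identical(dim(pred_mask), dim(gt_mask))) {
    stop("dsc(): mask shapes differ")
  }
  if (is.null(classes)) {
    classes <- setdiff(sort(unique(c(as.integer(pred_mask),
                                     as.integer(gt_mask)))), 0L)
    if (!length(classes)) classes <- 1L
  }
  out <- vapply(classes, function(k) {
    p <- pred_mask == k
    g <- gt_mask == k
    denom <- sum(p) + sum(g)
    if (denom == 0) 100 else 200 * sum(p & g) / denom
  }, numeric(1))
  names(out) <- paste0("class", classes)
  out
}

# Boundary pixels: inside the mask with at least one 4-neighbour outside
# (the image border counts as outside).
boundary_points <- function(mask) {
  m <- mask != 0
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  inner <- pad[2:(H + 1L), 2:(W + 1L)]
  up <- pad[1:H, 2:(W + 1L)]
  dn <- pad[3:(H + 2L), 2:(W + 1L)]
  lf <- pad[2:(H + 1L), 1:W]
  rt <- pad[2:(H + 1L), 3:(W + 2L)]
  b <- inner & !(up & dn & lf & rt)
  which(b, arr.ind = TRUE)
}

#' 95th-percentile Hausdorff distance
#'
#' Extracts the boundary point sets of both masks, computes the directed
#' nearest-neighbour surface distances in both directions, pools them, and
#' returns the linearly interpolated 95th percentile, scaled by the pixel
#' spacing. If either mask is empty the image diagonal is returned as a
#' worst-case sentinel, flagged via the `"empty_mask"` attribute (never a
#' silent zero).
#'
#' @param pred_mask,gt_mask Integer/logical matrices of equal shape.
#' @param spacing Physical size of one pixel, `c(row, col)`.
#' @param probs Percentile in `[0, 1]` (default 0.95; 1 gives the full
#'   Hausdorff distance).
#' @return Distance (same units as `spacing`).
#' @export
hd95 <- function(pred_mask, gt_mask, spacing = c(1, 1), probs = 0.95) {
  if (!identical(dim(pred_mask), dim(gt_mask))) {
    stop("hd95(): mask shapes differ")
  }
  bp <- boundary_points(pred_mask)
  bg <- boundary_points(gt_mask)
  if (nrow(bp) == 0L || nrow(bg) == 0L) {
    diag_len <- sqrt(sum((dim(pred_mask) * spacing)^2))
    out <- diag_len
    attr(out, "empty_mask") <- TRUE
    return(out)
  }
  ps <- sweep(bp, 2, spacing, "*")
  gs <- sweep(bg, 2, spacing, "*")
  d2 <- outer(ps[, 1], gs[, 1], "-")^2 + outer(ps[, 2], gs[, 2], "-")^2
  d_pg <- sqrt(apply(d2, 1, min))   # pred boundary -> gt surface
  d_gp <- sqrt(apply(d2, 2, min))   # gt boundary -> pred surface
  as.numeric(stats::quantile(c(d_pg, d_gp), probs = probs, type = 7))
}

#' Confusion-matrix rates for a binary mask pair
#'
#' From TP/FP/TN/FN: mean IoU over the two classes, accuracy, sensitivity
#' (recall) and specificity. Ratios with zero denominators are reported as
#' `NA`, never as 0.
#'
#' @param pred_mask,gt_mask Binary (0/1 or logical) matrices of equal shape.
#' @return Named vector `c(miou, acc, sen, spe)` in `[0, 1]`.
#' @export
confusion_metrics <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask))) {
    stop("confusion_metrics(): mask shapes differ")
  }
  p <- pred_mask != 0
  g <- gt_mask != 0
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  iou_fg <- ratio(tp, tp + fp + fn)
  iou_bg <- ratio(tn, tn + fp + fn)
  c(miou = mean(c(iou_fg, iou_bg)),
    acc = ratio(tp + tn, tp + tn + fp + fn),
    sen = ratio(tp, tp + fn),
    spe = ratio(tn, tn + fp))
}

#' Paired t-test with confidence intervals for model comparison
#'
#' Two-sided paired t-test on per-case score differences (`a - b`), plus the
#' 95% confidence interval of each model's mean score
#' (`mean +- t_{0.975, n-1} * se`). Zero-variance, all-zero differences give
#' `t = 0`, `p = 1`.
#'
#' @param scores_a,scores_b Per-case scores of the two models, paired by
#'   case; equal lengths, `n >= 2`.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `sf_ttest`: list with `t`, `p`, `significant`,
#'   `ci_a`, `ci_b`, `mean_a`, `mean_b`, `n`, `alpha`.
#' @export
paired_t_test <- function(scores_a, scores_b, alpha = 0.05) {
  n <- length(scores_a)
  if (length(scores_b) != n) stop("paired_t_test(): unequal lengths")
  if (n < 2L) stop("paired_t_test(): need at least 2 paired cases")
  d <- scores_a - scores_b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- list(statistic = sign(mean(d)) * Inf, p.value = 0)
    }
  } else {
    ht <- stats::t.test(scores_a, scores_b, paired = TRUE,
                        conf.level = 1 - alpha)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  ci <- function(x) {
    se <- stats::sd(x) / sqrt(n)
    m <- mean(x)
    q <- stats::qt(1 - alpha / 2, df = n - 1)
    c(lower = m - q * se, upper = m + q * se)
  }
  structure(list(t = tt$statistic, p = tt$p.value,
                 significant = tt$p.value < alpha,
                 ci_a = ci(scores_a), ci_b = ci(scores_b),
                 mean_a = mean(scores_a), mean_b = mean(scores_b),
                 n = n, alpha = alpha),
            class = "sf_ttest")
}

#' @export
print.sf_ttest <- function(x, ...) {
  cat(sprintf("Paired t-test (n = %d): t = %.4f, p = %.4g, significant: %s\n",
              x$n, x$t, x$p, if (x$significant) "yes" else "no"))
  cat(sprintf("  mean A = %.4f, 95%% CI (%.4f, %.4f)\n",
              x$mean_a, x$ci_a[1], x$ci_a[2]))
  cat(sprintf("  mean B = %.4f, 95%% CI (%.4f, %.4f)\n",
              x$mean_b, x$ci_b[1], x$ci_b[2]))
  invisible(x)
}

#' Model-comparison table from per-case score vectors
#'
#' Runs [paired_t_test()] of a reference model against each competitor and
#' assembles a comparison table (method, t, p, significant, CI of the
#' competitor's mean) with the reference model's own CI as the final row.
#'
#' @param reference Per-case scores of the reference model.
#' @param competitors Named list of per-case score vectors.
#' @param reference_name Label of the reference row.
#' @param alpha Significance level.
#' @return A data frame; write with `utils::write.csv` or serialize with
#'   `jsonlite::toJSON` for reporting.
#' @export
ttest_table <- function(reference, competitors, reference_name = "reference",
                        alpha = 0.05) {
  rows <- lapply(names(competitors), function(nm) {
    r <- paired_t_test(reference, competitors[[nm]], alpha = alpha)
    data.frame(method = nm, t = r$t, p = r$p, significant = r$significant,
               ci_lower = r$ci_b[["lower"]], ci_upper = r$ci_b[["upper"]])
  })
  ref_ci <- paired_t_test(reference, competitors[[1]], alpha = alpha)$ci_a
  rows <- c(rows, list(data.frame(
    method = reference_name, t = NA_real_, p = NA_real_, significant = NA,
    ci_lower = ref_ci[["lower"]], ci_upper = ref_ci[["upper"]])))
  do.call(rbind, rows)
}
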