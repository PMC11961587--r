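# Compound objective: 0.3 * cross-entropy + 0.7 * soft Dice per branch,
# deep supervision over four branches with weights 0.7 / 0.1 / 0.1 / 0.1
# (auxiliary logits are bilinearly upsampled to full resolution and scored
# against the full-resolution labels, avoiding label aliasing of thin
# structures).

#' Loss configuration
#'
#' @param ce_weight,dice_weight Weights of the cross-entropy and Dice terms
#'   inside each branch (defaults 0.3 and 0.7).
#' @param branch_weights Deep-supervision weights for the main, 1/8, 1/16 and
#'   1/32 branches; must be non-negative and sum to 1 (defaults
#'   `c(0.7, 0.1, 0.1, 0.1)`).
#' @param dice_eps Dice smoothing constant.
#' @return A loss-config list.
#' @export
loss_config <- function(ce_weight = 0.3, dice_weight = 0.7,
                        branch_weights = c(0.7, 0.1, 0.1, 0.1),
                        dice_eps = 1e-5) {
  stopifnot(ce_weight >= 0, dice_weight >= 0, all(branch_weights >= 0))
  if (abs(sum(branch_weights) - 1) > 1e-9) {
    stop("loss_config(): branch weights must sum to 1")
  }
  list(ce_weight = ce_weight, dice_weight = dice_weight,
       branch_weights = branch_weights, dice_eps = dice_eps)
}

as_probs4 <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) array(x, c(d, 1L)) else x
}

#' Soft Dice loss
#'
#' `1 - (2*I + eps) / (|p| + |y| + eps)` with `I = sum(p * y)`, computed per
#' class and sample and averaged. Crisp (0/1) predictions recover the set
#' formula `1 - 2|P & G| / (|P| + |G|)` as `eps -> 0`.
#'
#' @param pred_probs Class probabilities `[H, W, K]` or `[H, W, K, B]`,
#'   summing to 1 over classes.
#' @param target_onehot One-hot target of the same shape.
#' @param eps Smoothing constant.
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred_probs, target_onehot, eps = 1e-5) {
  p <- as_probs4(pred_probs)
  y <- as_probs4(target_onehot)
  if (!identical(dim(p), dim(y))) {
    stop("dice_loss(): prediction and target shapes differ")
  }
  d <- dim(p)
  K <- d[3]; B <- d[4]
  total <- 0
  for (b in seq_len(B)) for (k in seq_len(K)) {
    pk <- p[, , k, b]; yk <- y[, , k, b]
    I <- sum(pk * yk)
    total <- total + 1 - (2 * I + eps) / (sum(pk) + sum(yk) + eps)
  }
  total / (K * B)
}

as_labels3 <- function(target) {
  d <- dim(target)
  if (is.null(d)) stop("target must be an integer label array")
  if (length(d) == 2L) array(as.integer(target), c(d, 1L))
  else array(as.integer(target), d)
}

onehot_labels <- function(target, K) {
  t3 <- as_labels3(target)
  d <- dim(t3)
  y <- array(0, c(d[1], d[2], K, d[3]))
  for (b in seq_len(d[3])) for (k in seq_len(K)) {
    y[, , k, b] <- as.numeric(t3[, , b] == (k - 1L))
  }
  y
}

#' Combined cross-entropy + Dice loss of one logits branch
#'
#' `ce_weight * CE + dice_weight * Dice` on softmaxed logits.
#'
#' @param logits Raw scores `[H, W, K]` or `[H, W, K, B]`.
#' @param target Integer labels in `0..K-1`, `[H, W]` or `[H, W, B]`.
#' @param cfg A [loss_config()].
#' @return Scalar loss, with attributes `ce` and `dice` holding the parts.
#' @export
combined_loss <- function(logits, target, cfg = loss_config()) {
  lt <- new_tensor(as_probs4(logits))
  t3 <- as_labels3(target)
  ce <- as.numeric(tval(op_ce_from_logits(lt, t3)))
  dl <- as.numeric(tval(op_dice_from_logits(lt, t3, cfg$dice_eps)))
  out <- cfg$ce_weight * ce + cfg$dice_weight * dl
  attr(out, "ce") <- ce
  attr(out, "dice") <- dl
  out
}

combined_loss_t <- function(logits, target3, cfg) {
  ce <- op_ce_from_logits(logits, target3)
  dl <- op_dice_from_logits(logits, target3, cfg$dice_eps)
  op_wsum(list(ce, dl), c(cfg$ce_weight, cfg$dice_weight))
}

total_loss_t <- function(bundle, target3, cfg) {
  d <- dim(tval(bundle$main))
  branches <- list(bundle$main)
  if (!is.null(bundle$aux8)) {
    branches <- c(branches, lapply(list(bundle$aux8, bundle$aux16,
                                        bundle$aux32),
                                   function(a) op_bilinear(a, d[1], d[2])))
  } else if (any(cfg$branch_weights[-1] > 0)) {
    stop("total_loss(): auxiliary branches missing but their weights are > 0")
  }
  parts <- lapply(branches, function(br) combined_loss_t(br, target3, cfg))
  w <- cfg$branch_weights[seq_along(parts)]
  total <- op_wsum(parts, w)
  attr(total, "branches") <- vapply(parts, function(p) as.numeric(tval(p)),
                                    numeric(1))
  total
}

#' Deep-supervision total loss
#'
#' Upsamples each auxiliary logits map bilinearly to the main resolution,
#' scores every branch with [combined_loss()] against the full-resolution
#' labels, and returns the branch-weighted sum.
#'
#' @param bundle Logits bundle (list with `main` and optionally `aux8`,
#'   `aux16`, `aux32`) as produced by [decoder_forward()].
#' @param target_mask Integer labels `[H, W]` or `[H, W, B]`.
#' @param cfg A [loss_config()].
#' @return Scalar loss with attribute `branches` (per-branch values, main
#'   first).
#' @export
total_loss <- function(bundle, target_mask, cfg = loss_config()) {
  bt <- lapply(bundle, function(x) {
    if (is_tensor(x)) x else new_tensor(as_probs4(x))
  })
  t3 <- as_labels3(target_mask)
  res <- total_loss_t(bt, t3, cfg)
  out <- as.numeric(tval(res))
  attr(out, "branches") <- attr(res, "branches")
  out
}
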