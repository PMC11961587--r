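# Training / evaluation / prediction pipeline.

#' Training run configuration
#'
#' Defaults: batch size 12 with either Adam (learning rate 1e-4, weight
#' decay 1e-4) or SGD (base learning rate 0.05, momentum 0.9, weight decay
#' 1e-4) — the two standard recipes for this architecture family. Epoch count and schedule are
#' open; the default is a constant learning rate with optional early
#' stopping on validation Dice.
#'
#' @param optimizer `"adam"` or `"sgd"`.
#' @param lr Learning rate; defaults to 1e-4 (Adam) / 0.05 (SGD).
#' @param weight_decay L2 weight decay (default 1e-4).
#' @param momentum SGD momentum (default 0.9).
#' @param batch_size Mini-batch size (default 12).
#' @param epochs Maximum epochs.
#' @param seed RNG seed controlling shuffling (and any weight init done at
#'   training time).
#' @param early_stop_dsc Stop once validation mean foreground Dice (percent)
#'   reaches this value; `NULL` disables.
#' @param verbose Print per-epoch progress?
#' @return A `run_config` list.
#' @export
run_config <- function(optimizer = c("adam", "sgd"), lr = NULL,
                       weight_decay = 1e-4, momentum = 0.9,
                       batch_size = 12L, epochs = 10L, seed = 1L,
                       early_stop_dsc = NULL, verbose = TRUE) {
  optimizer <- match.arg(optimizer)
  if (is.null(lr)) lr <- if (optimizer == "adam") 1e-4 else 0.05
  list(optimizer = optimizer, lr = lr, weight_decay = weight_decay,
       momentum = momentum, batch_size = as.integer(batch_size),
       epochs = as.integer(epochs), seed = as.integer(seed),
       early_stop_dsc = early_stop_dsc, verbose = isTRUE(verbose))
}

dataset_splits <- function(dataset) {
  split <- attr(dataset, "split")
  n <- length(dataset)
  if (is.null(split)) {
    n_train <- floor(0.7 * n)
    n_val <- floor(0.1 * n)
    split <- rep("test", n)
    split[seq_len(n_train)] <- "train"
    if (n_val > 0) split[n_train + seq_len(n_val)] <- "val"
  }
  list(train = which(split == "train"), val = which(split == "val"),
       test = which(split == "test"))
}

batch_arrays <- function(dataset, idx) {
  s1 <- dataset[[idx[1]]]
  d <- dim(s1$image)
  B <- length(idx)
  x <- array(0, c(d[1], d[2], d[3], B))
  y <- array(0L, c(d[1], d[2], B))
  for (j in seq_along(idx)) {
    x[, , , j] <- dataset[[idx[j]]]$image
    y[, , j] <- dataset[[idx[j]]]$mask
  }
  list(x = x, y = y)
}

mean_fg_dsc <- function(pred, gt, K) {
  mean(dsc(pred, gt, classes = seq_len(K - 1L)))
}

eval_mean_dsc <- function(model, dataset, idx) {
  K <- model$config$num_classes
  scores <- vapply(idx, function(i) {
    ba <- batch_arrays(dataset, i)
    bundle <- model_forward_t(model, new_tensor(ba$x), train = FALSE)
    pred <- logits_to_mask(tval(bundle$main))
    mean_fg_dsc(pred[, , 1], ba$y[, , 1], K)
  }, numeric(1))
  mean(scores)
}

#' Train a segmentation model
#'
#' Optimizes the deep-supervision compound loss ([total_loss()]) with the
#' configured optimizer. Logs per-epoch branch losses and validation mean
#' foreground Dice; aborts with a diagnostic on non-finite loss.
#'
#' @param model An [scaleformer()] model (modified in place and returned).
#' @param dataset An `sf_dataset`; its split attribute selects train/val.
#' @param cfg A [run_config()].
#' @param loss_cfg A [loss_config()].
#' @return The trained model, with a `log` data frame (epoch, mean training
#'   loss, per-branch means, validation Dice) and the configs attached as
#'   attributes.
#' @export
train_scaleformer <- function(model, dataset, cfg = run_config(),
                              loss_cfg = loss_config()) {
  splits <- dataset_splits(dataset)
  if (!length(splits$train)) stop("train_scaleformer(): empty training split")
  set.seed(cfg$seed)
  params <- sf_parameters(model)
  opt <- if (cfg$optimizer == "adam") {
    opt_adam(params, lr = cfg$lr, weight_decay = cfg$weight_decay)
  } else {
    opt_sgd(params, lr = cfg$lr, momentum = cfg$momentum,
            weight_decay = cfg$weight_decay)
  }
  log_rows <- list()
  for (epoch in seq_len(cfg$epochs)) {
    order <- sample(splits$train)
    batches <- split(order, ceiling(seq_along(order) / cfg$batch_size))
    ep_loss <- 0
    ep_branches <- NULL
    for (bi in seq_along(batches)) {
      ba <- batch_arrays(dataset, batches[[bi]])
      bundle <- model_forward_t(model, new_tensor(ba$x), train = TRUE)
      loss <- total_loss_t(bundle, ba$y, loss_cfg)
      lv <- as.numeric(tval(loss))
      if (!is.finite(lv)) {
        stop(sprintf(
          "train_scaleformer(): non-finite loss %g at epoch %d batch %d (diverged; lower the learning rate)",
          lv, epoch, bi))
      }
      zero_grads(params)
      sf_backward(loss)
      opt_step(opt)
      ep_loss <- ep_loss + lv * length(batches[[bi]])
      br <- attr(loss, "branches")
      ep_branches <- if (is.null(ep_branches)) br * length(batches[[bi]])
                     else ep_branches + br * length(batches[[bi]])
    }
    n_tr <- length(splits$train)
    ep_loss <- ep_loss / n_tr
    ep_branches <- ep_branches / n_tr
    val_dsc <- if (length(splits$val)) {
      eval_mean_dsc(model, dataset, splits$val)
    } else NA_real_
    if (cfg$verbose) {
      message(sprintf(
        "epoch %d/%d  loss %.4f  branches [%s]  val DSC %s",
        epoch, cfg$epochs, ep_loss,
        paste(sprintf("%.3f", ep_branches), collapse = ", "),
        if (is.na(val_dsc)) "-" else sprintf("%.2f%%", val_dsc)))
    }
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, loss = ep_loss,
      loss_main = ep_branches[1],
      loss_aux8 = if (length(ep_branches) > 1) ep_branches[2] else NA_real_,
      loss_aux16 = if (length(ep_branches) > 2) ep_branches[3] else NA_real_,
      loss_aux32 = if (length(ep_branches) > 3) ep_branches[4] else NA_real_,
      val_dsc = val_dsc)
    if (!is.null(cfg$early_stop_dsc) && !is.na(val_dsc) &&
        val_dsc >= cfg$early_stop_dsc) break
  }
  attr(model, "log") <- do.call(rbind, log_rows)
  attr(model, "run_config") <- cfg
  attr(model, "loss_config") <- loss_cfg
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the model configuration, every parameter value,
#' the normalization running statistics, the training log and the seed, so
#' `load_checkpoint()` reproduces the model (and its metrics) exactly.
#'
#' @param model A trained `sf_model`.
#' @param path Destination `.rds` file.
#' @return `save_checkpoint`: invisibly, `path`. `load_checkpoint`: the
#'   restored `sf_model`.
#' @export
save_checkpoint <- function(model, path) {
  ck <- list(config = model$config,
             params = params_state(model),
             bn = bn_states(model),
             log = attr(model, "log"),
             run_config = attr(model, "run_config"))
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- do.call(scaleformer, ck$config[!vapply(ck$config, is.null,
                                                  logical(1))])
  load_params_state(model, ck$params)
  load_bn_states(model, ck$bn)
  attr(model, "log") <- ck$log
  attr(model, "run_config") <- ck$run_config
  model
}

#' Evaluate a model on a dataset split
#'
#' Computes per-case metrics: per-class and mean foreground Dice (percent),
#' mean foreground HD95 (pixels; empty predictions fall back to the image
#' diagonal and are flagged), and binary foreground confusion rates. When a
#' second model is supplied, a paired t-test on per-case mean Dice is
#' attached.
#'
#' @param model A trained `sf_model` (or a checkpoint path).
#' @param dataset An `sf_dataset`.
#' @param split Which split to score (default `"test"`; `"all"` scores
#'   every case).
#' @param compare Optional second model/checkpoint for the paired test.
#' @return Data frame of per-case metrics; aggregate means/sds as the
#'   `"aggregate"` attribute, the test report (if any) as `"ttest"`.
#' @export
evaluate_model <- function(model, dataset, split = "test", compare = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (is.character(compare)) compare <- load_checkpoint(compare)
  K <- model$config$num_classes
  idx <- if (identical(split, "all")) seq_along(dataset)
         else dataset_splits(dataset)[[split]]
  if (!length(idx)) stop(sprintf("evaluate_model(): empty split '%s'", split))
  score_case <- function(mod, i) {
    ba <- batch_arrays(dataset, i)
    bundle <- model_forward_t(mod, new_tensor(ba$x), train = FALSE)
    pred <- logits_to_mask(tval(bundle$main))[, , 1]
    gt <- ba$y[, , 1]
    per_class <- dsc(pred, gt, classes = seq_len(K - 1L))
    hd <- vapply(seq_len(K - 1L), function(k) {
      as.numeric(hd95(pred == k, gt == k))
    }, numeric(1))
    cm <- confusion_metrics(pred != 0, gt != 0)
    c(dsc_mean = mean(per_class), per_class,
      hd95_mean = mean(hd), cm)
  }
  rows <- t(vapply(idx, function(i) score_case(model, i),
                   score_case(model, idx[1])))
  df <- data.frame(case = idx, rows, row.names = NULL, check.names = FALSE)
  agg <- data.frame(metric = colnames(rows),
                    mean = colMeans(rows, na.rm = TRUE),
                    sd = apply(rows, 2, stats::sd, na.rm = TRUE),
                    row.names = NULL)
  attr(df, "aggregate") <- agg
  if (!is.null(compare)) {
    rows_b <- t(vapply(idx, function(i) score_case(compare, i),
                       rows[1, ]))
    attr(df, "ttest") <- paired_t_test(rows[, "dsc_mean"],
                                       rows_b[, "dsc_mean"])
    attr(df, "compare_scores") <- rows_b[, "dsc_mean"]
  }
  df
}

#' Predict label masks for images
#'
#' Argmax of the main logits, case by case (deterministic). Inputs whose
#' sizes are not divisible by 32 are rejected unless `auto_resize = TRUE`,
#' in which case they are bilinearly resized for inference and the predicted
#' mask is nearest-neighbour resized back.
#'
#' @param model A trained `sf_model` (or checkpoint path).
#' @param images A list of `[H, W]` / `[H, W, C]` arrays, a single such
#'   array, or an `sf_dataset`.
#' @param auto_resize Resize inputs to the nearest multiple of 32?
#' @return List of integer label masks.
#' @export
predict_masks <- function(model, images, auto_resize = FALSE) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (inherits(images, "sf_dataset")) {
    images <- lapply(images, function(s) s$image)
  } else if (!is.list(images)) {
    images <- list(images)
  }
  # lists of dataset samples are accepted too
  images <- lapply(images, function(el) {
    if (is.list(el) && !is.null(el$image)) el$image else el
  })
  lapply(images, function(img) {
    xt <- as_fmap(img)
    d <- dim(xt)
    H <- d[1]; W <- d[2]
    if (H %% 32L != 0L || W %% 32L != 0L) {
      if (!auto_resize) {
        stop(sprintf(
          "predict_masks(): %dx%d input not divisible by 32 (set auto_resize = TRUE)",
          H, W))
      }
      Hr <- max(32L, round(H / 32) * 32L)
      Wr <- max(32L, round(W / 32) * 32L)
      xt <- tval(op_bilinear(new_tensor(xt), Hr, Wr))
    }
    bundle <- model_forward_t(model, new_tensor(xt), train = FALSE)
    mask <- logits_to_mask(tval(bundle$main))[, , 1]
    if (!identical(dim(mask), c(H, W))) {
      ih <- pmin(pmax(round((seq_len(H) - 0.5) * nrow(mask) / H + 0.5), 1),
                 nrow(mask))
      iw <- pmin(pmax(round((seq_len(W) - 0.5) * ncol(mask) / W + 0.5), 1),
                 ncol(mask))
      mask <- mask[ih, iw]
    }
    mask
  })
}

#' Write predicted masks as PNG files
#'
#' @param masks List of integer masks (from [predict_masks()]).
#' @param dir Output directory.
#' @param names Optional file names.
#' @return Invisibly, the written paths.
#' @export
write_masks <- function(masks, dir, names = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(names)) names <- sprintf("pred_%04d.png", seq_along(masks))
  paths <- file.path(dir, names)
  for (i in seq_along(masks)) png::writePNG(masks[[i]] / 255, paths[i])
  invisible(paths)
}
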