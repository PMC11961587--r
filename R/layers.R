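# Parameterized layers built on the autodiff core.  A "module" is a plain
# list of parameter tensors (and nested modules) plus static configuration;
# sf_parameters() walks the structure to collect every parameter tensor.

init_norm <- function(dm, sd) new_param(array(stats::rnorm(prod(dm), 0, sd), dm))
init_zero <- function(dm) new_param(array(0, dm))
init_one <- function(dm) new_param(array(1, dm))

layer_conv <- function(cin, cout, k = 3L, bias = TRUE) {
  sd <- sqrt(2 / (k * k * cin))
  list(w = init_norm(c(k, k, cin, cout), sd), b = init_zero(cout),
       k = as.integer(k))
}

fwd_conv <- function(m, x, stride = 1L, pad = (m$k - 1L) %/% 2L) {
  op_conv2d(x, m$w, m$b, stride = stride, pad = pad)
}

layer_dwconv <- function(ch, k = 3L) {
  sd <- sqrt(2 / (k * k))
  list(w = init_norm(c(k, k, ch), sd), b = init_zero(ch), k = as.integer(k))
}

fwd_dwconv <- function(m, x, stride = 1L, pad = (m$k - 1L) %/% 2L,
                       pad_mode = "zero") {
  if (pad_mode != "zero" && pad > 0L) {
    x <- op_pad_hw(x, pad, pad, pad, pad, mode = pad_mode)
    pad <- 0L
  }
  op_dwconv2d(x, m$w, m$b, stride = stride, pad = pad)
}

layer_bn <- function(ch) {
  st <- new.env(parent = emptyenv())
  st$rm <- rep(0, ch)
  st$rv <- rep(1, ch)
  list(gamma = init_one(ch), beta = init_zero(ch), state = st)
}

fwd_bn <- function(m, x, train = TRUE) {
  op_batchnorm(x, m$gamma, m$beta, m$state, training = train)
}

layer_ln <- function(ch) list(gamma = init_one(ch), beta = init_zero(ch))

fwd_ln <- function(m, x) op_channel_layernorm(x, m$gamma, m$beta)

layer_dense <- function(fin, fout) {
  list(W = init_norm(c(fout, fin), sqrt(2 / fin)), b = init_zero(fout))
}

fwd_dense <- function(m, x) op_dense(x, m$W, m$b)

# Squeeze-Excitation: global pool -> bottleneck -> sigmoid channel gate.
layer_se <- function(ch, reduction = 4L) {
  hidden <- max(1L, ch %/% reduction)
  list(fc1 = layer_dense(ch, hidden), fc2 = layer_dense(hidden, ch), ch = ch)
}

fwd_se <- function(m, x) {
  d <- dim(tval(x))
  s <- op_global_mean_hw(x)                       # [1,1,C,B]
  s <- op_reshape(s, c(m$ch, d[4]))               # [C,B]
  s <- op_gelu(fwd_dense(m$fc1, s))
  s <- op_sigmoid(fwd_dense(m$fc2, s))
  s <- op_reshape(s, c(1, 1, m$ch, d[4]))
  op_mul(x, s)
}

# 1x1 convolution expressed through the conv kernel (weights [1,1,cin,cout]).
layer_proj <- function(cin, cout) {
  list(w = init_norm(c(1, 1, cin, cout), sqrt(1 / cin)), b = init_zero(cout),
       k = 1L)
}

fwd_proj <- function(m, x) op_conv2d(x, m$w, m$b, stride = 1L, pad = 0L)

# ---- parameter plumbing -------------------------------------------------

sf_parameters <- function(m, prefix = "") {
  out <- list()
  if (is_tensor(m)) {
    if (isTRUE(m$is_param)) out[[prefix]] <- m
    return(out)
  }
  if (is.list(m)) {
    nms <- names(m)
    for (i in seq_along(m)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      out <- c(out, sf_parameters(m[[i]],
                                  if (nzchar(prefix)) paste0(prefix, ".", nm)
                                  else nm))
    }
  }
  out
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Set every parameter tensor in a module to zero (residual-collapse tests).
zero_params <- function(m) {
  for (p in sf_parameters(m)) p$v[] <- 0
  invisible(m)
}

# Snapshot / restore parameter values (checkpointing).
params_state <- function(m) lapply(sf_parameters(m), function(p) p$v)

load_params_state <- function(m, st) {
  ps <- sf_parameters(m)
  stopifnot(identical(names(ps), names(st)))
  for (nm in names(ps)) ps[[nm]]$v <- st[[nm]]
  invisible(m)
}

# BatchNorm running-statistic snapshot (environments need explicit copying).
bn_states <- function(m, prefix = "") {
  out <- list()
  if (is.list(m) && !is_tensor(m)) {
    if (!is.null(m$state) && is.environment(m$state)) {
      out[[paste0(prefix, ".state")]] <- list(rm = m$state$rm, rv = m$state$rv)
    }
    nms <- names(m)
    for (i in seq_along(m)) {
      if (is.list(m[[i]]) && !is_tensor(m[[i]])) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        out <- c(out, bn_states(m[[i]], paste0(prefix, ".", nm)))
      }
    }
  }
  out
}

load_bn_states <- function(m, st, prefix = "") {
  if (is.list(m) && !is_tensor(m)) {
    key <- paste0(prefix, ".state")
    if (!is.null(m$state) && is.environment(m$state) && !is.null(st[[key]])) {
      m$state$rm <- st[[key]]$rm
      m$state$rv <- st[[key]]$rv
    }
    nms <- names(m)
    for (i in seq_along(m)) {
      if (is.list(m[[i]]) && !is_tensor(m[[i]])) {
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        load_bn_states(m[[i]], st, paste0(prefix, ".", nm))
      }
    }
  }
  invisible(m)
}

# ---- optimizers ---------------------------------------------------------

opt_adam <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 1e-4) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(params, function(p) array(0, dim = dim(p$v)))
  st$v <- lapply(params, function(p) array(0, dim = dim(p$v)))
  list(kind = "adam", params = params, lr = lr, beta1 = beta1, beta2 = beta2,
       eps = eps, wd = weight_decay, st = st)
}

opt_sgd <- function(params, lr = 0.05, momentum = 0.9, weight_decay = 1e-4) {
  st <- new.env(parent = emptyenv())
  st$u <- lapply(params, function(p) array(0, dim = dim(p$v)))
  list(kind = "sgd", params = params, lr = lr, momentum = momentum,
       wd = weight_decay, st = st)
}

opt_step <- function(opt) {
  if (opt$kind == "adam") {
    opt$st$t <- opt$st$t + 1L
    t <- opt$st$t
    for (i in seq_along(opt$params)) {
      p <- opt$params[[i]]
      g <- p$grad
      if (is.null(g)) next
      if (opt$wd > 0) g <- g + opt$wd * p$v
      opt$st$m[[i]] <- opt$beta1 * opt$st$m[[i]] + (1 - opt$beta1) * g
      opt$st$v[[i]] <- opt$beta2 * opt$st$v[[i]] + (1 - opt$beta2) * g^2
      mhat <- opt$st$m[[i]] / (1 - opt$beta1^t)
      vhat <- opt$st$v[[i]] / (1 - opt$beta2^t)
      p$v <- p$v - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    }
  } else {
    for (i in seq_along(opt$params)) {
      p <- opt$params[[i]]
      g <- p$grad
      if (is.null(g)) next
      if (opt$wd > 0) g <- g + opt$wd * p$v
      opt$st$u[[i]] <- opt$momentum * opt$st$u[[i]] + g
      p$v <- p$v - opt$lr * opt$st$u[[i]]
    }
  }
  invisible(opt)
}
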