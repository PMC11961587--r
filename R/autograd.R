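# Reverse-mode automatic differentiation on dense arrays.
#
# A tensor is an environment holding a value (`v`), an accumulated gradient
# (`grad`), its parents in the computation graph and a `backfn` that maps the
# upstream gradient to one gradient per parent.  Feature maps are stored
# [H, W, C, B]; token matrices [N, d, B]; scalars as length-1 arrays.

.sf <- new.env(parent = emptyenv())
.sf$id <- 0L
.sf$attn_macs <- 0
.sf$isa_macs <- 0

sf_next_id <- function() {
  .sf$id <- .sf$id + 1L
  .sf$id
}

#' Reset the attention multiply-accumulate counters
#'
#' The package instruments its attention kernels with multiply-accumulate
#' (MAC) counters so that the advertised complexity laws (token-grid attention
#' cost growing as s^4, channel-affinity cost linear in the token count) can
#' be measured rather than assumed. This zeroes both counters.
#' @return Invisibly, the previous counter values.
#' @seealso [sf_counters()], [gmsa_cost()]
#' @export
sf_reset_counters <- function() {
  old <- sf_counters()
  .sf$attn_macs <- 0
  .sf$isa_macs <- 0
  invisible(old)
}

#' Read the attention multiply-accumulate counters
#'
#' @return A list with `attn_macs` (token-grid scaled-dot-product attention)
#'   and `isa_macs` (inter-scale channel-affinity products).
#' @export
sf_counters <- function() {
  list(attn_macs = .sf$attn_macs, isa_macs = .sf$isa_macs)
}

new_tensor <- function(v, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  e$id <- sf_next_id()
  class(e) <- "sf_tensor"
  e
}

is_tensor <- function(x) inherits(x, "sf_tensor")

as_tensor <- function(x) {
  if (is_tensor(x)) return(x)
  if (is.null(dim(x))) x <- array(as.numeric(x), dim = length(x))
  new_tensor(x)
}

tval <- function(x) if (is_tensor(x)) x$v else x

new_param <- function(v) {
  p <- new_tensor(v)
  p$is_param <- TRUE
  p
}

#' @export
print.sf_tensor <- function(x, ...) {
  d <- dim(x$v)
  cat("<sf_tensor", if (is.null(d)) length(x$v) else paste(d, collapse = "x"),
      if (isTRUE(x$is_param)) "param" else "", ">\n")
  invisible(x)
}

# Topological order by iterative DFS, then one reverse sweep.
sf_backward <- function(out, seed = NULL) {
  if (is.null(seed)) seed <- array(1, dim = dim(out$v))
  order <- vector("list", 256L)
  n <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = out, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents)
        if (is.null(seen[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
    } else {
      n <- n + 1L
      if (n > length(order)) order <- c(order, vector("list", length(order)))
      order[[n]] <- node
    }
  }
  out$grad <- seed
  for (i in seq_len(n)) {
    node <- order[[n - i + 1L]]
    if (is.null(node$backfn) || is.null(node$grad)) next
    gs <- node$backfn(node$grad)
    for (j in seq_along(node$parents)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- node$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(out)
}

# ---- broadcasting helpers ----------------------------------------------

# Expand `v` (whose dim has 1s) to `target` dims by index replication.
bc_expand <- function(v, target) {
  d <- dim(v)
  if (identical(d, target)) return(v)
  idx <- lapply(seq_along(target), function(k) {
    if (d[k] == target[k]) seq_len(target[k]) else rep(1L, target[k])
  })
  do.call(`[`, c(list(v), idx, list(drop = FALSE)))
}

# Sum `g` (dims = target) back down to `source` dims.
bc_reduce <- function(g, source) {
  d <- dim(g)
  if (identical(d, source)) return(g)
  keep <- which(source == d)
  res <- apply(g, keep, sum)
  array(res, dim = source)
}

slice_arr <- function(v, dm, idx) {
  nd <- length(dim(v))
  args <- rep(list(quote(expr = )), nd)
  args[[dm]] <- idx
  do.call(`[`, c(list(v), args, list(drop = FALSE)))
}

# ---- elementwise ops ----------------------------------------------------

op_add <- function(a, b) {
  a <- as_tensor(a); b <- as_tensor(b)
  da <- dim(a$v); db <- dim(b$v)
  if (identical(da, db)) {
    new_tensor(a$v + b$v, list(a, b), function(g) list(g, g))
  } else if (length(da) == length(db)) {
    target <- pmax(da, db)
    new_tensor(bc_expand(a$v, target) + bc_expand(b$v, target), list(a, b),
               function(g) list(bc_reduce(g, da), bc_reduce(g, db)))
  } else stop("op_add: rank mismatch")
}

op_mul <- function(a, b) {
  a <- as_tensor(a); b <- as_tensor(b)
  da <- dim(a$v); db <- dim(b$v)
  if (length(da) != length(db)) stop("op_mul: rank mismatch")
  target <- pmax(da, db)
  av <- bc_expand(a$v, target); bv <- bc_expand(b$v, target)
  new_tensor(av * bv, list(a, b),
             function(g) list(bc_reduce(g * bv, da), bc_reduce(g * av, db)))
}

op_smul <- function(a, k) {
  a <- as_tensor(a)
  new_tensor(a$v * k, list(a), function(g) list(g * k))
}

op_sub <- function(a, b) op_add(a, op_smul(b, -1))

op_mean <- function(a) {
  a <- as_tensor(a)
  n <- length(a$v)
  new_tensor(array(mean(a$v), 1L), list(a),
             function(g) list(array(as.numeric(g) / n, dim = dim(a$v))))
}

op_sum <- function(a) {
  a <- as_tensor(a)
  new_tensor(array(sum(a$v), 1L), list(a),
             function(g) list(array(as.numeric(g), dim = dim(a$v))))
}

# Weighted sum of scalar tensors.
op_wsum <- function(xs, w) {
  xs <- lapply(xs, as_tensor)
  v <- 0
  for (i in seq_along(xs)) v <- v + w[i] * as.numeric(xs[[i]]$v)
  new_tensor(array(v, 1L), xs,
             function(g) lapply(seq_along(xs),
                                function(i) array(as.numeric(g) * w[i], 1L)))
}

op_sigmoid <- function(a) {
  a <- as_tensor(a)
  s <- 1 / (1 + exp(-a$v))
  new_tensor(s, list(a), function(g) list(g * s * (1 - s)))
}

op_relu <- function(a) {
  a <- as_tensor(a)
  m <- a$v > 0
  new_tensor(a$v * m, list(a), function(g) list(g * m))
}

# Smooth GELU (tanh approximation).
op_gelu <- function(a) {
  a <- as_tensor(a)
  x <- a$v
  c0 <- sqrt(2 / pi)
  u <- c0 * (x + 0.044715 * x^3)
  t <- tanh(u)
  new_tensor(0.5 * x * (1 + t), list(a), function(g) {
    du <- c0 * (1 + 3 * 0.044715 * x^2)
    list(g * (0.5 * (1 + t) + 0.5 * x * (1 - t^2) * du))
  })
}

# ---- shape ops ----------------------------------------------------------

op_reshape <- function(a, dm) {
  a <- as_tensor(a)
  d0 <- dim(a$v)
  new_tensor(array(a$v, dim = dm), list(a),
             function(g) list(array(g, dim = d0)))
}

op_aperm <- function(a, perm) {
  a <- as_tensor(a)
  inv <- order(perm)
  new_tensor(aperm(a$v, perm), list(a), function(g) list(aperm(g, inv)))
}

op_slice <- function(a, dm, idx) {
  a <- as_tensor(a)
  d0 <- dim(a$v)
  new_tensor(slice_arr(a$v, dm, idx), list(a), function(g) {
    gx <- array(0, dim = d0)
    nd <- length(d0)
    args <- rep(list(quote(expr = )), nd)
    args[[dm]] <- idx
    list(do.call(`[<-`, c(list(gx), args, list(value = g))))
  })
}

op_concat <- function(xs, dm) {
  xs <- lapply(xs, as_tensor)
  dims <- lapply(xs, function(x) dim(x$v))
  sizes <- vapply(dims, function(d) d[dm], numeric(1))
  dout <- dims[[1]]
  dout[dm] <- sum(sizes)
  v <- array(0, dim = dout)
  off <- 0L
  nd <- length(dout)
  for (i in seq_along(xs)) {
    args <- rep(list(quote(expr = )), nd)
    args[[dm]] <- off + seq_len(sizes[i])
    v <- do.call(`[<-`, c(list(v), args, list(value = xs[[i]]$v)))
    off <- off + sizes[i]
  }
  new_tensor(v, xs, function(g) {
    out <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- slice_arr(g, dm, off + seq_len(sizes[i]))
      off <- off + sizes[i]
    }
    out
  })
}

# Pad H/W of a [H,W,C,B] map. mode: "zero", "replicate" (edge), "circular".
op_pad_hw <- function(a, pt, pb, pl, pr, mode = "zero") {
  a <- as_tensor(a)
  d <- dim(a$v)
  H <- d[1]; W <- d[2]
  Ho <- H + pt + pb; Wo <- W + pl + pr
  ih <- seq_len(Ho) - pt  # source row for each output row
  iw <- seq_len(Wo) - pl
  if (mode == "replicate") {
    ih <- pmin(pmax(ih, 1L), H); iw <- pmin(pmax(iw, 1L), W)
  } else if (mode == "circular") {
    ih <- ((ih - 1L) %% H) + 1L; iw <- ((iw - 1L) %% W) + 1L
  } else {
    ih[ih < 1L | ih > H] <- NA_integer_
    iw[iw < 1L | iw > W] <- NA_integer_
  }
  v <- array(0, dim = c(Ho, Wo, d[3], d[4]))
  okh <- !is.na(ih); okw <- !is.na(iw)
  v[okh, okw, , ] <- a$v[ih[okh], iw[okw], , , drop = FALSE]
  new_tensor(v, list(a), function(g) {
    gx <- array(0, dim = d)
    hs <- ih[okh]; ws <- iw[okw]
    gsub <- g[okh, okw, , , drop = FALSE]
    # scatter-add (padding modes can map several outputs to one input)
    for (jj in seq_along(ws)) for (ii in seq_along(hs))
      gx[hs[ii], ws[jj], , ] <- gx[hs[ii], ws[jj], , ] + gsub[ii, jj, , ]
    list(gx)
  })
}

op_crop_hw <- function(a, h, w) {
  a <- as_tensor(a)
  d <- dim(a$v)
  if (d[1] == h && d[2] == w) return(a)
  new_tensor(a$v[seq_len(h), seq_len(w), , , drop = FALSE], list(a),
             function(g) {
               gx <- array(0, dim = d)
               gx[seq_len(h), seq_len(w), , ] <- g
               list(gx)
             })
}

# ---- reductions over feature maps ---------------------------------------

# Global average over H, W: [H,W,C,B] -> [1,1,C,B]
op_global_mean_hw <- function(a) {
  a <- as_tensor(a)
  d <- dim(a$v)
  n <- d[1] * d[2]
  xm <- matrix(aperm(a$v, c(1, 2, 3, 4)), nrow = n)  # [HW, C*B]
  v <- array(colMeans(xm), dim = c(1, 1, d[3], d[4]))
  new_tensor(v, list(a), function(g) {
    list(bc_expand(g, d) / n)
  })
}

# Mean over dims 1:2 of a 3D array [A,D,B] -> [1,B] matrix-shaped tensor.
op_mean3_12 <- function(a) {
  a <- as_tensor(a)
  d <- dim(a$v)
  n <- d[1] * d[2]
  v <- array(colMeans(matrix(a$v, nrow = n)), dim = c(1, d[3]))
  new_tensor(v, list(a), function(g) {
    gg <- array(0, dim = d)
    for (b in seq_len(d[3])) gg[, , b] <- g[1, b] / n
    list(gg)
  })
}

# Channel-wise mean and max over C: [H,W,C,B] -> [H,W,1,B] each (for the
# spatial-attention statistics).
op_chan_mean <- function(a) {
  a <- as_tensor(a)
  d <- dim(a$v)
  v <- array(apply(a$v, c(1, 2, 4), mean), dim = c(d[1], d[2], 1, d[4]))
  new_tensor(v, list(a), function(g) list(bc_expand(g, d) / d[3]))
}

op_chan_max <- function(a) {
  a <- as_tensor(a)
  d <- dim(a$v)
  m <- apply(a$v, c(1, 2, 4), max)
  v <- array(m, dim = c(d[1], d[2], 1, d[4]))
  new_tensor(v, list(a), function(g) {
    mask <- a$v == bc_expand(v, d)
    # split gradient among ties
    cnt <- array(apply(mask, c(1, 2, 4), sum), dim = dim(v))
    list(bc_expand(g / cnt, d) * mask)
  })
}

# ---- matrix ops ---------------------------------------------------------

# Dense layer on [Fin, B] matrices: y = W x + b, W [Fout, Fin], b [Fout].
op_dense <- function(x, W, b) {
  x <- as_tensor(x); W <- as_tensor(W); b <- as_tensor(b)
  xv <- x$v; Wv <- W$v
  y <- Wv %*% xv + as.numeric(b$v)
  new_tensor(y, list(x, W, b), function(g) {
    list(t(Wv) %*% g, g %*% t(xv), array(rowSums(g), dim = dim(b$v)))
  })
}

# Batched matmul on 3D stacks: a [N,K,B] x b [K,P,B] -> [N,P,B]
op_bmm <- function(a, b) {
  a <- as_tensor(a); b <- as_tensor(b)
  da <- dim(a$v); db <- dim(b$v)
  stopifnot(da[2] == db[1], da[3] == db[3])
  B <- da[3]
  mk <- function(x, i, nr, nc) matrix(x[, , i], nr, nc)
  v <- array(0, dim = c(da[1], db[2], B))
  for (k in seq_len(B)) {
    v[, , k] <- mk(a$v, k, da[1], da[2]) %*% mk(b$v, k, db[1], db[2])
  }
  new_tensor(v, list(a, b), function(g) {
    ga <- array(0, dim = da); gb <- array(0, dim = db)
    for (k in seq_len(B)) {
      gk <- mk(g, k, da[1], db[2])
      ga[, , k] <- gk %*% t(mk(b$v, k, db[1], db[2]))
      gb[, , k] <- t(mk(a$v, k, da[1], da[2])) %*% gk
    }
    list(ga, gb)
  })
}

# Softmax over one axis of a 3D stack [N,D,B]; axis 1 normalizes each column
# (over tokens), axis 2 each row (over channels).
op_softmax3 <- function(a, axis) {
  a <- as_tensor(a)
  d <- dim(a$v)
  p <- array(0, dim = d)
  for (k in seq_len(d[3])) {
    m <- matrix(a$v[, , k], d[1], d[2])
    if (axis == 2) {
      e <- exp(m - apply(m, 1, max))
      p[, , k] <- e / rowSums(e)
    } else {
      e <- exp(sweep(m, 2, apply(m, 2, max)))
      p[, , k] <- sweep(e, 2, colSums(e), "/")
    }
  }
  new_tensor(p, list(a), function(g) {
    gx <- array(0, dim = d)
    for (k in seq_len(d[3])) {
      pk <- p[, , k, drop = FALSE][, , 1]
      gk <- g[, , k, drop = FALSE][, , 1]
      pk <- matrix(pk, d[1], d[2]); gk <- matrix(gk, d[1], d[2])
      if (axis == 2) {
        s <- rowSums(gk * pk)
        gx[, , k] <- pk * (gk - s)
      } else {
        s <- colSums(gk * pk)
        gx[, , k] <- pk * sweep(gk, 2, s)
      }
    }
    list(gx)
  })
}

# ---- C++-backed spatial ops ---------------------------------------------

op_conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  x <- as_tensor(x); w <- as_tensor(w); b <- as_tensor(b)
  y <- conv2d_fwd_cpp(x$v, w$v, as.numeric(b$v), as.integer(stride),
                      as.integer(pad))
  new_tensor(y, list(x, w, b), function(g) {
    r <- conv2d_bwd_cpp(x$v, w$v, g, as.integer(stride), as.integer(pad))
    list(r$gx, r$gw, array(r$gb, dim = dim(b$v)))
  })
}

op_dwconv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  x <- as_tensor(x); w <- as_tensor(w); b <- as_tensor(b)
  y <- dwconv2d_fwd_cpp(x$v, w$v, as.numeric(b$v), as.integer(stride),
                        as.integer(pad))
  new_tensor(y, list(x, w, b), function(g) {
    r <- dwconv2d_bwd_cpp(x$v, w$v, g, as.integer(stride), as.integer(pad))
    list(r$gx, r$gw, array(r$gb, dim = dim(b$v)))
  })
}

op_avgpool <- function(x, kh, kw, sh = kh, sw = kw) {
  x <- as_tensor(x)
  d <- dim(x$v)
  y <- avgpool_fwd_cpp(x$v, as.integer(kh), as.integer(kw),
                       as.integer(sh), as.integer(sw))
  new_tensor(y, list(x), function(g) {
    list(avgpool_bwd_cpp(g, d[1], d[2], as.integer(kh), as.integer(kw),
                         as.integer(sh), as.integer(sw)))
  })
}

op_bilinear <- function(x, ho, wo) {
  x <- as_tensor(x)
  d <- dim(x$v)
  if (d[1] == ho && d[2] == wo) return(x)
  y <- bilinear_fwd_cpp(x$v, as.integer(ho), as.integer(wo))
  new_tensor(y, list(x), function(g) list(bilinear_bwd_cpp(g, d[1], d[2])))
}

op_nearest_up <- function(x, fh, fw) {
  x <- as_tensor(x)
  y <- nearest_up_fwd_cpp(x$v, as.integer(fh), as.integer(fw))
  new_tensor(y, list(x),
             function(g) list(nearest_up_bwd_cpp(g, as.integer(fh),
                                                 as.integer(fw))))
}

# ---- normalization ------------------------------------------------------

# BatchNorm over (H, W, B) per channel; `state` is an environment carrying
# running_mean / running_var, updated as a side effect in training mode.
op_batchnorm <- function(x, gamma, beta, state, training = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  x <- as_tensor(x); gamma <- as_tensor(gamma); beta <- as_tensor(beta)
  d <- dim(x$v)
  C <- d[3]
  n <- d[1] * d[2] * d[4]
  xm <- matrix(aperm(x$v, c(1, 2, 4, 3)), ncol = C)  # [HWB, C]
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    state$rm <- (1 - momentum) * state$rm + momentum * mu
    state$rv <- (1 - momentum) * state$rv + momentum * va * n / max(n - 1, 1)
  } else {
    mu <- state$rm
    va <- state$rv
  }
  ivar <- 1 / sqrt(va + eps)
  xhat_m <- sweep(sweep(xm, 2, mu), 2, ivar, "*")
  ym <- sweep(sweep(xhat_m, 2, as.numeric(gamma$v), "*"), 2,
              as.numeric(beta$v), "+")
  y <- aperm(array(ym, dim = c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  new_tensor(y, list(x, gamma, beta), function(g) {
    gm <- matrix(aperm(g, c(1, 2, 4, 3)), ncol = C)
    ggamma <- colSums(gm * xhat_m)
    gbeta <- colSums(gm)
    gv <- as.numeric(gamma$v) * ivar
    if (training) {
      gxm <- sweep(
        gm * n - matrix(gbeta, nrow(gm), C, byrow = TRUE) -
          xhat_m * matrix(ggamma, nrow(gm), C, byrow = TRUE),
        2, gv / n, "*")
    } else {
      gxm <- sweep(gm, 2, gv, "*")
    }
    gx <- aperm(array(gxm, dim = c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
    list(gx, array(ggamma, dim = dim(gamma$v)), array(gbeta, dim = dim(beta$v)))
  })
}

# Layer normalization over the channel axis at every pixel (pre-norm for the
# attention / FFN sub-blocks).
op_channel_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_tensor(x); gamma <- as_tensor(gamma); beta <- as_tensor(beta)
  d <- dim(x$v)
  C <- d[3]
  xm <- matrix(aperm(x$v, c(3, 1, 2, 4)), nrow = C)  # [C, HWB]
  mu <- colMeans(xm)
  va <- colMeans(xm^2) - mu^2
  ivar <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, ivar, "*")
  ym <- sweep(xhat * as.numeric(gamma$v), 1, as.numeric(beta$v), "+")
  y <- aperm(array(ym, dim = c(C, d[1], d[2], d[4])), c(2, 3, 1, 4))
  new_tensor(y, list(x, gamma, beta), function(g) {
    gm <- matrix(aperm(g, c(3, 1, 2, 4)), nrow = C)
    ggamma <- rowSums(gm * xhat)
    gbeta <- rowSums(gm)
    gy <- gm * as.numeric(gamma$v)
    s1 <- colSums(gy)
    s2 <- colSums(gy * xhat)
    gxm <- sweep(gy * C - matrix(s1, C, ncol(gm), byrow = TRUE) -
                   xhat * matrix(s2, C, ncol(gm), byrow = TRUE),
                 2, ivar / C, "*")
    gx <- aperm(array(gxm, dim = c(C, d[1], d[2], d[4])), c(2, 3, 1, 4))
    list(gx, array(ggamma, dim = dim(gamma$v)), array(gbeta, dim = dim(beta$v)))
  })
}

# ---- fused losses -------------------------------------------------------

# Multi-class cross-entropy from logits [H,W,K,B] against integer labels
# [H,W,B] in 0..K-1; mean over pixels and batch.
op_ce_from_logits <- function(logits, target) {
  logits <- as_tensor(logits)
  d <- dim(logits$v)
  K <- d[3]
  n <- d[1] * d[2] * d[4]
  lm <- matrix(aperm(logits$v, c(1, 2, 4, 3)), ncol = K)  # [HWB, K]
  m <- apply(lm, 1, max)
  e <- exp(lm - m)
  p <- e / rowSums(e)
  tid <- as.integer(target) + 1L  # flattened [H,W,B] matches row order
  ll <- log(p[cbind(seq_len(n), tid)])
  v <- array(-mean(ll), 1L)
  new_tensor(v, list(logits), function(g) {
    gm <- p
    gm[cbind(seq_len(n), tid)] <- gm[cbind(seq_len(n), tid)] - 1
    gm <- gm * (as.numeric(g) / n)
    gx <- aperm(array(gm, dim = c(d[1], d[2], d[4], K)), c(1, 2, 4, 3))
    list(gx)
  })
}

# Soft multi-class Dice loss from logits; target as integer labels [H,W,B].
# Per sample and class: 1 - (2*I + eps) / (S_pred + S_true + eps), averaged.
op_dice_from_logits <- function(logits, target, eps = 1e-5) {
  logits <- as_tensor(logits)
  d <- dim(logits$v)
  K <- d[3]; B <- d[4]
  npix <- d[1] * d[2]
  probs <- array(0, dim = d)
  loss <- 0
  store <- vector("list", B)
  for (b in seq_len(B)) {
    lm <- matrix(logits$v[, , , b], nrow = npix, ncol = K)
    e <- exp(lm - apply(lm, 1, max))
    p <- e / rowSums(e)
    y <- matrix(0, npix, K)
    tb <- as.integer(target[, , b]) + 1L
    y[cbind(seq_len(npix), tb)] <- 1
    I <- colSums(p * y)
    S <- colSums(p) + colSums(y)
    loss <- loss + sum(1 - (2 * I + eps) / (S + eps))
    store[[b]] <- list(p = p, y = y, I = I, S = S)
    probs[, , , b] <- array(p, dim = c(d[1], d[2], K))
  }
  v <- array(loss / (K * B), 1L)
  out <- new_tensor(v, list(logits), function(g) {
    gx <- array(0, dim = d)
    gscale <- as.numeric(g) / (K * B)
    for (b in seq_len(B)) {
      st <- store[[b]]
      denom <- st$S + eps
      # dL_k/dp_{x,k} = (2I+eps)/(S+eps)^2 - 2*y_{x,k}/(S+eps)
      gp <- sweep(-2 * st$y, 2, denom, "/") +
        matrix((2 * st$I + eps) / denom^2, npix, K, byrow = TRUE)
      gp <- gp * gscale
      # softmax backward per pixel
      s <- rowSums(gp * st$p)
      gl <- st$p * (gp - s)
      gx[, , , b] <- array(gl, dim = c(d[1], d[2], K))
    }
    list(gx)
  })
  attr(out, "probs") <- probs
  out
}
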