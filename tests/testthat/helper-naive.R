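# Independent brute-force reference implementations.  Everything here is
# written with explicit loops and base-R arithmetic, sharing no code with the
# package's compute path; the oracles consume the same *weights* as the
# modules under test but re-derive every operation from its definition.

naive_softmax_rows <- function(m) {
  out <- m
  for (i in seq_len(nrow(m))) {
    e <- exp(m[i, ] - max(m[i, ]))
    out[i, ] <- e / sum(e)
  }
  out
}

naive_softmax_cols <- function(m) t(naive_softmax_rows(t(m)))

# Average-pool a [H, W] matrix onto an s x s grid with replicate padding,
# returning tokens in row-major grid order.
naive_pool_tokens <- function(mat, s) {
  H <- nrow(mat); W <- ncol(mat)
  hp <- ceiling(H / s) * s; wp <- ceiling(W / s) * s
  big <- matrix(0, hp, wp)
  for (i in seq_len(hp)) for (j in seq_len(wp)) {
    big[i, j] <- mat[min(i, H), min(j, W)]
  }
  ph <- hp / s; pw <- wp / s
  tok <- numeric(s * s)
  for (r in seq_len(s)) for (cc in seq_len(s)) {
    block <- big[(r - 1) * ph + seq_len(ph), (cc - 1) * pw + seq_len(pw),
                 drop = FALSE]
    tok[(r - 1) * s + cc] <- mean(block)
  }
  tok
}

naive_broadcast_tokens <- function(tok, s, H, W) {
  ph <- ceiling(H / s); pw <- ceiling(W / s)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    r <- (i - 1) %/% ph + 1; cc <- (j - 1) %/% pw + 1
    out[i, j] <- tok[(r - 1) * s + cc]
  }
  out
}

proj_mat <- function(p) matrix(p$w$v, dim(p$w$v)[3], dim(p$w$v)[4])
proj_bias <- function(p) as.numeric(p$b$v)

# Apply a 1x1 projection to an [H, W, C] array via explicit loops.
naive_proj <- function(x, p) {
  W <- proj_mat(p); b <- proj_bias(p)
  d <- dim(x)
  out <- array(0, c(d[1], d[2], ncol(W)))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    out[i, j, ] <- as.numeric(x[i, j, ] %*% W) + b
  }
  out
}

# Full GMSA composition for a single [H, W, C] sample, per definition:
# split channels -> project Q/K/V -> pool to s^2 tokens -> multi-head
# softmax(QK^T/sqrt(dh))V -> broadcast -> output projection -> concat.
naive_gmsa <- function(x, m) {
  d <- dim(x)
  out <- array(0, d)
  off <- 0L
  for (gi in seq_along(m$scales)) {
    w <- m$group_widths[gi]; s <- m$scales[gi]; heads <- m$heads[gi]
    xg <- x[, , off + seq_len(w), drop = FALSE]
    gp <- m$groups[[gi]]
    tok_of <- function(arr) {  # token matrix [N, w]
      matrix(vapply(seq_len(w), function(c) naive_pool_tokens(arr[, , c], s),
                    numeric(s * s)), nrow = s * s, ncol = w)
    }
    Vp <- naive_proj(xg, gp$v)
    Vt <- tok_of(Vp)
    if (s == 1L) {
      A <- Vt
    } else {
      Qp <- naive_proj(xg, gp$q); Kp <- naive_proj(xg, gp$k)
      Qt <- tok_of(Qp); Kt <- tok_of(Kp)
      dh <- w / heads
      A <- matrix(0, s * s, w)
      for (h in seq_len(heads)) {
        idx <- (h - 1) * dh + seq_len(dh)
        sc <- (Qt[, idx, drop = FALSE] %*% t(Kt[, idx, drop = FALSE])) /
          sqrt(dh)
        A[, idx] <- naive_softmax_rows(sc) %*% Vt[, idx, drop = FALSE]
      }
    }
    back <- array(0, c(d[1], d[2], w))
    for (c in seq_len(w)) {
      back[, , c] <- naive_broadcast_tokens(A[, c], s, d[1], d[2])
    }
    out[, , off + seq_len(w)] <- naive_proj(back, gp$o)
    off <- off + w
  }
  out
}

# Step-by-step ISA for a single [H, W, C] sample.
naive_isa <- function(x, m) {
  d <- dim(x)
  N <- d[1] * d[2]
  flat <- function(arr) {  # row-major tokens [N, C]
    out <- matrix(0, N, dim(arr)[3])
    for (c in seq_len(dim(arr)[3])) out[, c] <- as.numeric(t(arr[, , c]))
    out
  }
  Q <- flat(naive_proj(x, m$q))
  K <- flat(naive_proj(x, m$k))
  V <- flat(naive_proj(x, m$v))
  g <- m$groups; dg <- m$dg
  cas <- vector("list", g); qhat <- vector("list", g)
  for (i in seq_len(g)) {
    idx <- (i - 1) * dg + seq_len(dg)
    qhat[[i]] <- naive_softmax_rows(Q[, idx, drop = FALSE])
    khat <- naive_softmax_cols(K[, idx, drop = FALSE])
    cas[[i]] <- t(khat) %*% V[, idx, drop = FALSE]
  }
  pooled <- vapply(cas, mean, numeric(1))
  W1 <- m$gate_fc1$W$v; b1 <- as.numeric(m$gate_fc1$b$v)
  W2 <- m$gate_fc2$W$v; b2 <- as.numeric(m$gate_fc2$b$v)
  gelu <- function(z) 0.5 * z * (1 + tanh(sqrt(2 / pi) * (z + 0.044715 * z^3)))
  gates <- 1 / (1 + exp(-(W2 %*% gelu(W1 %*% pooled + b1) + b2)))
  A <- matrix(0, dg, dg)
  for (i in seq_len(g)) A <- A + m$mix$v[i] * gates[i] * cas[[i]]
  outtok <- matrix(0, N, d[3])
  for (i in seq_len(g)) {
    outtok[, (i - 1) * dg + seq_len(dg)] <- qhat[[i]] %*% A
  }
  out <- array(0, d)
  for (c in seq_len(d[3])) out[, , c] <- matrix(outtok[, c], d[1], d[2],
                                                byrow = TRUE)
  out
}

# Exhaustive surface-distance HD at percentile p: explicit neighbour checks
# for boundaries, all-pairs distances, manual type-7 quantile.
naive_hd <- function(pred, gt, p = 0.95) {
  bnd <- function(m) {
    m <- m != 0
    pts <- NULL
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      if (!m[i, j]) next
      nb <- c(
        if (i > 1) m[i - 1, j] else FALSE,
        if (i < nrow(m)) m[i + 1, j] else FALSE,
        if (j > 1) m[i, j - 1] else FALSE,
        if (j < ncol(m)) m[i, j + 1] else FALSE)
      if (!all(nb)) pts <- rbind(pts, c(i, j))
    }
    pts
  }
  bp <- bnd(pred); bg <- bnd(gt)
  if (is.null(bp) || is.null(bg)) return(NA_real_)
  dmin <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      min(sqrt((a[i, 1] - b[, 1])^2 + (a[i, 2] - b[, 2])^2))
    }, numeric(1))
  }
  pool <- sort(c(dmin(bp, bg), dmin(bg, bp)))
  n <- length(pool)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  pool[lo] + (h - lo) * (pool[min(lo + 1, n)] - pool[lo])
}

# Closed-form paired t-test.
naive_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# Direct-loop spatial ops for the conv-block oracles.
naive_conv2d <- function(x, w, b, stride = 1, pad = 1) {
  d <- dim(x); kd <- dim(w)
  Ho <- (d[1] + 2 * pad - kd[1]) %/% stride + 1
  Wo <- (d[2] + 2 * pad - kd[2]) %/% stride + 1
  out <- array(0, c(Ho, Wo, kd[4]))
  for (o in seq_len(kd[4])) for (io in seq_len(Ho)) for (jo in seq_len(Wo)) {
    s <- b[o]
    for (ki in seq_len(kd[1])) for (kj in seq_len(kd[2])) {
      i <- (io - 1) * stride - pad + ki
      j <- (jo - 1) * stride - pad + kj
      if (i >= 1 && i <= d[1] && j >= 1 && j <= d[2]) {
        s <- s + sum(w[ki, kj, , o] * x[i, j, ])
      }
    }
    out[io, jo, o] <- s
  }
  out
}

naive_bn_single <- function(x, gamma, beta, eps = 1e-5) {
  # batch statistics over H, W for a single sample (biased variance)
  d <- dim(x)
  out <- x
  for (c in seq_len(d[3])) {
    v <- x[, , c]
    mu <- mean(v)
    va <- mean(v^2) - mu^2
    out[, , c] <- gamma[c] * (v - mu) / sqrt(va + eps) + beta[c]
  }
  out
}

naive_gelu <- function(z) 0.5 * z * (1 + tanh(sqrt(2 / pi) * (z + 0.044715 * z^3)))

# Tiny model used across pipeline tests: 32x32 scenes, narrow widths.
tiny_spec <- function(seed = 7L) {
  scene_spec(image_size = 32L, num_classes = 3L,
             object_counts = list(c(1L, 1L), c(1L, 3L)),
             radii = list(c(6, 9), c(2, 3)),
             seed = seed)
}

tiny_model <- function(seed = 5L, num_classes = 3L, ...) {
  scaleformer(input_size = 32L, in_channels = 1L, num_classes = num_classes,
              stage_channels = c(8L, 8L, 8L, 8L),
              stage_depths = c(1L, 1L, 1L, 1L),
              ffn_ratio = 2L, lpu_expand = 2L, seed = seed, ...)
}
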