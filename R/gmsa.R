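# Grouped multi-scale attention (GMSA).
#
# Channels are split into G groups; group i projects its pixels to Q/K/V,
# pools them onto an s_i x s_i token grid (patch size H/s_i x W/s_i), runs
# scaled dot-product attention over the s_i^2 tokens, broadcasts the tokens
# back over their patches and applies a per-group output projection before
# the groups are concatenated.  Small s = few large patches (global context),
# large s = many small patches (fine detail); the per-group attention-score
# cost grows as s^4 * d.

# Promote a plain array to the internal [H, W, C, B] layout.
as_fmap <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature map must be an array")
  rank <- length(d)
  if (rank == 2L) x <- array(x, c(d, 1L, 1L))
  else if (rank == 3L) x <- array(x, c(d, 1L))
  else if (rank != 4L) stop("feature map must have 2-4 dimensions")
  attr(x, "orig_rank") <- rank
  x
}

restore_rank <- function(v, rank) {
  d <- dim(v)
  attr(v, "orig_rank") <- NULL
  if (rank == 2L) matrix(v, d[1], d[2])
  else if (rank == 3L) array(v, d[1:3])
  else v
}

#' Split a feature map into channel groups
#'
#' Partitions the channel axis of a feature map into consecutive groups whose
#' widths are given by `widths`. Concatenating the returned groups in order
#' reproduces the input exactly.
#'
#' @param X Feature map: array `[H, W, C]` or `[H, W, C, B]`.
#' @param widths Integer vector of per-group channel counts; must sum to `C`.
#' @return A list of feature maps, one per group, in order.
#' @examples
#' x <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
#' parts <- split_channels(x, c(4, 4))
#' stopifnot(identical(x, array(c(parts[[1]], parts[[2]]), dim(x))))
#' @export
split_channels <- function(X, widths) {
  xt <- as_fmap(X)
  rank <- attr(xt, "orig_rank")
  C <- dim(xt)[3]
  widths <- as.integer(widths)
  if (sum(widths) != C) {
    stop(sprintf(
      "split_channels(): group widths sum to %d but the map has %d channels",
      sum(widths), C))
  }
  out <- vector("list", length(widths))
  off <- 0L
  for (i in seq_along(widths)) {
    out[[i]] <- restore_rank(slice_arr(xt, 3L, off + seq_len(widths[i])),
                             rank)
    off <- off + widths[i]
  }
  out
}

# Internal: tokenize a [H,W,C,B] tensor onto an s x s grid by non-overlapping
# average pooling; edge-pads (replicate) when H or W is not a multiple of s.
tokenize_t <- function(x, s) {
  d <- dim(tval(x))
  H <- d[1]; W <- d[2]
  hp <- ceiling(H / s) * s
  wp <- ceiling(W / s) * s
  if (hp != H || wp != W) {
    x <- op_pad_hw(x, 0L, hp - H, 0L, wp - W, mode = "replicate")
  }
  pooled <- op_avgpool(x, hp %/% s, wp %/% s)          # [s, s, C, B]
  tok <- op_aperm(pooled, c(2, 1, 3, 4))               # column (w) fastest
  op_reshape(tok, c(s * s, d[3], d[4]))                # row-major tokens
}

detokenize_t <- function(tok, s, height, width) {
  d <- dim(tval(tok))
  grid <- op_reshape(tok, c(s, s, d[2], d[3]))         # [w, h, C, B]
  grid <- op_aperm(grid, c(2, 1, 3, 4))
  ph <- ceiling(height / s)
  pw <- ceiling(width / s)
  up <- op_nearest_up(grid, ph, pw)
  op_crop_hw(up, height, width)
}

#' Tokenize a feature map onto an s-by-s grid
#'
#' Divides the spatial extent into `s * s` non-overlapping patches of size
#' `(H/s, W/s)` and summarizes each patch by its per-channel mean, yielding
#' `s^2` tokens in row-major grid order. When `H` or `W` is not divisible by
#' `s`, the map is edge-padded up to the next multiple before pooling.
#'
#' @param x Feature map `[H, W]`, `[H, W, C]` or `[H, W, C, B]`.
#' @param s Grid side length (positive integer); requires `H >= s`, `W >= s`.
#' @return Token matrix `[s^2, C]` (or `[s^2, C, B]` for batched input).
#' @examples
#' m <- matrix(1:16, 4, 4, byrow = TRUE)
#' tokenize(m, 2)  # patch means 3.5, 5.5, 11.5, 13.5
#' @seealso [detokenize()], [gmsa_forward()]
#' @export
tokenize <- function(x, s) {
  if (s < 1) stop("tokenize(): scale s must be a positive integer")
  xt <- as_fmap(x)
  rank <- attr(xt, "orig_rank")
  if (dim(xt)[1] < s || dim(xt)[2] < s) {
    stop(sprintf("tokenize(): s=%d exceeds the %dx%d spatial size",
                 s, dim(xt)[1], dim(xt)[2]))
  }
  v <- tval(tokenize_t(new_tensor(xt), as.integer(s)))
  d <- dim(v)
  if (rank <= 3L) matrix(v, d[1], d[2]) else v
}

#' Broadcast a token grid back to a spatial map
#'
#' Inverse layout operation of [tokenize()]: each of the `s^2` tokens is
#' broadcast (nearest-neighbour) over its source patch, and any padding that
#' tokenization introduced is cropped so the output is exactly
#' `height x width`.
#'
#' @param T Token matrix `[s^2, C]` or `[s^2, C, B]`.
#' @param s Grid side length used to tokenize.
#' @param height,width Target spatial size.
#' @return Feature map `[height, width, C]` (or with a batch axis).
#' @export
detokenize <- function(T, s, height, width) {
  d <- dim(T)
  if (is.null(d)) T <- matrix(T, ncol = 1)
  d <- dim(T)
  if (d[1] != s * s) {
    stop(sprintf("detokenize(): expected %d tokens (s^2), got %d", s * s, d[1]))
  }
  rank3 <- length(d) == 3L
  tt <- if (rank3) T else array(T, c(d, 1L))
  v <- tval(detokenize_t(new_tensor(tt), as.integer(s),
                         as.integer(height), as.integer(width)))
  if (rank3) v else array(v, dim(v)[1:3])
}

# Internal multi-head scaled-dot-product attention on [N, d, B] tensors.
attention_t <- function(q, k, v, heads) {
  d <- dim(tval(q))
  N <- d[1]; dm <- d[2]; B <- d[3]
  if (dm %% heads != 0) {
    stop(sprintf("attention: width %d not divisible by %d heads", dm, heads))
  }
  dh <- dm %/% heads
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- (h - 1L) * dh + seq_len(dh)
    qh <- op_slice(q, 2L, idx)
    kh <- op_slice(k, 2L, idx)
    vh <- op_slice(v, 2L, idx)
    scores <- op_smul(op_bmm(qh, op_aperm(kh, c(2, 1, 3))), 1 / sqrt(dh))
    .sf$attn_macs <- .sf$attn_macs + as.numeric(B) * N * N * dh
    A <- op_softmax3(scores, axis = 2)
    outs[[h]] <- op_bmm(A, vh)
  }
  if (heads == 1L) outs[[1]] else op_concat(outs, 2L)
}

#' Scaled dot-product attention over token matrices
#'
#' Standard multi-head attention: per head, `softmax(Q K^T / sqrt(d_h)) V`.
#' Every attention row is a convex combination of the value rows. The number
#' of query-key multiply-accumulates is added to the package counter read by
#' [sf_counters()].
#'
#' @param Q,K,V Token matrices `[N, d]` or `[N, d, B]`, equal shapes.
#' @param heads Number of attention heads; `d` must be divisible by it.
#' @return Array shaped like `Q`.
#' @export
scaled_dot_attention <- function(Q, K, V, heads = 1L) {
  toT <- function(x) {
    d <- dim(x)
    if (is.null(d)) stop("token matrices must be matrices or 3D arrays")
    if (length(d) == 2L) array(x, c(d, 1L)) else x
  }
  rank2 <- length(dim(Q)) == 2L
  out <- tval(attention_t(new_tensor(toT(Q)), new_tensor(toT(K)),
                          new_tensor(toT(V)), as.integer(heads)))
  if (rank2) matrix(out, dim(out)[1], dim(out)[2]) else out
}

default_heads <- function(width) max(1L, width %/% 32L)

#' Construct a grouped multi-scale attention module
#'
#' @param channels Total input channels `C`.
#' @param scales Integer vector of per-group grid sides `s_i`; the number of
#'   groups `G` is `length(scales)`.
#' @param group_widths Per-group channel widths summing to `channels`, or
#'   `"auto"` for an equal split (`C` must then be divisible by `G`).
#' @param heads_per_group Heads per group; default `max(1, d_i / 32)`.
#' @return A GMSA module holding the per-group Q/K/V/output projections.
#' @seealso [gmsa_forward()], [gmsa_cost()]
#' @export
gmsa <- function(channels, scales, group_widths = "auto",
                 heads_per_group = NULL) {
  G <- length(scales)
  if (identical(group_widths, "auto")) {
    if (channels %% G != 0) {
      stop(sprintf("gmsa(): %d channels not divisible into %d equal groups",
                   channels, G))
    }
    group_widths <- rep(channels %/% G, G)
  }
  group_widths <- as.integer(group_widths)
  if (sum(group_widths) != channels) {
    stop(sprintf("gmsa(): group widths sum to %d, expected %d",
                 sum(group_widths), channels))
  }
  if (length(group_widths) != G) stop("gmsa(): one width per scale required")
  if (any(scales < 1)) stop("gmsa(): scales must be >= 1")
  if (is.null(heads_per_group)) heads_per_group <- default_heads(group_widths)
  heads_per_group <- rep(as.integer(heads_per_group), length.out = G)
  if (any(group_widths %% heads_per_group != 0)) {
    stop("gmsa(): each group width must be divisible by its head count")
  }
  groups <- vector("list", G)
  for (i in seq_len(G)) {
    d <- group_widths[i]
    # a single-token grid (s = 1) attends trivially: softmax over one logit
    # is 1 and the output is V, so Q/K projections are only created for s > 1
    if (scales[i] == 1L) {
      groups[[i]] <- list(v = layer_proj(d, d), o = layer_proj(d, d))
    } else {
      groups[[i]] <- list(q = layer_proj(d, d), k = layer_proj(d, d),
                          v = layer_proj(d, d), o = layer_proj(d, d))
    }
  }
  structure(list(channels = as.integer(channels),
                 scales = as.integer(scales),
                 group_widths = group_widths,
                 heads = heads_per_group,
                 groups = groups),
            class = c("sf_gmsa", "sf_module"))
}

gmsa_forward_t <- function(x, m) {
  d <- dim(tval(x))
  if (d[3] != m$channels) {
    stop(sprintf("gmsa_forward(): map has %d channels, module expects %d",
                 d[3], m$channels))
  }
  res <- min(d[1], d[2])
  bad <- m$scales[m$scales > res]
  if (length(bad)) {
    stop(sprintf(
      "gmsa_forward(): scale s=%d exceeds the %dx%d stage resolution",
      bad[1], d[1], d[2]))
  }
  outs <- vector("list", length(m$scales))
  off <- 0L
  for (i in seq_along(m$scales)) {
    w <- m$group_widths[i]
    s <- m$scales[i]
    xg <- op_slice(x, 3L, off + seq_len(w))
    off <- off + w
    v <- tokenize_t(fwd_proj(m$groups[[i]]$v, xg), s)
    a <- if (s == 1L) {
      .sf$attn_macs <- .sf$attn_macs + as.numeric(d[4]) * w
      v
    } else {
      q <- tokenize_t(fwd_proj(m$groups[[i]]$q, xg), s)
      k <- tokenize_t(fwd_proj(m$groups[[i]]$k, xg), s)
      attention_t(q, k, v, m$heads[i])
    }
    map <- detokenize_t(a, s, d[1], d[2])
    outs[[i]] <- fwd_proj(m$groups[[i]]$o, map)
  }
  if (length(outs) == 1L) outs[[1]] else op_concat(outs, 3L)
}

#' Apply grouped multi-scale attention to a feature map
#'
#' Per group: project to Q/K/V, tokenize at the group's scale, attend over
#' the token grid, broadcast back, apply the group's output projection;
#' groups are concatenated along channels. Output shape equals input shape.
#'
#' @param X Feature map `[H, W, C]` or `[H, W, C, B]` (or an internal tensor).
#' @param cfg A module from [gmsa()] with `channels == C`; every scale must
#'   satisfy `s_i <= min(H, W)`.
#' @return Feature map of the same shape as `X`.
#' @export
gmsa_forward <- function(X, cfg) {
  if (is_tensor(X)) return(gmsa_forward_t(X, cfg))
  xt <- as_fmap(X)
  rank <- attr(xt, "orig_rank")
  restore_rank(tval(gmsa_forward_t(new_tensor(xt), cfg)), rank)
}

#' Token counts and attention cost of a GMSA configuration
#'
#' Reports, per group, the token count `N_i = s_i^2` and the attention-score
#' multiply-accumulate estimate `N_i^2 * d_i = s_i^4 * d_i`, plus totals.
#'
#' @param cfg A [gmsa()] module, or a list with `scales` and `group_widths`.
#' @param stage_resolution Optional spatial side length, echoed in the report
#'   (and used to flag scales exceeding it).
#' @param json If `TRUE`, return the report as a JSON string.
#' @return A list with a per-group data frame and the total cost (or JSON).
#' @export
gmsa_cost <- function(cfg, stage_resolution = NULL, json = FALSE) {
  scales <- as.integer(cfg$scales)
  widths <- as.integer(cfg$group_widths)
  tokens <- scales^2
  macs <- as.numeric(scales)^4 * widths
  df <- data.frame(group = seq_along(scales), scale = scales, width = widths,
                   tokens = tokens, attn_macs = macs)
  rep <- list(groups = df, total_macs = sum(macs))
  if (!is.null(stage_resolution)) {
    rep$stage_resolution <- as.integer(stage_resolution)
    rep$scale_fits <- scales <= stage_resolution
  }
  if (json) jsonlite::toJSON(rep, dataframe = "rows", auto_unbox = TRUE)
  else rep
}
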