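# Inter-scale attention (ISA).
#
# A linear-complexity, channel-affinity attention used after GMSA to exchange
# information across the scale groups.  Per group, a [d_g, d_g] channel
# affinity CA_i = softmax_tokens(k_i)^T v_i is computed (cost linear in the
# token count N = h*w).  Each CA_i is globally pooled to one scalar; the g
# scalars pass through a small gate network and a sigmoid, scaling their
# affinity maps.  The scaled maps are mixed by a learned combination across
# the group axis into one shared map A, which every group applies to its
# channel-softmaxed queries: out_i = softmax_chan(q_i) A.

map_to_tokens_t <- function(x) {
  d <- dim(tval(x))
  op_reshape(op_aperm(x, c(2, 1, 3, 4)), c(d[1] * d[2], d[3], d[4]))
}

tokens_to_map_t <- function(tok, H, W) {
  d <- dim(tval(tok))
  op_aperm(op_reshape(tok, c(W, H, d[2], d[3])), c(2, 1, 3, 4))
}

# Learned mixture across the group axis: A = sum_j theta_j * CA_j.
op_mix3 <- function(xs, theta) {
  xs <- lapply(xs, as_tensor)
  theta <- as_tensor(theta)
  th <- as.numeric(theta$v)
  v <- array(0, dim = dim(xs[[1]]$v))
  for (j in seq_along(xs)) v <- v + th[j] * xs[[j]]$v
  new_tensor(v, c(xs, list(theta)), function(g) {
    gs <- lapply(seq_along(xs), function(j) g * th[j])
    gt <- vapply(xs, function(x) sum(g * x$v), numeric(1))
    c(gs, list(array(gt, dim = dim(theta$v))))
  })
}

#' Construct an inter-scale attention module
#'
#' @param channels Total channels `c`; must be divisible by `groups`.
#' @param groups Number of scale groups `g` the channel axis is split into.
#' @param gate_reduction Reduction ratio of the two-layer gate network that
#'   turns the pooled per-group affinities into sigmoid gates (default 2).
#' @return An ISA module with Q/K/V projections, gate network, and the
#'   learned group-mixing weights.
#' @seealso [isa_forward()]
#' @export
isa <- function(channels, groups = 2L, gate_reduction = 2L) {
  if (channels %% groups != 0) {
    stop(sprintf("isa(): %d channels not divisible by %d groups",
                 channels, groups))
  }
  hidden <- max(1L, as.integer(groups) %/% as.integer(gate_reduction))
  structure(list(
    channels = as.integer(channels),
    groups = as.integer(groups),
    dg = as.integer(channels %/% groups),
    q = layer_proj(channels, channels),
    k = layer_proj(channels, channels),
    v = layer_proj(channels, channels),
    gate_fc1 = layer_dense(groups, hidden),
    gate_fc2 = layer_dense(hidden, groups),
    mix = new_param(array(1 / groups, groups))
  ), class = c("sf_isa", "sf_module"))
}

#' Project a feature map to flattened Q, K, V token matrices
#'
#' Applies the module's three linear (1x1) projections and flattens the
#' spatial grid row-major into `N = h*w` tokens.
#'
#' @param X Feature map `[H, W, C]` or `[H, W, C, B]`.
#' @param cfg An [isa()] module with matching channels.
#' @return List with `Q`, `K`, `V`, each `[N, C]` (or `[N, C, B]`).
#' @export
project_qkv <- function(X, cfg) {
  xt <- as_fmap(X)
  rank <- attr(xt, "orig_rank")
  if (dim(xt)[3] != cfg$channels) {
    stop(sprintf("project_qkv(): map has %d channels, module expects %d",
                 dim(xt)[3], cfg$channels))
  }
  x <- new_tensor(xt)
  out <- lapply(list(cfg$q, cfg$k, cfg$v), function(p) {
    v <- tval(map_to_tokens_t(fwd_proj(p, x)))
    if (rank <= 3L) matrix(v, dim(v)[1], dim(v)[2]) else v
  })
  names(out) <- c("Q", "K", "V")
  out
}

channel_affinity_t <- function(k_i, v_i) {
  d <- dim(tval(k_i))
  khat <- op_softmax3(k_i, axis = 1)   # over tokens, per channel
  ca <- op_bmm(op_aperm(khat, c(2, 1, 3)), v_i)
  .sf$isa_macs <- .sf$isa_macs + as.numeric(d[3]) * d[1] * d[2] * d[2]
  ca
}

#' Channel-affinity map of one scale group
#'
#' `CA = softmax_tokens(k)^T v`: keys are softmax-normalized over the token
#' axis and contracted with the values, giving a `[d, d]` channel-channel
#' affinity whose cost is linear in the token count. The multiply count is
#' added to the `isa_macs` counter ([sf_counters()]).
#'
#' @param k_i,v_i Token matrices `[N, d]` or `[N, d, B]`.
#' @return Affinity array `[d, d]` (or `[d, d, B]`).
#' @export
channel_affinity <- function(k_i, v_i) {
  rank2 <- length(dim(k_i)) == 2L
  to3 <- function(x) if (length(dim(x)) == 2L) array(x, c(dim(x), 1L)) else x
  out <- tval(channel_affinity_t(new_tensor(to3(k_i)), new_tensor(to3(v_i))))
  if (rank2) matrix(out, dim(out)[1], dim(out)[2]) else out
}

#' Gates from pooled group affinities
#'
#' Global-average-pools each group's affinity map to a single scalar, passes
#' the `g` scalars through the module's two-layer gate network and squashes
#' with a sigmoid, yielding one gate in (0, 1) per group.
#'
#' @param affinities List of `[d, d]` (or `[d, d, B]`) affinity arrays.
#' @param cfg An [isa()] module providing the gate network.
#' @return Gate matrix `[g, B]` (a vector when `B = 1`).
#' @export
group_gate <- function(affinities, cfg) {
  to3 <- function(x) if (length(dim(x)) == 2L) array(x, c(dim(x), 1L)) else x
  tens <- lapply(affinities, function(a) new_tensor(to3(a)))
  g <- gate_t(tens, cfg)
  v <- tval(g)
  if (ncol(v) == 1L) as.numeric(v) else v
}

gate_t <- function(ca_list, cfg) {
  pooled <- lapply(ca_list, op_mean3_12)            # each [1, B]
  pv <- op_concat(pooled, 1L)                       # [g, B]
  op_sigmoid(fwd_dense(cfg$gate_fc2, op_gelu(fwd_dense(cfg$gate_fc1, pv))))
}

isa_forward_t <- function(x, m) {
  d <- dim(tval(x))
  if (d[3] != m$channels) {
    stop(sprintf("isa_forward(): map has %d channels, module expects %d",
                 d[3], m$channels))
  }
  H <- d[1]; W <- d[2]; B <- d[4]
  q <- map_to_tokens_t(fwd_proj(m$q, x))
  k <- map_to_tokens_t(fwd_proj(m$k, x))
  v <- map_to_tokens_t(fwd_proj(m$v, x))
  g <- m$groups
  dg <- m$dg
  qs <- vector("list", g)
  cas <- vector("list", g)
  for (i in seq_len(g)) {
    idx <- (i - 1L) * dg + seq_len(dg)
    qs[[i]] <- op_softmax3(op_slice(q, 2L, idx), axis = 2)  # over channels
    cas[[i]] <- channel_affinity_t(op_slice(k, 2L, idx), op_slice(v, 2L, idx))
  }
  gates <- gate_t(cas, m)                                    # [g, B]
  scaled <- vector("list", g)
  for (i in seq_len(g)) {
    gi <- op_reshape(op_slice(gates, 1L, i), c(1L, 1L, B))
    scaled[[i]] <- op_mul(cas[[i]], gi)
  }
  A <- op_mix3(scaled, m$mix)                                # shared [dg,dg,B]
  outs <- lapply(qs, function(qi) op_bmm(qi, A))             # [N, dg, B]
  tok <- if (g == 1L) outs[[1]] else op_concat(outs, 2L)
  tokens_to_map_t(tok, H, W)
}

#' Apply inter-scale attention to a feature map
#'
#' Computes per-group channel affinities, gates them with the pooled-affinity
#' sigmoid gates, mixes the gated maps across the group axis into a single
#' shared affinity, and applies it to each group's channel-softmaxed queries.
#' Output shape equals input shape; cost is linear in the pixel count.
#'
#' @param X Feature map `[H, W, C]` or `[H, W, C, B]` (or internal tensor).
#' @param cfg An [isa()] module with `channels == C`.
#' @return Feature map shaped like `X`.
#' @export
isa_forward <- function(X, cfg) {
  if (is_tensor(X)) return(isa_forward_t(X, cfg))
  xt <- as_fmap(X)
  rank <- attr(xt, "orig_rank")
  restore_rank(tval(isa_forward_t(new_tensor(xt), cfg)), rank)
}
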