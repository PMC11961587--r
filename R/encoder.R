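# Hierarchical encoder: a stride-4 convolutional patch-embedding stem, then
# four stages.  Each stage opens with a Local Perception Unit (LPU) — a
# convolutional residual block that supplies locality and translation
# behaviour the attention path lacks — followed by L_i MSEAUs, each a
# pre-norm residual chain GMSA -> FFN -> ISA -> FFN.  The stage-leading LPU
# carries the between-stage downsampling (pooled skip + strided depthwise).

#' Construct a local perception unit
#'
#' `LPU(X) = Skip(X) + Proj(SE(DWConv(Conv(Norm(X)))))`: batch-norm, 1x1
#' channel expansion (+BN, smooth-GELU), 3x3 depthwise conv (+BN, GELU;
#' stride 2 when downsampling), squeeze-excitation, and a 1x1 shrink back to
#' the output width. The skip path is the identity (no downsampling) or
#' 2x2 average pooling plus a channel projection (downsampling).
#'
#' @param cin,cout Input / output channels (`cin == cout` unless downsampling).
#' @param downsample Halve the spatial resolution?
#' @param expand Expansion ratio of the hidden width (default 4).
#' @param pad_mode Padding for the depthwise conv: `"zero"` (default),
#'   `"circular"` or `"replicate"`. Circular padding makes the unit exactly
#'   translation-equivariant on wrapped shifts.
#' @return An LPU module.
#' @export
lpu <- function(cin, cout = cin, downsample = FALSE, expand = 4L,
                pad_mode = "zero") {
  if (!downsample && cin != cout) {
    stop("lpu(): identity skip requires cin == cout")
  }
  hidden <- as.integer(expand) * cin
  structure(list(
    cin = cin, cout = cout, downsample = downsample, pad_mode = pad_mode,
    norm = layer_bn(cin),
    expandp = layer_proj(cin, hidden), bn1 = layer_bn(hidden),
    dw = layer_dwconv(hidden, 3L), bn2 = layer_bn(hidden),
    se = layer_se(hidden),
    proj = layer_proj(hidden, cout),
    skip_proj = if (downsample) layer_proj(cin, cout)
  ), class = c("sf_lpu", "sf_module"))
}

lpu_forward_t <- function(x, m, train = TRUE) {
  y <- fwd_bn(m$norm, x, train)
  y <- op_gelu(fwd_bn(m$bn1, fwd_proj(m$expandp, y), train))
  stride <- if (m$downsample) 2L else 1L
  y <- op_gelu(fwd_bn(m$bn2,
                      fwd_dwconv(m$dw, y, stride = stride, pad = 1L,
                                 pad_mode = m$pad_mode), train))
  y <- fwd_proj(m$proj, fwd_se(m$se, y))
  skip <- if (m$downsample) {
    fwd_proj(m$skip_proj, op_avgpool(x, 2L, 2L))
  } else x
  op_add(skip, y)
}

#' Apply a local perception unit
#'
#' @param X Feature map `[H, W, C]` or `[H, W, C, B]` (or internal tensor).
#' @param params An [lpu()] module.
#' @param train Use batch statistics (TRUE) or running statistics (FALSE).
#' @return Feature map; spatial size halves iff the module downsamples.
#' @export
lpu_forward <- function(X, params, train = TRUE) {
  if (is_tensor(X)) return(lpu_forward_t(X, params, train))
  xt <- as_fmap(X)
  rank <- attr(xt, "orig_rank")
  restore_rank(tval(lpu_forward_t(new_tensor(xt), params, train)), rank)
}

#' Construct a pointwise feed-forward block
#'
#' Two 1x1 projections with a smooth-GELU between, expansion ratio `ratio`.
#'
#' @param channels Input/output channels.
#' @param ratio Hidden expansion ratio (default 4).
#' @return An FFN module.
#' @export
ffn <- function(channels, ratio = 4L) {
  hidden <- as.integer(ratio) * channels
  structure(list(fc1 = layer_proj(channels, hidden),
                 fc2 = layer_proj(hidden, channels)),
            class = c("sf_ffn", "sf_module"))
}

ffn_forward_t <- function(x, m) fwd_proj(m$fc2, op_gelu(fwd_proj(m$fc1, x)))

#' Apply a feed-forward block
#' @param X Feature map (array or internal tensor).
#' @param params An [ffn()] module.
#' @return Feature map of the same shape.
#' @export
ffn_forward <- function(X, params) {
  if (is_tensor(X)) return(ffn_forward_t(X, params))
  xt <- as_fmap(X)
  rank <- attr(xt, "orig_rank")
  restore_rank(tval(ffn_forward_t(new_tensor(xt), params)), rank)
}

#' Construct a multi-scale extraction and aggregation unit
#'
#' Four pre-norm residual sub-blocks:
#' `X + GMSA(LN(X))`, `+ FFN(LN(.))`, `+ ISA(LN(.))`, `+ FFN(LN(.))`.
#'
#' @param channels Stage channels.
#' @param scales Per-group token-grid sides for the GMSA sub-block.
#' @param isa_groups Group count of the ISA sub-block.
#' @param ffn_ratio FFN expansion ratio.
#' @param heads_per_group,group_widths Forwarded to [gmsa()].
#' @param isa_gate_reduction Forwarded to [isa()].
#' @return An MSEAU module.
#' @export
mseau <- function(channels, scales, isa_groups = 2L, ffn_ratio = 4L,
                  heads_per_group = NULL, group_widths = "auto",
                  isa_gate_reduction = 2L) {
  structure(list(
    ln1 = layer_ln(channels),
    gmsa = gmsa(channels, scales, group_widths, heads_per_group),
    ln2 = layer_ln(channels),
    ffn1 = ffn(channels, ffn_ratio),
    ln3 = layer_ln(channels),
    isa = isa(channels, isa_groups, isa_gate_reduction),
    ln4 = layer_ln(channels),
    ffn2 = ffn(channels, ffn_ratio)
  ), class = c("sf_mseau", "sf_module"))
}

mseau_forward_t <- function(x, m) {
  x <- op_add(x, gmsa_forward_t(fwd_ln(m$ln1, x), m$gmsa))
  x <- op_add(x, ffn_forward_t(fwd_ln(m$ln2, x), m$ffn1))
  x <- op_add(x, isa_forward_t(fwd_ln(m$ln3, x), m$isa))
  op_add(x, ffn_forward_t(fwd_ln(m$ln4, x), m$ffn2))
}

#' Apply a multi-scale extraction and aggregation unit
#' @param X Feature map (array or internal tensor).
#' @param cfg An [mseau()] module.
#' @return Feature map of the same shape.
#' @export
mseau_forward <- function(X, cfg) {
  if (is_tensor(X)) return(mseau_forward_t(X, cfg))
  xt <- as_fmap(X)
  rank <- attr(xt, "orig_rank")
  restore_rank(tval(mseau_forward_t(new_tensor(xt), cfg)), rank)
}

# Clamp configured scales to the stage resolution (a 7-token-per-side grid
# cannot exceed a 4x4 map; the effective scale is min(s, resolution)).
clamp_scales <- function(scales, resolution) {
  pmin(as.integer(scales), as.integer(resolution))
}

#' Construct the four-stage hierarchical encoder
#'
#' A 7x7 stride-4 convolutional patch embedding, then four stages of one LPU
#' (downsampling from stage 2 on) plus `depths[i]` MSEAUs, emitting a feature
#' pyramid at strides 4, 8, 16 and 32. Configured scales are clamped to each
#' stage's resolution.
#'
#' @param input_size Input side length; must be divisible by 32.
#' @param in_channels Image channels (1 grayscale, 3 RGB).
#' @param channels Four stage widths, e.g. `c(64, 128, 256, 512)`.
#' @param depths Four MSEAU counts per stage.
#' @param scales List of four integer vectors of per-group scales, default
#'   `list(c(1,2,4,7), c(1,2,4,7), c(1,7), c(1,7))`.
#' @param ffn_ratio,isa_groups,isa_gate_reduction,lpu_expand Block settings.
#' @return An encoder module.
#' @export
encoder <- function(input_size = 224L, in_channels = 1L,
                    channels = c(64L, 128L, 256L, 512L),
                    depths = c(2L, 2L, 2L, 2L),
                    scales = list(c(1L, 2L, 4L, 7L), c(1L, 2L, 4L, 7L),
                                  c(1L, 7L), c(1L, 7L)),
                    ffn_ratio = 4L, isa_groups = 2L, isa_gate_reduction = 2L,
                    lpu_expand = 4L) {
  if (input_size %% 32L != 0L) {
    stop(sprintf(
      "encoder(): input size %d is not divisible by 32; resize required",
      input_size))
  }
  stopifnot(length(channels) == 4L, length(depths) == 4L,
            length(scales) == 4L, all(depths >= 1L))
  resolutions <- input_size %/% c(4L, 8L, 16L, 32L)
  stages <- vector("list", 4L)
  for (i in 1:4) {
    st_scales <- clamp_scales(scales[[i]], resolutions[i])
    blocks <- lapply(seq_len(depths[i]), function(j) {
      mseau(channels[i], st_scales, isa_groups, ffn_ratio,
            isa_gate_reduction = isa_gate_reduction)
    })
    stages[[i]] <- list(
      lpu = if (i == 1L) lpu(channels[1], channels[1], FALSE, lpu_expand)
            else lpu(channels[i - 1], channels[i], TRUE, lpu_expand),
      blocks = blocks,
      scales = st_scales,
      resolution = resolutions[i])
  }
  structure(list(
    input_size = as.integer(input_size),
    in_channels = as.integer(in_channels),
    channels = as.integer(channels),
    depths = as.integer(depths),
    resolutions = resolutions,
    stem_conv = layer_conv(in_channels, channels[1], k = 7L),
    stem_bn = layer_bn(channels[1]),
    stages = stages
  ), class = c("sf_encoder", "sf_module"))
}

encoder_forward_t <- function(x, m, train = TRUE) {
  d <- dim(tval(x))
  if (d[1] %% 32L != 0L || d[2] %% 32L != 0L) {
    stop(sprintf(
      "encoder_forward(): %dx%d input is not divisible by 32; resize required",
      d[1], d[2]))
  }
  y <- op_conv2d(x, m$stem_conv$w, m$stem_conv$b, stride = 4L, pad = 3L)
  y <- op_gelu(fwd_bn(m$stem_bn, y, train))
  pyramid <- vector("list", 4L)
  for (i in 1:4) {
    y <- lpu_forward_t(y, m$stages[[i]]$lpu, train)
    for (blk in m$stages[[i]]$blocks) y <- mseau_forward_t(y, blk)
    pyramid[[i]] <- y
  }
  names(pyramid) <- paste0("stride", c(4L, 8L, 16L, 32L))
  pyramid
}

#' Run the encoder, returning the feature pyramid
#'
#' @param image Input `[H, W, C]` or `[H, W, C, B]` with `H`, `W` divisible
#'   by 32 (or an internal tensor).
#' @param cfgs An [encoder()] module.
#' @param train Use batch statistics in the normalization layers.
#' @return Named list of maps at strides 4, 8, 16, 32.
#' @export
encoder_forward <- function(image, cfgs, train = TRUE) {
  if (is_tensor(image)) return(encoder_forward_t(image, cfgs, train))
  xt <- as_fmap(image)
  rank <- attr(xt, "orig_rank")
  out <- encoder_forward_t(new_tensor(xt), cfgs, train)
  lapply(out, function(t) restore_rank(tval(t), rank))
}
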