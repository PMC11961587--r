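# Context-perception decoder.  The deepest pyramid map enters directly (no
# CPB — the decoder stream does not exist yet); every shallower stage is
# reached by bilinear x2 upsampling + 1x1 width reduction, fused with the
# matching encoder map by a Context Perception Block, refined by an
# Inception block and re-weighted by channel-then-spatial attention (CSA).
# Auxiliary 1x1 heads tap the stride-8/16/32 states for deep supervision;
# the stride-4 state is carried to full resolution through two simple-fusion
# steps with low-level stem features before the main 1x1 head.

#' Construct a context perception block
#'
#' Fuses an encoder map with the decoder stream at equal resolution:
#' `x' = ConvFuse(SE(concat(enc, dec)))`, `gate = sigmoid(Conv(dec))`,
#' `out = enc + gate * x'` (residual on the encoder stream).
#'
#' @param channels Channels of both inputs and the output.
#' @return A CPB module.
#' @export
cpb <- function(channels) {
  structure(list(
    channels = as.integer(channels),
    se = layer_se(2L * channels),
    fuse = layer_conv(2L * channels, channels, k = 3L),
    gate = layer_conv(channels, channels, k = 3L)
  ), class = c("sf_cpb", "sf_module"))
}

cpb_forward_t <- function(enc, dec, m) {
  de <- dim(tval(enc)); dd <- dim(tval(dec))
  if (de[1] != dd[1] || de[2] != dd[2]) {
    stop(sprintf("cpb_forward(): spatial mismatch %dx%d vs %dx%d",
                 de[1], de[2], dd[1], dd[2]))
  }
  xp <- fwd_conv(m$fuse, fwd_se(m$se, op_concat(list(enc, dec), 3L)))
  gate <- op_sigmoid(fwd_conv(m$gate, dec))
  op_add(enc, op_mul(gate, xp))
}

#' Apply a context perception block
#' @param enc,dec Encoder / decoder feature maps of equal spatial size
#'   (arrays or internal tensors).
#' @param params A [cpb()] module.
#' @return Fused feature map shaped like `enc`.
#' @export
cpb_forward <- function(enc, dec, params) {
  if (is_tensor(enc)) return(cpb_forward_t(enc, dec, params))
  et <- as_fmap(enc); dt <- as_fmap(dec)
  rank <- attr(et, "orig_rank")
  restore_rank(tval(cpb_forward_t(new_tensor(et), new_tensor(dt), params)),
               rank)
}

#' Construct an Inception refinement block
#'
#' Parallel 1x1, 3x3, 5x5 (two stacked 3x3) and pooled branches, each of
#' width `channels/4`, concatenated and projected back to `channels`.
#'
#' @param channels Input/output channels; must be divisible by 4.
#' @return An Inception module.
#' @export
inception <- function(channels) {
  if (channels %% 4L != 0L) stop("inception(): channels must be divisible by 4")
  w <- channels %/% 4L
  structure(list(
    channels = as.integer(channels),
    b1 = layer_proj(channels, w),
    b3 = layer_conv(channels, w, k = 3L),
    b5a = layer_conv(channels, w, k = 3L), b5b = layer_conv(w, w, k = 3L),
    bp = layer_proj(channels, w),
    proj = layer_proj(channels, channels)
  ), class = c("sf_inception", "sf_module"))
}

inception_forward_t <- function(x, m) {
  pooled <- op_avgpool(op_pad_hw(x, 1L, 1L, 1L, 1L, "zero"), 3L, 3L, 1L, 1L)
  br <- list(fwd_proj(m$b1, x),
             fwd_conv(m$b3, x),
             fwd_conv(m$b5b, fwd_conv(m$b5a, x)),
             fwd_proj(m$bp, pooled))
  fwd_proj(m$proj, op_concat(br, 3L))
}

#' Apply an Inception block
#' @param X Feature map (array or internal tensor).
#' @param params An [inception()] module.
#' @return Feature map of the same shape.
#' @export
inception_forward <- function(X, params) {
  if (is_tensor(X)) return(inception_forward_t(X, params))
  xt <- as_fmap(X)
  rank <- attr(xt, "orig_rank")
  restore_rank(tval(inception_forward_t(new_tensor(xt), params)), rank)
}

#' Construct a channel + spatial attention block
#'
#' Channel attention (global pool, bottleneck, sigmoid, per-channel scale)
#' followed by spatial attention (channelwise mean and max statistics, 7x7
#' conv, sigmoid, per-pixel scale).
#'
#' @param channels Input channels.
#' @param reduction Channel-attention bottleneck ratio (default 4).
#' @return A CSA module.
#' @export
csa <- function(channels, reduction = 4L) {
  structure(list(
    channels = as.integer(channels),
    ca = layer_se(channels, reduction),
    sa = layer_conv(2L, 1L, k = 7L)
  ), class = c("sf_csa", "sf_module"))
}

csa_forward_t <- function(x, m) {
  y <- fwd_se(m$ca, x)
  stats <- op_concat(list(op_chan_mean(y), op_chan_max(y)), 3L)
  # replicate padding keeps the spatial gate free of border artefacts (a
  # uniform map then yields a spatially constant gate)
  stats <- op_pad_hw(stats, 3L, 3L, 3L, 3L, mode = "replicate")
  gate <- op_sigmoid(fwd_conv(m$sa, stats, pad = 0L))   # [H, W, 1, B]
  op_mul(y, gate)
}

#' Apply channel-then-spatial attention
#' @param X Feature map (array or internal tensor).
#' @param params A [csa()] module.
#' @return Re-weighted feature map of the same shape.
#' @export
csa_forward <- function(X, params) {
  if (is_tensor(X)) return(csa_forward_t(X, params))
  xt <- as_fmap(X)
  rank <- attr(xt, "orig_rank")
  restore_rank(tval(csa_forward_t(new_tensor(xt), params)), rank)
}

#' Construct the low-level feature stems
#'
#' Two cascaded conv(3x3)-BN-ReLU blocks on the raw image: the first keeps
#' full resolution, the second (computed from the first, stride 2) halves it.
#'
#' @param in_channels Image channels.
#' @param channels Stem feature width.
#' @return A stem module.
#' @export
stems <- function(in_channels, channels) {
  structure(list(
    channels = as.integer(channels),
    c1 = layer_conv(in_channels, channels, k = 3L), bn1 = layer_bn(channels),
    c2 = layer_conv(channels, channels, k = 3L), bn2 = layer_bn(channels)
  ), class = c("sf_stems", "sf_module"))
}

stem_features_t <- function(img, m, train = TRUE) {
  f_full <- op_relu(fwd_bn(m$bn1, fwd_conv(m$c1, img), train))
  f_half <- op_relu(fwd_bn(m$bn2, fwd_conv(m$c2, f_full, stride = 2L), train))
  list(f_full = f_full, f_half = f_half)
}

#' Compute full- and half-resolution stem features
#' @param image Input image (array or internal tensor).
#' @param params A [stems()] module.
#' @param train Use batch statistics.
#' @return List with `f_full` (`H x W`) and `f_half` (`H/2 x W/2`).
#' @export
stem_features <- function(image, params, train = TRUE) {
  if (is_tensor(image)) return(stem_features_t(image, params, train))
  xt <- as_fmap(image)
  rank <- attr(xt, "orig_rank")
  out <- stem_features_t(new_tensor(xt), params, train)
  lapply(out, function(t) restore_rank(tval(t), rank))
}

#' Construct a simple fusion block
#'
#' Bilinearly upsamples the coarse stream x2, concatenates the fine
#' (low-level) stream and applies conv(3x3)-BN-ReLU.
#'
#' @param c_high,c_low Channels of the coarse / fine inputs.
#' @param c_out Output channels.
#' @return A fusion module.
#' @export
simple_fusion_block <- function(c_high, c_low, c_out) {
  structure(list(
    conv = layer_conv(c_high + c_low, c_out, k = 3L),
    bn = layer_bn(c_out)
  ), class = c("sf_fusion", "sf_module"))
}

simple_fusion_t <- function(high, low, m, train = TRUE) {
  dh <- dim(tval(high)); dl <- dim(tval(low))
  if (dl[1] != 2L * dh[1] || dl[2] != 2L * dh[2]) {
    stop(sprintf(
      "simple_fusion(): fine map %dx%d is not 2x the coarse map %dx%d",
      dl[1], dl[2], dh[1], dh[2]))
  }
  up <- op_bilinear(high, dl[1], dl[2])
  op_relu(fwd_bn(m$bn, fwd_conv(m$conv, op_concat(list(up, low), 3L)), train))
}

#' Fuse a coarse stream with a 2x-finer low-level stream
#' @param high Coarse feature map; `low` must be exactly twice its size.
#' @param low Fine feature map.
#' @param params A [simple_fusion_block()] module.
#' @param train Use batch statistics.
#' @return Feature map at `low`'s resolution.
#' @export
simple_fusion <- function(high, low, params, train = TRUE) {
  if (is_tensor(high)) return(simple_fusion_t(high, low, params, train))
  ht <- as_fmap(high); lt <- as_fmap(low)
  rank <- attr(ht, "orig_rank")
  restore_rank(tval(simple_fusion_t(new_tensor(ht), new_tensor(lt),
                                    params, train)), rank)
}

#' Construct the full decoder
#'
#' @param channels Encoder stage widths `C1..C4`.
#' @param num_classes Segmentation classes `K`.
#' @param stem_channels Width of the low-level stems (default
#'   `max(16, C1/2)`).
#' @param aux_heads Attach the stride-8/16/32 deep-supervision heads?
#' @return A decoder module.
#' @export
decoder <- function(channels, num_classes, stem_channels = NULL,
                    aux_heads = TRUE) {
  C <- as.integer(channels)
  K <- as.integer(num_classes)
  if (is.null(stem_channels)) stem_channels <- max(16L, C[1] %/% 2L)
  structure(list(
    channels = C, num_classes = K, stem_channels = as.integer(stem_channels),
    aux_heads = isTRUE(aux_heads),
    refine4 = list(inc = inception(C[4]), csa = csa(C[4])),
    up3 = layer_proj(C[4], C[3]), cpb3 = cpb(C[3]),
    refine3 = list(inc = inception(C[3]), csa = csa(C[3])),
    up2 = layer_proj(C[3], C[2]), cpb2 = cpb(C[2]),
    refine2 = list(inc = inception(C[2]), csa = csa(C[2])),
    up1 = layer_proj(C[2], C[1]), cpb1 = cpb(C[1]),
    refine1 = list(inc = inception(C[1]), csa = csa(C[1])),
    fuse_half = simple_fusion_block(C[1], stem_channels, stem_channels),
    fuse_full = simple_fusion_block(stem_channels, stem_channels,
                                    stem_channels),
    head = layer_proj(stem_channels, K),
    aux32 = if (aux_heads) layer_proj(C[4], K),
    aux16 = if (aux_heads) layer_proj(C[3], K),
    aux8 = if (aux_heads) layer_proj(C[2], K)
  ), class = c("sf_decoder", "sf_module"))
}

decoder_forward_t <- function(pyramid, stem_feats, m, train = TRUE) {
  refine <- function(x, r) csa_forward_t(inception_forward_t(x, r$inc), r$csa)
  up2x <- function(x, proj) {
    d <- dim(tval(x))
    fwd_proj(proj, op_bilinear(x, 2L * d[1], 2L * d[2]))
  }
  d4 <- refine(pyramid[[4]], m$refine4)                       # stride 32
  d3 <- refine(cpb_forward_t(pyramid[[3]], up2x(d4, m$up3), m$cpb3),
               m$refine3)                                     # stride 16
  d2 <- refine(cpb_forward_t(pyramid[[2]], up2x(d3, m$up2), m$cpb2),
               m$refine2)                                     # stride 8
  d1 <- refine(cpb_forward_t(pyramid[[1]], up2x(d2, m$up1), m$cpb1),
               m$refine1)                                     # stride 4
  f2 <- simple_fusion_t(d1, stem_feats$f_half, m$fuse_half, train)
  f1 <- simple_fusion_t(f2, stem_feats$f_full, m$fuse_full, train)
  main <- fwd_proj(m$head, f1)
  aux <- if (m$aux_heads) {
    list(aux8 = fwd_proj(m$aux8, d2),
         aux16 = fwd_proj(m$aux16, d3),
         aux32 = fwd_proj(m$aux32, d4))
  }
  c(list(main = main), aux)
}

#' Run the decoder on a feature pyramid
#'
#' @param pyramid List of encoder maps at strides 4, 8, 16, 32 (arrays or
#'   internal tensors).
#' @param stems List with `f_full` / `f_half` from [stem_features()].
#' @param params A [decoder()] module.
#' @param train Use batch statistics.
#' @return Logits bundle: `main` at full resolution plus (when enabled)
#'   `aux8`, `aux16`, `aux32`, each with `num_classes` channels.
#' @export
decoder_forward <- function(pyramid, stems, params, train = TRUE) {
  if (is_tensor(pyramid[[1]])) {
    return(decoder_forward_t(pyramid, stems, params, train))
  }
  ranks <- attr(as_fmap(pyramid[[1]]), "orig_rank")
  pt <- lapply(pyramid, function(x) new_tensor(as_fmap(x)))
  st <- lapply(stems, function(x) new_tensor(as_fmap(x)))
  out <- decoder_forward_t(pt, st, params, train)
  lapply(out, function(t) restore_rank(tval(t), ranks))
}
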