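# Full segmentation model: encoder + low-level stems + decoder, with the
# deep-supervision logits bundle as output.

default_stage_scales <- function() {
  list(c(1L, 2L, 4L, 7L), c(1L, 2L, 4L, 7L), c(1L, 7L), c(1L, 7L))
}

#' Construct the segmentation model
#'
#' @param input_size Input side length, divisible by 32 (default 224).
#' @param in_channels Image channels (1 grayscale, 3 RGB).
#' @param num_classes Segmentation classes including background.
#' @param stage_channels,stage_depths Encoder widths and MSEAU counts.
#' @param stage_scales List of four per-group scale vectors; the default
#'   `[1,2,4,7] / [1,2,4,7] / [1,7] / [1,7]` mixes a global token (s = 1)
#'   with progressively finer grids. Scales are clamped to each stage's
#'   resolution.
#' @param ffn_ratio,isa_groups,isa_gate_reduction,lpu_expand Block settings.
#' @param stem_channels Low-level stem width (default `max(16, C1/2)`).
#' @param aux_heads Attach deep-supervision heads?
#' @param seed Optional RNG seed for weight initialization.
#' @return An `sf_model`.
#' @export
scaleformer <- function(input_size = 224L, in_channels = 1L, num_classes = 2L,
                        stage_channels = c(64L, 128L, 256L, 512L),
                        stage_depths = c(2L, 2L, 2L, 2L),
                        stage_scales = default_stage_scales(),
                        ffn_ratio = 4L, isa_groups = 2L,
                        isa_gate_reduction = 2L, lpu_expand = 4L,
                        stem_channels = NULL, aux_heads = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  config <- list(input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 stage_channels = as.integer(stage_channels),
                 stage_depths = as.integer(stage_depths),
                 stage_scales = lapply(stage_scales, as.integer),
                 ffn_ratio = as.integer(ffn_ratio),
                 isa_groups = as.integer(isa_groups),
                 isa_gate_reduction = as.integer(isa_gate_reduction),
                 lpu_expand = as.integer(lpu_expand),
                 stem_channels = if (is.null(stem_channels)) NULL
                                 else as.integer(stem_channels),
                 aux_heads = isTRUE(aux_heads))
  enc <- encoder(input_size, in_channels, stage_channels, stage_depths,
                 stage_scales, ffn_ratio, isa_groups, isa_gate_reduction,
                 lpu_expand)
  dec <- decoder(stage_channels, num_classes, stem_channels, aux_heads)
  stm <- stems(in_channels, dec$stem_channels)
  structure(list(config = config, encoder = enc, stems = stm, decoder = dec),
            class = c("sf_model", "sf_module"))
}

#' @export
print.sf_model <- function(x, ...) {
  cf <- x$config
  np <- sum(vapply(sf_parameters(x), function(p) length(p$v), numeric(1)))
  cat(sprintf(
    "<sf_model: %dx%d input, %d classes, channels [%s], depths [%s], %s parameters>\n",
    cf$input_size, cf$input_size, cf$num_classes,
    paste(cf$stage_channels, collapse = ","),
    paste(cf$stage_depths, collapse = ","),
    format(np, big.mark = ",")))
  invisible(x)
}

model_forward_t <- function(model, x, train = TRUE) {
  pyramid <- encoder_forward_t(x, model$encoder, train)
  sf <- stem_features_t(x, model$stems, train)
  decoder_forward_t(pyramid, sf, model$decoder, train)
}

#' Forward pass of the full model
#'
#' @param model An [scaleformer()] model.
#' @param images `[H, W, C]` or `[H, W, C, B]` array (or internal tensor),
#'   `H` and `W` divisible by 32.
#' @param train Use batch statistics in normalization layers.
#' @return Logits bundle (`main` plus auxiliary maps when enabled).
#' @export
model_forward <- function(model, images, train = TRUE) {
  if (is_tensor(images)) return(model_forward_t(model, images, train))
  xt <- as_fmap(images)
  rank <- attr(xt, "orig_rank")
  out <- model_forward_t(model, new_tensor(xt), train)
  lapply(out, function(t) restore_rank(tval(t), rank))
}

# Argmax over the class axis of main logits -> integer masks [H, W, B].
logits_to_mask <- function(main) {
  d <- dim(main)
  out <- array(0L, c(d[1], d[2], d[4]))
  for (b in seq_len(d[4])) {
    out[, , b] <- apply(main[, , , b, drop = FALSE][, , , 1, drop = TRUE],
                        c(1, 2), which.max) - 1L
  }
  out
}
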