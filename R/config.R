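#' Model configuration
#'
#' Builds the hyperparameter set that pins down the network architecture.
#' The default values define the reference model: a group-normalized
#' residual encoder with bottleneck blocks (3, 4, 6, 3) whose widths are the
#' classic (64, 256, 512, 1024, 2048) layout scaled by a frozen global
#' multiplier of 0.78125, a dynamic sparse attention (DSA) bottleneck at
#' 1/16 resolution, and a transpose-convolution decoder with skip
#' concatenations at 1/8, 1/4 and 1/2. With `input_size = c(224, 224)` this
#' configuration has about 24.4 M trainable parameters and about 8.6 G
#' multiply-accumulates per forward pass.
#'
#' @param input_size integer vector (H, W); both must be divisible by 16.
#'   The DSA memory units are sized for the bottleneck resolution
#'   (H/16 x W/16), so a model is built for one input size.
#' @param width_scale global channel multiplier; fractions of the default
#'   widths give small models for CPU experimentation (e.g. 0.125).
#' @param stem_width channels of the 7x7 stem convolution.
#' @param stage_widths output channels of the four residual stages.
#' @param block_counts number of bottleneck blocks per stage.
#' @param decoder_widths channels of the four decoder up-stages (the last is
#'   the pre-head width).
#' @param gn_groups maximum group count for group normalization; the actual
#'   count per layer is the largest divisor of the channel count not
#'   exceeding this.
#' @param sparse_ratio Bernoulli keep-probability p of the DSA mask,
#'   in `[0, 1]`. 0.9 retains 90% of the normalized attention entries during
#'   training; at evaluation the mask is replaced by its expectation.
#' @param threshold probability cutoff used to binarize predicted masks.
#' @param out_channels output channels (1 for binary lesion masks).
#' @return a list of class `hds_config`.
#' @export
#' @examples
#' cfg <- hds_config(input_size = c(64, 64), width_scale = 0.125)
#' scaled_widths(cfg)$stages
hds_config <- function(input_size = c(224, 224),
                       width_scale = 1,
                       stem_width = 50,
                       stage_widths = c(200, 400, 800, 1600),
                       block_counts = c(3, 4, 6, 3),
                       decoder_widths = c(256, 128, 64, 32),
                       gn_groups = 32,
                       sparse_ratio = 0.9,
                       threshold = 0.5,
                       out_channels = 1) {
  input_size <- as.integer(input_size)
  if (length(input_size) != 2L || any(input_size %% 16L != 0L))
    stop("input_size must be two integers divisible by 16", call. = FALSE)
  if (width_scale <= 0) stop("width_scale must be positive", call. = FALSE)
  if (sparse_ratio < 0 || sparse_ratio > 1)
    stop("sparse_ratio must lie in [0, 1]", call. = FALSE)
  if (length(stage_widths) != 4L || length(block_counts) != 4L)
    stop("four encoder stages are required", call. = FALSE)
  if (length(decoder_widths) != 4L)
    stop("four decoder widths are required", call. = FALSE)
  if (any(c(stage_widths, decoder_widths, stem_width) < 1))
    stop("all widths must be >= 1", call. = FALSE)
  structure(list(
    input_size = input_size, width_scale = width_scale,
    stem_width = stem_width, stage_widths = stage_widths,
    block_counts = as.integer(block_counts),
    decoder_widths = decoder_widths, gn_groups = as.integer(gn_groups),
    sparse_ratio = sparse_ratio, threshold = threshold,
    out_channels = as.integer(out_channels)
  ), class = "hds_config")
}

round_width <- function(w, mult) as.integer(pmax(mult, mult * round(w / mult)))

#' Effective channel widths after applying the global multiplier
#'
#' Stage widths are rounded to multiples of 4 (the bottleneck mid width is a
#' quarter of the stage width); stem and decoder widths to multiples of 2.
#'
#' @param cfg an `hds_config`.
#' @return list with `stem`, `stages`, `mids`, `decoder`.
#' @export
scaled_widths <- function(cfg) {
  s <- cfg$width_scale
  stages <- round_width(cfg$stage_widths * s, 4L)
  list(stem = round_width(cfg$stem_width * s, 2L),
       stages = stages,
       mids = stages %/% 4L,
       decoder = round_width(cfg$decoder_widths * s, 2L))
}

bottleneck_tokens <- function(cfg) {
  prod(cfg$input_size %/% 16L)
}
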