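#' Sch-net architectural configuration
#'
#' Captures the full hyperparameter set of the architecture: four
#' convolutional blocks of two 3x3 conv layers each (64/128/256/512 filters
#' at width scale 1) with 2x2 max pooling, three average-pooled skip
#' connections of 512 filters each, a CBAM stage on the 2048-channel merged
#' map, a 512-filter 3x3 fusion convolution, and a fully connected head of
#' 512 then 2 neurons. `width_scale` multiplies every filter count (the
#' 2-way output is fixed) so desk-scale models keep the same topology.
#'
#' @param width_scale Positive rational applied to all filter counts.
#' @param cbam_reduction_ratio Channel-attention bottleneck ratio `r`.
#' @param cbam_spatial_kernel Spatial-attention convolution kernel size.
#' @param variant One of `"schnet"` (full model), `"backbone"`,
#'   `"backbone_sc"` (skip connections, no CBAM), `"backbone_cbam"`
#'   (CBAM on the backbone output, no skip connections).
#' @param merge_mode `"concat"` (default; honors the 2048-channel merged
#'   width) or `"add"` (projections summed with the backbone output).
#' @param input_shape Network input geometry, frequency rows x time columns.
#' @param seed Initialization seed recorded in the config.
#' @return A `schnet_config` object with derived fields `block_filters`,
#'   `skip_filters`, `merged_channels`, `fusion_filters`, `head_sizes`.
#' @export
schnet_config <- function(width_scale = 1, cbam_reduction_ratio = 16L,
                          cbam_spatial_kernel = 7L, variant = "schnet",
                          merge_mode = "concat",
                          input_shape = c(128L, 256L), seed = 1L) {
  stopifnot(width_scale > 0)
  variant <- match.arg(variant,
                       c("schnet", "backbone", "backbone_sc", "backbone_cbam"))
  merge_mode <- match.arg(merge_mode, c("concat", "add"))
  block_filters <- as.integer(round(c(64, 128, 256, 512) * width_scale))
  if (any(block_filters < 1)) stop("width_scale too small: empty layer")
  skip_filters <- as.integer(round(512 * width_scale))
  merged_channels <- if (merge_mode == "concat") {
    block_filters[4] + 3L * skip_filters
  } else block_filters[4]
  cfg <- structure(
    list(width_scale = width_scale,
         block_filters = block_filters,
         skip_filters = skip_filters,
         merged_channels = merged_channels,
         cbam_reduction_ratio = as.integer(cbam_reduction_ratio),
         cbam_spatial_kernel = as.integer(cbam_spatial_kernel),
         fusion_filters = as.integer(round(512 * width_scale)),
         head_sizes = c(as.integer(round(512 * width_scale)), 2L),
         variant = variant, merge_mode = merge_mode,
         input_shape = as.integer(input_shape), seed = as.integer(seed)),
    class = "schnet_config")
  validate_schnet_config(cfg)
  cfg
}

validate_schnet_config <- function(cfg) {
  if (cfg$merge_mode == "concat" &&
      cfg$merged_channels != cfg$block_filters[4] + 3L * cfg$skip_filters) {
    stop("config error: merged_channels (", cfg$merged_channels,
         ") must equal block_filters[4] + 3 * skip_filters (",
         cfg$block_filters[4] + 3L * cfg$skip_filters, ")")
  }
  if (any(cfg$input_shape %% 16L != 0L)) {
    stop("config error: input_shape must be divisible by 16 ",
         "(four 2x2 poolings)")
  }
  invisible(cfg)
}

#' @export
print.schnet_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<schnet_config: variant=%s width=%g blocks=(%s) skips=3x%d ",
    "merged=%d fusion=%d head=(%d,%d) input=%dx%d>\n"),
    x$variant, x$width_scale, paste(x$block_filters, collapse = ","),
    x$skip_filters, x$merged_channels, x$fusion_filters,
    x$head_sizes[1], x$head_sizes[2], x$input_shape[1], x$input_shape[2]))
  invisible(x)
}

#' Number of convolutional layers in a configuration
#'
#' Counts 3x3 conv layers: 8 in the backbone, 3 skip projections, and the
#' fusion convolution (the CBAM spatial-attention kernel and the fully
#' connected layers are not convolutions in this inventory).
#'
#' @param cfg A [schnet_config()].
#' @return Integer count (12 for the full model).
#' @export
schnet_conv_layer_count <- function(cfg) {
  8L + (if (cfg$variant %in% c("schnet", "backbone_sc")) 3L else 0L) + 1L
}
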