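# Spatial enhancement encoder: four hierarchical stages, each fusing a
# frequency-dynamic-convolution branch with a three-directional state-space
# branch (concat + pointwise convolution), with a residual connection around
# the stage and strided-convolution downsampling. One independent encoder
# instance serves each modality.

#' Encoder configuration
#'
#' @param in_channels input channels of the volume (1 per modality)
#' @param channels the four stage widths, strictly increasing
#' @param d_state per-stage state sizes of the sequence branch
#' @param d_conv per-stage 1D convolution widths of the sequence branch
#' @param n_kernels dynamic-convolution kernel count N
#' @param directions scan directions of the sequence branch
#' @param use_tdmamba include the state-space branch (FALSE = the
#'   pure-dynamic-convolution ablation)
#' @param seed initialization seed
#' @return plain list consumed by [new_see_encoder()]
#' @export
encoder_config <- function(in_channels = 1L, channels = c(32L, 64L, 128L, 256L),
                           d_state = c(8L, 8L, 16L, 16L),
                           d_conv = c(3L, 3L, 5L, 5L), n_kernels = 4L,
                           directions = c("depth", "height", "width"),
                           use_tdmamba = TRUE, seed = 1L) {
  if (length(channels) != 4L) stop("encoder_config: exactly 4 stages")
  if (any(diff(channels) <= 0)) stop("encoder_config: channels must increase")
  list(in_channels = as.integer(in_channels), channels = as.integer(channels),
       d_state = as.integer(rep_len(d_state, 4L)),
       d_conv = as.integer(rep_len(d_conv, 4L)),
       n_kernels = as.integer(n_kernels), directions = directions,
       use_tdmamba = isTRUE(use_tdmamba), seed = as.integer(seed))
}

#' Instantiate a four-stage encoder
#' @param cfg an [encoder_config()]
#' @return module list of class `see_encoder`
#' @export
new_see_encoder <- function(cfg = encoder_config()) {
  with_seed(cfg$seed, {
    stages <- vector("list", 4L)
    cin <- cfg$in_channels
    for (s in 1:4) {
      cs <- cfg$channels[s]
      st <- list(
        stem_w = init_conv_w(cs, cin, 3L), stem_b = init_zeros(cs),
        stem_g = ad_param(rep(1, cs)), stem_be = init_zeros(cs),
        fuse_g = ad_param(rep(1, cs)), fuse_be = init_zeros(cs),
        fd = fdconv_config(cs, cs, 3L, cfg$n_kernels,
                           seed = sample.int(1e6, 1)),
        td = if (cfg$use_tdmamba)
          new_td_mamba(cs, cfg$d_state[s], cfg$d_conv[s], cfg$directions,
                       seed = sample.int(1e6, 1)) else NULL,
        fuse_w = init_conv_w(cs, if (cfg$use_tdmamba) 2L * cs else cs, 1L),
        fuse_b = init_zeros(cs),
        down_w = init_conv_w(cs, cs, 3L), down_b = init_zeros(cs)
      )
      stages[[s]] <- st
      cin <- cs
    }
    structure(list(cfg = cfg, stages = stages), class = "see_encoder")
  })
}

see_stage_node <- function(st, x) {
  d <- dim_of(ad_value(x))
  if (any(d[3:5] < 2L))
    stop("see_stage: spatial dimension < 2 before downsampling")
  stem <- ad_relu(ad_instnorm_ch(ad_conv3d(x, st$stem_w, st$stem_b),
                                 st$stem_g, st$stem_be))
  fd <- fdconv_node(st$fd, stem)
  branches <- if (!is.null(st$td))
    ad_concat(list(fd, td_mamba_node(st$td, stem)), 2L) else fd
  fused <- ad_add(ad_instnorm_ch(ad_conv3d(branches, st$fuse_w, st$fuse_b),
                                 st$fuse_g, st$fuse_be), stem)
  skip <- ad_relu(fused)
  down <- ad_relu(ad_conv3d(skip, st$down_w, st$down_b, stride = 2L))
  list(skip = skip, down = down)
}

#' Run one encoder stage
#'
#' Stem convolution, the two branches, concat + pointwise fusion with a
#' residual, then strided x2 downsampling; output spatial dims are
#' ceil(input / 2) and channels become the stage width.
#'
#' @param X (B,C,D,H,W) feature map matching the stage input channels
#' @param encoder a [new_see_encoder()]
#' @param stage stage index 1..4
#' @return list with `skip` (pre-downsample) and `out` (downsampled) arrays
#' @export
see_stage <- function(X, encoder, stage = 1L) {
  stopifnot(inherits(encoder, "see_encoder"))
  X <- as_feature_map(X)
  r <- see_stage_node(encoder$stages[[stage]], ad_const(X))
  list(skip = ad_value(r$skip), out = ad_value(r$down))
}

see_forward_node <- function(encoder, x) {
  skips <- vector("list", 4L)
  cur <- x
  for (s in 1:4) {
    r <- see_stage_node(encoder$stages[[s]], cur)
    skips[[s]] <- r$skip
    cur <- r$down
  }
  list(skips = skips, bottleneck = cur)
}

#' Full encoder forward pass
#'
#' @param X single-modality (B,1,D,H,W) feature map
#' @param encoder a [new_see_encoder()]
#' @return list of 4 `skips` (stage-resolution features) and the
#'   `bottleneck` at 1/16 resolution
#' @export
see_forward <- function(X, encoder) {
  stopifnot(inherits(encoder, "see_encoder"))
  X <- as_feature_map(X)
  if (dim(X)[2] != encoder$cfg$in_channels)
    stop(sprintf("see_forward: expected %d-channel input, got %d",
                 encoder$cfg$in_channels, dim(X)[2]))
  r <- see_forward_node(encoder, ad_const(X))
  list(skips = lapply(r$skips, ad_value), bottleneck = ad_value(r$bottleneck))
}
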