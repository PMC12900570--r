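# Position-aware attention fusion at the bottleneck.
#
# Per modality, features are globally enhanced by a three-directional
# state-space block ("rotational" scanning) followed by a channel layer norm
# gated with sigmoid(W_g F_rot). The two enhanced maps are fused channel by
# channel (each channel pair compressed to one channel by a per-channel
# 1x1x1 convolution), and an enhanced position attention map - built from
# axis-pooled positional descriptors - rescales the fused map voxelwise.

#' Instantiate a position-aware attention fusion module
#'
#' @param channels bottleneck channels C
#' @param d_state state size of the rotational scan branches
#' @param n_modalities 2 for dual-modality input, 1 to skip the cross-modal
#'   compression
#' @param seed initialization seed
#' @return module list of class `paaf`
#' @export
new_paaf <- function(channels, d_state = 16L, n_modalities = 2L, seed = 1L) {
  C <- as.integer(channels)
  with_seed(seed, {
    mk_rot <- function() list(
      td = new_td_mamba(C, d_state, 3L, seed = sample.int(1e6, 1)),
      gamma = ad_param(rep(1, C)), beta = init_zeros(C),
      gate_w = init_conv_w(C, C, 1L)
    )
    structure(list(
      channels = C, n_modalities = as.integer(n_modalities),
      rot = lapply(seq_len(n_modalities), function(i) mk_rot()),
      fuse_w1 = ad_param(rep(0.5, C)), fuse_w2 = ad_param(rep(0.5, C)),
      fuse_b = init_zeros(C),
      epa_vd = init_linear_w(C, 1L), epa_vh = init_linear_w(C, 1L),
      epa_vw = init_linear_w(C, 1L), epa_b = init_zeros(1L)
    ), class = "paaf")
  })
}

rotational_enhance_node <- function(rot, f) {
  frot <- td_mamba_node(rot$td, f)
  gate <- ad_sigmoid(ad_conv3d(frot, rot$gate_w))
  ad_mul(ad_layernorm_ch(frot, rot$gamma, rot$beta), gate)
}

channel_fuse_node <- function(m, f1, f2) {
  ad_add_ch(ad_add(ad_scale_ch(f1, m$fuse_w1), ad_scale_ch(f2, m$fuse_w2)),
            m$fuse_b)
}

epa_node <- function(m, f) {
  d <- dim_of(ad_value(f))
  score <- function(desc, v) {       # desc (B,C,L) -> (B,L)
    L <- dim_of(ad_value(desc))[3]
    flat <- ad_reshape(ad_aperm(desc, c(1, 3, 2)), c(d[1] * L, d[2]))
    ad_reshape(ad_linear(flat, v), c(d[1], L))
  }
  sd_ <- score(ad_mean_trailing(f, 3L), m$epa_vd)
  sh <- score(ad_mean_trailing(ad_aperm(f, c(1, 2, 4, 3, 5)), 3L), m$epa_vh)
  sw <- score(ad_mean_trailing(ad_aperm(f, c(1, 2, 5, 3, 4)), 3L), m$epa_vw)
  wmap <- ad_sigmoid(ad_add(ad_outer_sum3(sd_, sh, sw), m$epa_b))
  list(out = ad_mul(f, ad_expand_ch(wmap, d[2])), weights = wmap)
}

paaf_node <- function(m, f1, f2 = NULL) {
  e1 <- rotational_enhance_node(m$rot[[1]], f1)
  fused <- if (is.null(f2)) e1
  else channel_fuse_node(m, e1, rotational_enhance_node(m$rot[[2]], f2))
  epa_node(m, fused)$out
}

#' Rotationally enhanced bottleneck features
#'
#' LayerNorm(F_rot) * sigmoid(W_g F_rot), where F_rot is the fusion of three
#' directional state-space scans of F and W_g acts on the channel axis per
#' voxel.
#'
#' @param F_ (B,C,D,H,W) bottleneck features of one encoder branch
#' @param module a [new_paaf()] (its first rotational branch is used), or
#'   NULL to create one seeded from `seed`
#' @param seed seed when `module` is NULL
#' @return array of the same shape
#' @export
rotational_enhance <- function(F_, module = NULL, seed = 1L) {
  F_ <- as_feature_map(F_)
  if (is.null(module)) module <- new_paaf(dim(F_)[2], seed = seed)
  ad_value(rotational_enhance_node(module$rot[[1]], ad_const(F_)))
}

#' Channel-wise cross-modal fusion
#'
#' For every channel index c the pair (F1[c], F2[c]) is compressed to a
#' single channel by a per-channel pointwise convolution; the recombined
#' channels form the cross-modal map.
#'
#' @param F1,F2 equal-shape (B,C,D,H,W) maps
#' @param module optional [new_paaf()]; defaults to averaging weights
#'   (0.5, 0.5) with zero bias
#' @return fused (B,C,D,H,W) array
#' @export
channel_decompose_fuse <- function(F1, F2, module = NULL) {
  F1 <- as_feature_map(F1); F2 <- as_feature_map(F2)
  if (!identical(dim(F1), dim(F2)))
    stop("channel_decompose_fuse: shape mismatch")
  if (is.null(module)) {
    C <- dim(F1)[2]
    module <- list(fuse_w1 = ad_const(rep(0.5, C)),
                   fuse_w2 = ad_const(rep(0.5, C)),
                   fuse_b = ad_const(rep(0, C)))
  }
  ad_value(channel_fuse_node(module, ad_const(F1), ad_const(F2)))
}

#' Enhanced position attention
#'
#' Pools the map along each axis into positional descriptors, scores each
#' position, combines the three axis scores additively and squashes through
#' a sigmoid into a spatial weight map in (0,1) that multiplies the input.
#'
#' @param F_ (B,C,D,H,W) cross-modal map
#' @param module optional [new_paaf()]
#' @param seed seed when `module` is NULL
#' @param return_weights also return the (B,1,D,H,W) weight map
#' @return weighted array, or list(out, weights)
#' @export
enhanced_position_attention <- function(F_, module = NULL, seed = 1L,
                                        return_weights = FALSE) {
  F_ <- as_feature_map(F_)
  if (is.null(module)) module <- new_paaf(dim(F_)[2], seed = seed)
  r <- epa_node(module, ad_const(F_))
  if (return_weights) list(out = ad_value(r$out), weights = ad_value(r$weights))
  else ad_value(r$out)
}
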