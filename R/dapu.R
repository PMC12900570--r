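# Depth-aware progressive upsampling decoder stage.
#
# Four cooperating parts per stage: (1) depth attention - slice descriptors
# from mean pooling over the in-plane axes, squeezed through a channel
# bottleneck and a sigmoid into per-(channel, slice) weights broadcast over
# H and W; (2) a multi-scale dilated-convolution boundary branch computed at
# the input resolution; (3) progressive x2 trilinear upsampling followed by
# convolution; (4) fusion with the skip feature (concat + pointwise) and a
# structure-preserving convolution with a residual connection.

#' Instantiate one decoder stage
#'
#' @param c_in input channels (previous decoder stage / bottleneck)
#' @param c_skip channels of the skip feature at 2x resolution
#' @param c_out output channels
#' @param dilations boundary-branch dilation rates (default 1, 2, 4)
#' @param reduction channel bottleneck ratio of the depth attention
#' @param seed initialization seed
#' @return module list of class `dapu`
#' @export
new_dapu <- function(c_in, c_skip, c_out, dilations = c(1L, 2L, 4L),
                     reduction = 2L, seed = 1L) {
  if (any(dilations <= 0) || anyDuplicated(dilations))
    stop("new_dapu: dilation rates must be positive and distinct")
  cin <- as.integer(c_in); cout <- as.integer(c_out)
  hid <- max(1L, cin %/% as.integer(reduction))
  cb <- max(1L, cout %/% 2L)
  with_seed(seed, {
    structure(list(
      c_in = cin, c_skip = as.integer(c_skip), c_out = cout,
      dilations = as.integer(dilations), c_bnd = cb,
      da_w1 = init_linear_w(cin, hid),
      da_b1 = ad_param(array(0.1, hid)),   # alive at init (see fdconv.R)
      da_w2 = init_linear_w(hid, cin), da_b2 = init_zeros(cin),
      bnd_w = lapply(dilations, function(dl) init_conv_w(cb, cin, 3L)),
      bnd_b = lapply(dilations, function(dl) init_zeros(cb)),
      bnd_fuse_w = init_conv_w(cb, length(dilations) * cb, 1L),
      bnd_fuse_b = init_zeros(cb),
      up_w = init_conv_w(cout, cin, 3L), up_b = init_zeros(cout),
      up_g = ad_param(rep(1, cout)), up_be = init_zeros(cout),
      fuse_w = init_conv_w(cout, cout + cb + as.integer(c_skip), 1L),
      fuse_b = init_zeros(cout),
      fuse_g = ad_param(rep(1, cout)), fuse_be = init_zeros(cout),
      struct_w = init_conv_w(cout, cout, 3L), struct_b = init_zeros(cout)
    ), class = "dapu")
  })
}

depth_pool_node <- function(x) ad_mean_trailing(x, 3L)   # (B,C,D)

depth_attention_node <- function(m, fdepth) {
  d <- dim_of(ad_value(fdepth))
  flat <- ad_reshape(ad_aperm(fdepth, c(1, 3, 2)), c(d[1] * d[3], d[2]))
  h <- ad_relu(ad_linear(flat, m$da_w1, m$da_b1))
  a <- ad_sigmoid(ad_linear(h, m$da_w2, m$da_b2))
  ad_aperm(ad_reshape(a, c(d[1], d[3], d[2])), c(1, 3, 2)) # (B,C,D)
}

depth_enhance_node <- function(x, a_d) ad_mul(x, a_d)     # head broadcast

boundary_branch_node <- function(m, x) {
  outs <- lapply(seq_along(m$dilations), function(i)
    ad_conv3d(x, m$bnd_w[[i]], m$bnd_b[[i]], dilation = m$dilations[i]))
  cat_ <- if (length(outs) == 1L) outs[[1]] else ad_concat(outs, 2L)
  ad_leakyrelu(ad_conv3d(cat_, m$bnd_fuse_w, m$bnd_fuse_b))
}

dapu_node <- function(m, x, skip) {
  xd <- dim_of(ad_value(x)); sd_ <- dim_of(ad_value(skip))
  if (!identical(sd_[3:5], 2L * xd[3:5]))
    stop("dapu_forward: skip spatial dims must be exactly 2x the input's")
  a_d <- depth_attention_node(m, depth_pool_node(x))
  xe <- depth_enhance_node(x, a_d)
  up <- ad_relu(ad_instnorm_ch(ad_conv3d(ad_upsample2(xe), m$up_w, m$up_b),
                               m$up_g, m$up_be))
  bnd <- ad_upsample2(boundary_branch_node(m, x))
  fused <- ad_relu(ad_instnorm_ch(
    ad_conv3d(ad_concat(list(up, bnd, skip), 2L), m$fuse_w, m$fuse_b),
    m$fuse_g, m$fuse_be))
  ad_relu(ad_add(ad_conv3d(fused, m$struct_w, m$struct_b), fused))
}

#' Per-slice mean pooling over the in-plane axes
#'
#' @param X (B,C,D,H,W) feature map
#' @return (B,C,D) array of slice descriptors
#' @export
depth_pool <- function(X) {
  X <- as_feature_map(X)
  ad_value(depth_pool_node(ad_const(X)))
}

#' Slice-importance attention from depth descriptors
#'
#' A_d = sigmoid(W2 ReLU(W1 F_depth + b1) + b2), applied per (batch, slice)
#' over the channel axis; every weight lies in (0,1).
#'
#' @param F_depth (B,C,D) array from [depth_pool()]
#' @param module a [new_dapu()] or a list with fields da_w1, da_b1, da_w2,
#'   da_b2; NULL creates a seeded default
#' @param seed seed when `module` is NULL
#' @return (B,C,D) array in (0,1)
#' @export
depth_attention <- function(F_depth, module = NULL, seed = 1L) {
  d <- dim(F_depth)
  if (length(d) != 3L) stop("depth_attention: expected a (B,C,D) array")
  if (is.null(module)) module <- new_dapu(d[2], d[2], d[2], seed = seed)
  ad_value(depth_attention_node(module, ad_const(F_depth)))
}

#' Broadcast slice weights over the in-plane axes
#'
#' @param X (B,C,D,H,W) feature map
#' @param A_d (B,C,D) attention weights
#' @return X * A_d with A_d broadcast along H and W
#' @export
depth_enhance <- function(X, A_d) {
  X <- as_feature_map(X)
  if (!identical(dim(X)[1:3], dim(A_d)))
    stop("depth_enhance: attention shape must match (B,C,D)")
  ad_value(depth_enhance_node(ad_const(X), ad_const(A_d)))
}

#' Multi-scale dilated boundary branch
#'
#' Parallel 3x3x3 convolutions at the configured dilation rates,
#' concatenated and fused by a pointwise convolution; spatial shape is
#' preserved.
#'
#' @param X (B,C,D,H,W) feature map
#' @param module a [new_dapu()] with matching input channels, or NULL
#' @param seed seed when `module` is NULL
#' @return (B, c_bnd, D, H, W) array
#' @export
boundary_branch <- function(X, module = NULL, seed = 1L) {
  X <- as_feature_map(X)
  if (is.null(module))
    module <- new_dapu(dim(X)[2], dim(X)[2], dim(X)[2], seed = seed)
  ad_value(boundary_branch_node(module, ad_const(X)))
}

#' One decoder stage forward pass
#'
#' @param X (B,c_in,D,H,W) decoder input
#' @param skip (B,c_skip,2D,2H,2W) encoder skip feature
#' @param module a [new_dapu()], or NULL for a seeded default matching the
#'   input shapes
#' @param seed seed when `module` is NULL
#' @return (B,c_out,2D,2H,2W) array
#' @export
dapu_forward <- function(X, skip, module = NULL, seed = 1L) {
  X <- as_feature_map(X); skip <- as_feature_map(skip)
  if (is.null(module))
    module <- new_dapu(dim(X)[2], dim(skip)[2], dim(skip)[2], seed = seed)
  ad_value(dapu_node(module, ad_const(X), ad_const(skip)))
}
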