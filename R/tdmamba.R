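# Three-directional Mamba-style block.
#
# Each scan direction owns an independent selective state-space branch:
# a depthwise 1D convolution along the sequence, SiLU gate-in, then the
# zero-order-hold discretized diagonal recurrence with input-dependent
# Delta, B, C projections (the defining "selective" mechanism), plus a
# per-channel skip. Branch outputs are concatenated on the channel axis and
# fused back to C channels by a pointwise convolution.

new_ssm_branch <- function(C, d_state, d_conv, dt_init = 0.1) {
  list(
    conv_w = ad_param(glorot(c(d_conv, C), d_conv, 1)),
    conv_b = init_zeros(C),
    w_dt = ad_param(glorot(c(C, C), C, C) * 0.1),
    b_dt = ad_param(rep(log(exp(dt_init) - 1), C)),
    w_B = ad_param(glorot(c(C, d_state), C, d_state)),
    w_C = ad_param(glorot(c(C, d_state), C, d_state)),
    A_log = ad_param(log(matrix(rep(seq_len(d_state), each = C), C, d_state))),
    D_skip = ad_param(rep(1, C))
  )
}

ssm_branch_forward <- function(br, s) {
  # s: (M,T,C) node
  d <- dim_of(ad_value(s))
  M <- d[1]; T_ <- d[2]; C <- d[3]
  u <- ad_silu(ad_conv1d_dw(s, br$conv_w, br$conv_b))
  u2 <- ad_reshape(u, c(M * T_, C))
  delta <- ad_reshape(ad_softplus(ad_linear(u2, br$w_dt, br$b_dt)),
                      c(M, T_, C))
  Bm <- ad_reshape(ad_linear(u2, br$w_B), c(M, T_, dim_of(ad_value(br$w_B))[2]))
  Cm <- ad_reshape(ad_linear(u2, br$w_C), c(M, T_, dim_of(ad_value(br$w_C))[2]))
  A <- ad_neg(ad_exp(br$A_log))
  y <- ad_scan(u, delta, A, Bm, Cm)
  ad_add(y, ad_scale_last(u, br$D_skip))
}

#' Create a three-directional state-space block
#'
#' @param channels feature channels C
#' @param d_state per-channel state size (default 8)
#' @param d_conv depthwise 1D convolution width along each scan (default 3)
#' @param directions subset of c("depth","height","width"); the
#'   sagittal-only ablation uses "depth"
#' @param seed initialization seed
#' @return module list usable with [td_mamba_forward()]
#' @export
new_td_mamba <- function(channels, d_state = 8L, d_conv = 3L,
                         directions = c("depth", "height", "width"),
                         seed = 1L) {
  if (length(directions) == 0L) stop("new_td_mamba: empty direction list")
  directions <- match.arg(directions, c("depth", "height", "width"),
                          several.ok = TRUE)
  with_seed(seed, {
    branches <- lapply(directions, function(d)
      new_ssm_branch(channels, d_state, d_conv))
    names(branches) <- directions
    nfuse <- length(directions) * channels
    list(channels = channels, directions = directions, branches = branches,
         fuse_w = init_conv_w(channels, nfuse, 1L),
         fuse_b = init_zeros(channels))
  })
}

td_mamba_node <- function(block, x) {
  xd <- dim_of(ad_value(x))
  outs <- lapply(block$directions, function(axis) {
    s <- ad_dir_flatten(x, axis)
    y <- ssm_branch_forward(block$branches[[axis]], s)
    ad_dir_unflatten(y, xd, axis)
  })
  cat_ <- if (length(outs) == 1L) outs[[1]] else ad_concat(outs, 2L)
  ad_conv3d(cat_, block$fuse_w, block$fuse_b)
}

#' Forward pass of the three-directional state-space block
#'
#' Output shape equals input shape. With `directions = "depth"` the block is
#' the sagittal-only ablation variant.
#'
#' @param X (B,C,D,H,W) feature map
#' @param directions scan directions (default all three)
#' @param block optional module from [new_td_mamba()]; created (seeded) when
#'   missing
#' @param seed seed used when `block` is NULL
#' @return array of the same shape as `X`
#' @export
td_mamba_forward <- function(X, directions = c("depth", "height", "width"),
                             block = NULL, seed = 1L) {
  X <- as_feature_map(X)
  if (length(directions) == 0L) stop("td_mamba_forward: empty direction list")
  if (is.null(block))
    block <- new_td_mamba(dim(X)[2], directions = directions, seed = seed)
  ad_value(td_mamba_node(block, ad_const(X)))
}
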