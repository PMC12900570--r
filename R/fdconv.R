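# Frequency dynamic convolution.
#
# Three cooperating parts: (1) a frequency-modulation branch — a depthwise
# convolution whose sigmoid output gates each voxel of each channel into
# (0,1), letting the layer emphasize or suppress frequency components per
# location; (2) an attention branch — global average pooling followed by a
# two-layer bottleneck producing a softmax distribution alpha over N
# parallel kernels; (3) the fused convolution Y = sum_i alpha_i (W_i * X_mod)
# + b. Because alpha is per sample, the N kernels are mixed in weight space
# first and a single convolution is run.

#' Configuration for a frequency dynamic convolution block
#'
#' @param in_channels,out_channels channel counts
#' @param kernel_size odd isotropic kernel size (default 3)
#' @param n_kernels number N of parallel kernels (default 4)
#' @param reduction bottleneck ratio of the attention branch (default 4)
#' @param seed initialization seed
#' @return module list of class `fdconv`
#' @export
fdconv_config <- function(in_channels, out_channels, kernel_size = 3L,
                          n_kernels = 4L, reduction = 4L, seed = 1L) {
  if (n_kernels < 1L) stop("fdconv_config: n_kernels must be >= 1")
  if (kernel_size %% 2L != 1L) stop("fdconv_config: kernel_size must be odd")
  if (reduction < 1L) stop("fdconv_config: reduction must be >= 1")
  k <- as.integer(kernel_size)
  hid <- max(1L, as.integer(in_channels) %/% as.integer(reduction))
  with_seed(seed, {
    structure(list(
      in_channels = as.integer(in_channels),
      out_channels = as.integer(out_channels),
      kernel_size = k, n_kernels = as.integer(n_kernels),
      # N kernel banks stacked on the first axis: (N*Cout, Cin, k,k,k)
      w = ad_param(glorot(c(n_kernels * out_channels, in_channels, k, k, k),
                          in_channels * k^3, out_channels)),
      b = init_zeros(out_channels),
      dw_w = ad_param(glorot(c(in_channels, 1L, k, k, k), k^3, k^3)),
      dw_b = init_zeros(in_channels),
      att_w1 = init_linear_w(in_channels, hid),
      # small positive bias keeps the narrow rectifier bottleneck alive
      att_b1 = ad_param(array(0.1, hid)),
      att_w2 = init_linear_w(hid, n_kernels),
      att_b2 = init_zeros(n_kernels)
    ), class = "fdconv")
  })
}

freq_modulate_node <- function(x, dw_w, dw_b) {
  gate <- ad_sigmoid(ad_conv3d(x, dw_w, dw_b,
                               groups = dim_of(ad_value(dw_w))[1]))
  ad_mul(x, gate)
}

attention_node <- function(cfg, x) {
  pooled <- ad_mean_trailing(x, 2L)            # (B, C)
  h <- ad_leakyrelu(ad_linear(pooled, cfg$att_w1, cfg$att_b1))
  logits <- ad_linear(h, cfg$att_w2, cfg$att_b2)
  ad_softmax_rows(logits)                      # (B, N), rows sum to 1
}

fdconv_node <- function(cfg, x, modulate = TRUE, alpha = NULL) {
  B <- dim_of(ad_value(x))[1]
  xm <- if (modulate) freq_modulate_node(x, cfg$dw_w, cfg$dw_b) else x
  if (is.null(alpha)) alpha <- attention_node(cfg, x)
  N <- cfg$n_kernels; Co <- cfg$out_channels
  wd <- dim_of(ad_value(cfg$w))
  K <- prod(wd[-1])
  # first axis stores kernel banks with the output channel varying fastest:
  # row index = o + Co*(i-1); regroup to (N, Co*K) for the alpha mix
  wbank <- ad_reshape(ad_aperm(ad_reshape(cfg$w, c(Co, N, K)), c(2, 1, 3)),
                      c(N, Co * K))
  outs <- vector("list", B)
  for (b in seq_len(B)) {
    ab <- ad_slice_rows(alpha, b)              # (1, N)
    wmix <- ad_reshape(ad_matmul(ab, wbank), c(Co, wd[-1]))
    xb <- if (B == 1L) xm else ad_slice_batch(xm, b)
    outs[[b]] <- ad_conv3d(xb, wmix, cfg$b)
  }
  if (B == 1L) outs[[1]] else ad_concat(outs, 1L)
}

#' Frequency-selective modulation (gating) of a feature map
#'
#' Computes X * sigmoid(Conv_dw(X)) with a per-channel depthwise kernel;
#' every modulation weight lies strictly inside (0, 1).
#'
#' @param X (B,C,D,H,W) feature map
#' @param dw_kernel depthwise kernel, (C,1,k,k,k) array
#' @param dw_bias per-channel bias (default zeros)
#' @return array of the same shape
#' @export
frequency_modulate <- function(X, dw_kernel, dw_bias = NULL) {
  X <- as_feature_map(X)
  kd <- dim_of(dw_kernel)
  if (length(kd) != 5L || kd[1] != dim(X)[2] || kd[2] != 1L)
    stop("frequency_modulate: depthwise kernel must be (C,1,k,k,k) with one filter per channel")
  if (is.null(dw_bias)) dw_bias <- rep(0, kd[1])
  ad_value(freq_modulate_node(ad_const(X), ad_const(dw_kernel),
                              ad_const(dw_bias)))
}

#' Per-sample kernel attention weights
#'
#' Global average pooling, two pointwise layers with a rectifier between,
#' softmax normalization: each row is a probability vector over the N
#' kernels.
#'
#' @param X (B,C,D,H,W) feature map
#' @param cfg an [fdconv_config()]
#' @return (B, N) matrix with nonnegative rows summing to 1
#' @export
attention_weights <- function(X, cfg) {
  X <- as_feature_map(X)
  if (dim(X)[2] != cfg$in_channels) stop("attention_weights: channel mismatch")
  ad_value(attention_node(cfg, ad_const(X)))
}

#' Frequency dynamic convolution forward pass
#'
#' Y = sum_i alpha_i (W_i * X_mod) + b with same padding and stride 1.
#'
#' @param X (B,C_in,D,H,W) feature map
#' @param cfg an [fdconv_config()]
#' @param modulate apply the frequency-modulation gate (default TRUE)
#' @param alpha optional fixed (B,N) attention weights overriding the
#'   attention branch
#' @return (B,C_out,D,H,W) array
#' @export
fdconv_forward <- function(X, cfg, modulate = TRUE, alpha = NULL) {
  X <- as_feature_map(X)
  if (dim(X)[2] != cfg$in_channels)
    stop(sprintf("fdconv_forward: input has %d channels, expected %d",
                 dim(X)[2], cfg$in_channels))
  if (!is.null(alpha)) alpha <- ad_const(matrix(alpha, nrow = dim(X)[1]))
  ad_value(fdconv_node(cfg, ad_const(X), modulate, alpha))
}
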