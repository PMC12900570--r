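# The hybrid frequency-domain-aware Tversky loss family.
#
# L_hybrid = lambda * L_Tversky(all classes) + (1 - lambda) * L_FD
# L_FD     = L_Tversky(vertebra only) + omega * L_freq
# L_freq   = mean_i | grad(p_vert)_i - grad(g_vert)_i |
#
# where the per-class Tversky term is w_c * (1 - TI_c) inside a sum
# normalized by sum(w_c), TI_c = (TP + eps) / (TP + alpha*FP + beta*FN + eps)
# with soft counts TP = sum p*g, FP = sum p*(1-g), FN = sum (1-p)*g, and the
# voxelwise gradient magnitude is the average of |central difference| along
# the depth, height and width axes.
#
# All losses are written on the autodiff tape: the exported functions take
# plain arrays and return numbers, while the internal *_node variants accept
# tape nodes and drive training. `loss_gradient()` exposes d loss / d p.

#' Loss parameter bundle
#'
#' Defaults follow the tuned configuration: alpha = 0.25, beta = 0.75 with
#' the disc beta raised by 20% (0.9), class weights 0.2 / 1.2 / 1.6 for
#' background / vertebra / disc, smoothing eps = 1e-6, frequency weight
#' omega = 0.07 and hybrid ratio lambda = 0.55.
#'
#' @param alpha,beta base false-positive / false-negative weights
#' @param disc_beta_uplift multiplicative raise of the disc beta
#' @param class_weights length-3 positive weights (background, vertebra, disc)
#' @param eps smoothing term
#' @param omega frequency-domain loss weight (>= 0)
#' @param lambda hybrid ratio in [0, 1]
#' @return list of class `loss_config`
#' @export
loss_config <- function(alpha = 0.25, beta = 0.75, disc_beta_uplift = 1.2,
                        class_weights = c(0.2, 1.2, 1.6), eps = 1e-6,
                        omega = 0.07, lambda = 0.55) {
  if (lambda < 0 || lambda > 1) stop("loss_config: lambda must lie in [0, 1]")
  if (omega < 0) stop("loss_config: omega must be >= 0")
  if (eps <= 0) stop("loss_config: eps must be > 0")
  if (any(class_weights <= 0)) stop("loss_config: class weights must be > 0")
  n <- length(class_weights)
  alphas <- rep(alpha, n)
  betas <- rep(beta, n)
  if (n >= 3) betas[3] <- beta * disc_beta_uplift  # disc class
  structure(list(alpha = alphas, beta = betas, w = class_weights, eps = eps,
                 omega = omega, lambda = lambda), class = "loss_config")
}

check_prob_target <- function(p, g, tol = 1e-4) {
  pv <- ad_value(p); gv <- ad_value(g)
  if (!identical(dim_of(pv), dim_of(gv)))
    stop("prediction and target shapes differ")
  d <- dim_of(pv)
  if (length(d) != 5L) stop("expected (batch, class, D, H, W) arrays")
  csum <- rowSums(aperm(pv, c(1, 3, 4, 5, 2)), dims = 4)
  if (max(abs(csum - 1)) > tol)
    stop("class probabilities must sum to 1 per voxel")
  invisible(TRUE)
}

tversky_node <- function(p, g, cfg, classes = NULL) {
  p <- ad_const(p)
  gv <- ad_value(g)
  nC <- dim_of(p$value)[2]
  if (is.null(classes)) classes <- seq_len(nC)
  total <- NULL
  wsum <- 0
  for (ci in classes) {
    pc <- ad_slice_ch(p, ci)
    gc <- gv[, ci, , , , drop = FALSE]
    tp <- ad_sum(ad_mul(pc, gc))
    fp <- ad_sum(ad_mul(pc, 1 - gc))
    fn <- ad_sub(sum(gc), tp)                 # sum((1-p)*g) = sum(g) - TP
    num <- ad_add(tp, cfg$eps)
    den <- ad_add(ad_add(tp, ad_mul(fp, cfg$alpha[ci])),
                  ad_add(ad_mul(fn, cfg$beta[ci]), cfg$eps))
    ti <- ad_div(num, den)
    term <- ad_mul(ad_sub(1, ti), cfg$w[ci])
    total <- if (is.null(total)) term else ad_add(total, term)
    wsum <- wsum + cfg$w[ci]
  }
  ad_div(total, wsum)
}

grad_mag_node <- function(x) {
  gsum <- ad_add(ad_add(ad_abs(ad_diff_axis(x, 3L)),
                        ad_abs(ad_diff_axis(x, 4L))),
                 ad_abs(ad_diff_axis(x, 5L)))
  ad_mul(gsum, 1 / 3)
}

freq_gradient_node <- function(p_vert, g_vert) {
  ad_mean(ad_abs(ad_sub(grad_mag_node(ad_const(p_vert)),
                        grad_mag_node(ad_const(g_vert)))))
}

fd_tversky_node <- function(p, g, cfg, vert_class = 2L) {
  lt <- tversky_node(p, g, cfg, classes = vert_class)
  pv <- ad_slice_ch(ad_const(p), vert_class)
  gv <- ad_value(g)[, vert_class, , , , drop = FALSE]
  ad_add(lt, ad_mul(freq_gradient_node(pv, gv), cfg$omega))
}

hfd_tversky_node <- function(p, g, cfg, vert_class = 2L) {
  ad_add(ad_mul(tversky_node(p, g, cfg), cfg$lambda),
         ad_mul(fd_tversky_node(p, g, cfg, vert_class), 1 - cfg$lambda))
}

#' Weighted multi-class soft Tversky loss
#'
#' @param p (batch, class, D, H, W) probabilities summing to 1 per voxel
#' @param g matching one-hot target array
#' @param cfg a [loss_config()]
#' @param classes integer subset of class indices to include (default all)
#' @return scalar loss in [0, 1)
#' @export
tversky_loss <- function(p, g, cfg = loss_config(), classes = NULL) {
  check_prob_target(p, g)
  ad_value(tversky_node(p, g, cfg, classes))
}

#' Frequency-domain gradient loss on the vertebra channel
#'
#' Mean absolute difference between the voxelwise gradient magnitudes of the
#' predicted and true vertebra maps. Gradients use central differences in the
#' interior and one-sided differences at volume borders, averaged over the
#' three axes.
#'
#' @param p_vert,g_vert (batch, 1, D, H, W) vertebra probability / target maps
#' @return scalar >= 0
#' @export
freq_gradient_loss <- function(p_vert, g_vert) {
  if (!identical(dim_of(p_vert), dim_of(g_vert)))
    stop("freq_gradient_loss: shapes differ")
  ad_value(freq_gradient_node(p_vert, g_vert))
}

#' Frequency-domain-aware Tversky loss (vertebra Tversky + omega * gradient)
#' @inheritParams tversky_loss
#' @param vert_class channel index of the vertebra class (default 2)
#' @export
fd_tversky_loss <- function(p, g, cfg = loss_config(), vert_class = 2L) {
  check_prob_target(p, g)
  ad_value(fd_tversky_node(p, g, cfg, vert_class))
}

#' Hybrid frequency-domain-aware Tversky loss
#'
#' \code{lambda * tversky_loss(all classes) + (1 - lambda) * fd_tversky_loss}.
#'
#' @inheritParams fd_tversky_loss
#' @export
hfd_tversky_loss <- function(p, g, cfg = loss_config(), vert_class = 2L) {
  check_prob_target(p, g)
  ad_value(hfd_tversky_node(p, g, cfg, vert_class))
}

#' Gradient of a loss with respect to the predicted probabilities
#'
#' Differentiates the chosen loss through the autodiff tape; mainly used for
#' gradient checking and for demonstrating differentiability.
#'
#' @inheritParams hfd_tversky_loss
#' @param which one of "tversky", "fd", "hfd"
#' @return array shaped like `p`
#' @export
loss_gradient <- function(p, g, cfg = loss_config(),
                          which = c("hfd", "tversky", "fd"),
                          vert_class = 2L) {
  which <- match.arg(which)
  node <- ad_param(p)
  loss <- switch(which,
                 tversky = tversky_node(node, g, cfg),
                 fd = fd_tversky_node(node, g, cfg, vert_class),
                 hfd = hfd_tversky_node(node, g, cfg, vert_class))
  ad_backward(loss)
  node$grad
}

#' One-hot encode an integer label array
#' @param labels (D,H,W) or (B,D,H,W) integer array with values 0..n_classes-1
#' @param n_classes number of classes
#' @return (B, n_classes, D, H, W) array
#' @keywords internal
one_hot <- function(labels, n_classes = 3L) {
  d <- dim(labels)
  if (length(d) == 3L) { labels <- array(labels, dim = c(1L, d)); d <- dim(labels) }
  out <- array(0, dim = c(d[1], n_classes, d[2], d[3], d[4]))
  for (c in seq_len(n_classes))
    out[, c, , , ] <- (labels == (c - 1L)) * 1
  out
}
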