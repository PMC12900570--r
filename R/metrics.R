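# Segmentation evaluation: overlap (DSC, IoU with +1 smoothing) and surface
# distances (HD95, ASSD) in physical millimetres.
#
# The overlap measures deliberately keep the +1 smoothing in numerator and
# denominator, which makes the empty-vs-empty comparison equal 1 instead of
# undefined; `smooth = FALSE` switches to the strict textbook definitions.
# Surfaces are foreground voxels with a 6-connected background (or
# out-of-volume) neighbour; distances are exact nearest-neighbour Euclidean
# distances between surface voxel centres scaled by the voxel spacing.

#' Dice similarity coefficient with +1 smoothing
#'
#' \code{(2|GT int Pred| + 1) / (|GT| + |Pred| + 1)}. With \code{smooth =
#' FALSE} the unsmoothed Dice is returned (NaN for two empty masks).
#'
#' @param gt,pred logical/0-1 arrays of identical shape
#' @param smooth keep the +1 smoothing (default TRUE)
#' @return scalar in [0, 1]
#' @export
dsc <- function(gt, pred, smooth = TRUE) {
  check_mask_pair(gt, pred)
  gt <- gt != 0; pred <- pred != 0
  inter <- sum(gt & pred)
  s <- if (smooth) 1 else 0
  (2 * inter + s) / (sum(gt) + sum(pred) + s)
}

#' Intersection over union (Jaccard) with +1 smoothing
#' @inheritParams dsc
#' @return scalar in [0, 1]
#' @export
iou <- function(gt, pred, smooth = TRUE) {
  check_mask_pair(gt, pred)
  gt <- gt != 0; pred <- pred != 0
  inter <- sum(gt & pred)
  s <- if (smooth) 1 else 0
  (inter + s) / (sum(gt) + sum(pred) - inter + s)
}

#' Surface voxels of a binary mask
#'
#' A foreground voxel belongs to the surface when at least one of its six
#' face neighbours is background or lies outside the volume.
#'
#' @param mask 3D logical/0-1 array
#' @return integer matrix (n x 3) of 1-based voxel indices (D, H, W order)
#' @export
surface_voxels <- function(mask) {
  m <- mask != 0
  d <- dim(m)
  if (length(d) != 3L) stop("surface_voxels: expected a 3D mask")
  # pad with background, then check the six shifts
  interior <- array(TRUE, dim = d)
  shift_ok <- function(ax, delta) {
    idx <- lapply(d, seq_len)
    src <- idx; src[[ax]] <- idx[[ax]] + delta
    keep <- src[[ax]] >= 1L & src[[ax]] <= d[ax]
    nb <- array(FALSE, dim = d)
    dst <- idx; dst[[ax]] <- idx[[ax]][keep]
    srcv <- src; srcv[[ax]] <- src[[ax]][keep]
    nb[dst[[1]], dst[[2]], dst[[3]]] <- m[srcv[[1]], srcv[[2]], srcv[[3]]]
    nb
  }
  all_nb <- shift_ok(1, -1) & shift_ok(1, 1) &
    shift_ok(2, -1) & shift_ok(2, 1) &
    shift_ok(3, -1) & shift_ok(3, 1)
  surf <- m & !all_nb
  which(surf, arr.ind = TRUE)
}

surface_coords_mm <- function(mask, spacing) {
  sv <- surface_voxels(mask)
  if (nrow(sv) == 0L) return(matrix(numeric(0), 0, 3))
  sweep(sv - 1, 2L, spacing, `*`)
}

directed_dists <- function(a_mm, b_mm) .cpp_nn_dist(a_mm, b_mm)

#' 95th-percentile Hausdorff distance (mm)
#'
#' Maximum over both directions of the 95th percentile (linear-interpolation
#' convention, R \code{quantile} type 7) of nearest surface-to-surface
#' Euclidean distances.
#'
#' @param gt,pred non-empty binary masks of identical shape
#' @param spacing voxel spacing (mm) per axis, length 3
#' @return distance in mm
#' @export
hd95 <- function(gt, pred, spacing = c(1, 1, 1)) {
  check_mask_pair(gt, pred)
  if (!any(gt != 0) || !any(pred != 0))
    stop("hd95: masks must both be non-empty; report the case as missing")
  a <- surface_coords_mm(gt, spacing)
  b <- surface_coords_mm(pred, spacing)
  d_ab <- stats::quantile(directed_dists(a, b), 0.95, names = FALSE, type = 7)
  d_ba <- stats::quantile(directed_dists(b, a), 0.95, names = FALSE, type = 7)
  max(d_ab, d_ba)
}

#' Average symmetric surface distance (mm)
#'
#' \code{(sum_a d(a, S(B)) + sum_b d(b, S(A))) / (|S(A)| + |S(B)|)}.
#'
#' @inheritParams hd95
#' @return distance in mm
#' @export
assd <- function(gt, pred, spacing = c(1, 1, 1)) {
  check_mask_pair(gt, pred)
  if (!any(gt != 0) || !any(pred != 0))
    stop("assd: masks must both be non-empty; report the case as missing")
  a <- surface_coords_mm(gt, spacing)
  b <- surface_coords_mm(pred, spacing)
  (sum(directed_dists(a, b)) + sum(directed_dists(b, a))) /
    (nrow(a) + nrow(b))
}

#' Per-class segmentation report for one case
#'
#' Computes DSC, IoU, HD95 and ASSD for the vertebra and disc classes plus
#' their unweighted means. Ten-class inputs are collapsed to the three-class
#' scheme first. Distance metrics are NA when either mask of a class is
#' empty.
#'
#' @param gt,pred label volumes (see [generate_phantom()]) or plain integer
#'   arrays under the three-class scheme
#' @param spacing voxel spacing in mm (taken from `gt` if it carries one)
#' @return object of class `metric_report`: a data.frame with rows vertebra,
#'   disc, mean
#' @export
evaluate_case <- function(gt, pred, spacing = NULL) {
  get_arr <- function(x) {
    if (inherits(x, "label_volume")) {
      if (identical(x$scheme, "TEN_CLASS")) x <- to_three_class(x)
      x$labels
    } else x
  }
  if (inherits(gt, "label_volume") && inherits(pred, "label_volume") &&
      !identical(gt$scheme, pred$scheme) &&
      !all(c(gt$scheme, pred$scheme) %in% c("TEN_CLASS", "THREE_CLASS")))
    stop("evaluate_case: label scheme mismatch")
  if (is.null(spacing))
    spacing <- if (inherits(gt, "label_volume")) gt$spacing else c(1, 1, 1)
  ga <- get_arr(gt); pa <- get_arr(pred)
  check_mask_pair(ga, pa)
  one_class <- function(lab) {
    g <- ga == lab; p <- pa == lab
    h <- tryCatch(hd95(g, p, spacing), error = function(e) NA_real_)
    s <- tryCatch(assd(g, p, spacing), error = function(e) NA_real_)
    c(dsc = dsc(g, p), iou = iou(g, p), hd95 = h, assd = s)
  }
  vert <- one_class(1L)
  disc <- one_class(2L)
  rep_ <- rbind(vertebra = vert, disc = disc, mean = (vert + disc) / 2)
  out <- as.data.frame(rep_)
  class(out) <- c("metric_report", "data.frame")
  out
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Segmentation metrics (DSC/IoU fractions, distances in mm):\n")
  print.data.frame(round(as.data.frame(x), 4))
  invisible(x)
}
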