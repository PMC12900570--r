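# Synthetic dual-modality lumbar-spine phantom.
#
# Emulates the structure of sagittal lumbar MR stacks: five superellipsoidal
# vertebral bodies stacked along the height axis, separated by four thinner
# disc slabs, with the characteristic contrast inversion between sequences
# (T1: fatty vertebral marrow bright, discs dark; T2: water-rich discs
# bright, vertebrae darker), plus Rician magnitude noise and a smooth
# multiplicative bias field. Labels exactly delineate the generating shapes
# under the ten-class scheme (0 background, 1-5 vertebrae L1..L5, 6-9 discs
# L1/L2..L4/L5).

#' Phantom generation parameters
#'
#' @param shape (D, H, W) voxel counts; all components >= 8
#' @param n_vertebrae number of vertebral bodies (>= 1), default 5
#' @param noise_sigma Rician noise scale as a fraction of the intensity
#'   contrast range (default 0.05)
#' @param bias_strength peak relative amplitude of the multiplicative bias
#'   field (default 0.2)
#' @param spacing voxel spacing in mm; default c(4.5, 1, 1): 4.0 mm slices
#'   plus 0.5 mm gap along the slice axis, in-plane spacing unstated in the
#'   source protocol and set to 1 mm
#' @param seed integer seed; the same config always yields bit-identical
#'   output
#' @return list of class `phantom_config`
#' @export
phantom_config <- function(shape = c(48L, 256L, 256L), n_vertebrae = 5L,
                           noise_sigma = 0.05, bias_strength = 0.2,
                           spacing = c(4.5, 1, 1), seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("phantom_config: shape must be 3 components, each >= 8")
  if (n_vertebrae < 1L) stop("phantom_config: n_vertebrae must be >= 1")
  if (noise_sigma < 0 || bias_strength < 0)
    stop("phantom_config: noise_sigma and bias_strength must be >= 0")
  structure(list(shape = shape, n_vertebrae = as.integer(n_vertebrae),
                 noise_sigma = noise_sigma, bias_strength = bias_strength,
                 spacing = spacing, seed = as.integer(seed)),
            class = "phantom_config")
}

# base intensities in arbitrary units (piecewise constant per structure)
PHANTOM_INTENSITY <- list(
  t1 = c(background = 0.10, vertebra = 0.80, disc = 0.35),
  t2 = c(background = 0.10, vertebra = 0.40, disc = 0.90)
)

# smooth multiplicative bias field from low-order cosine modes, in
# [1 - strength, 1 + strength]
bias_field <- function(shape, strength) {
  if (strength == 0) return(array(1, dim = shape))
  modes <- 2L
  axes <- lapply(shape, function(n) (seq_len(n) - 0.5) / n)
  f <- array(0, dim = shape)
  for (kd in 0:modes) for (kh in 0:modes) for (kw in 0:modes) {
    if (kd + kh + kw == 0 || kd + kh + kw > modes) next
    coef <- rnorm(1)
    ph <- runif(3, 0, 2 * pi)
    f <- f + coef *
      outer(outer(cos(pi * kd * axes[[1]] + ph[1]),
                  cos(pi * kh * axes[[2]] + ph[2])),
            cos(pi * kw * axes[[3]] + ph[3]))
  }
  rng <- max(abs(f))
  if (rng == 0) return(array(1, dim = shape))
  1 + strength * f / rng
}

#' Generate a dual-modality spine phantom with ground-truth labels
#'
#' @param cfg a [phantom_config()]
#' @return list with `volume` (class `volume_pair`: t1, t2, spacing, affine)
#'   and `labels` (class `label_volume` under the ten-class scheme)
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  D <- cfg$shape[1]; H <- cfg$shape[2]; W <- cfg$shape[3]
  nv <- cfg$n_vertebrae
  # column layout along H: vertebra height hv, disc height hd = ~0.35 hv,
  # column fills ~80% of H
  hv <- floor(0.8 * H / (nv + 0.35 * (nv - 1)))
  hd <- max(1L, floor(0.35 * hv))
  need <- nv * 2L + (nv - 1L)   # hv >= 2 and hd >= 1 at minimum
  if (hv < 2L)
    stop(sprintf(paste0("generate_phantom: height %d too small for %d ",
                        "vertebrae; need height >= %d"),
                 H, nv, ceiling(need / 0.8)))
  col_h <- nv * hv + (nv - 1L) * hd
  h0 <- floor((H - col_h) / 2)
  labels <- array(0L, dim = c(D, H, W))
  dc <- (D + 1) / 2; wc <- (W + 1) / 2
  ad <- 0.30 * D; aw <- 0.28 * W      # semi-axes of the vertebral bodies
  dgrid <- slice.index(labels, 1); hgrid <- slice.index(labels, 2)
  wgrid <- slice.index(labels, 3)
  pow <- 2.5                          # superellipsoid exponent
  for (i in seq_len(nv)) {
    top <- h0 + (i - 1L) * (hv + hd)
    hc <- top + (hv + 1) / 2
    r <- (abs((dgrid - dc) / ad)^pow + abs((wgrid - wc) / aw)^pow +
            abs((hgrid - hc) / (hv / 2))^pow)
    labels[r <= 1] <- i
    if (i < nv) {
      dtop <- top + hv
      in_h <- hgrid > dtop & hgrid <= dtop + hd
      rr <- (abs((dgrid - dc) / (0.92 * ad))^pow +
               abs((wgrid - wc) / (0.92 * aw))^pow)
      labels[in_h & rr <= 1] <- nv + i
    }
  }
  base_int <- function(mod) {
    b <- PHANTOM_INTENSITY[[mod]]
    out <- array(b["background"], dim = c(D, H, W))
    out[labels >= 1L & labels <= nv] <- b["vertebra"]
    out[labels > nv] <- b["disc"]
    out
  }
  contrast_range <- diff(range(unlist(PHANTOM_INTENSITY)))
  vols <- with_seed(cfg$seed, {
    bias <- bias_field(cfg$shape, cfg$bias_strength)
    make_mod <- function(mod) {
      s <- base_int(mod) * bias
      if (cfg$noise_sigma > 0) {
        sig <- cfg$noise_sigma * contrast_range
        n1 <- array(rnorm(length(s), 0, sig), dim = dim(s))
        n2 <- array(rnorm(length(s), 0, sig), dim = dim(s))
        s <- sqrt((s + n1)^2 + n2^2)   # Rician magnitude
      }
      s
    }
    list(t1 = make_mod("t1"), t2 = make_mod("t2"))
  })
  volume <- structure(list(t1 = vols$t1, t2 = vols$t2, spacing = cfg$spacing,
                           affine = diag(c(cfg$spacing, 1))),
                      class = "volume_pair")
  scheme <- if (nv == 5L) "TEN_CLASS" else "GENERIC"
  lab <- structure(list(labels = labels, scheme = scheme,
                        n_vertebrae = nv, spacing = cfg$spacing),
                   class = "label_volume")
  list(volume = volume, labels = lab)
}

#' Collapse a ten-class mask to the three-class scheme
#'
#' Vertebra labels map to 1, disc labels to 2, background stays 0.
#'
#' @param mask `label_volume` under the TEN_CLASS (or GENERIC) scheme
#' @return `label_volume` under THREE_CLASS
#' @export
to_three_class <- function(mask) {
  stopifnot(inherits(mask, "label_volume"))
  if (identical(mask$scheme, "THREE_CLASS"))
    stop("to_three_class: mask is already three-class")
  nv <- mask$n_vertebrae %||% 5L
  lab <- mask$labels
  out <- array(0L, dim = dim(lab))
  out[lab >= 1L & lab <= nv] <- 1L
  out[lab > nv] <- 2L
  structure(list(labels = out, scheme = "THREE_CLASS", n_vertebrae = nv,
                 spacing = mask$spacing), class = "label_volume")
}

#' Write a volume pair (and optional mask) to NIfTI files
#'
#' Creates `t1.nii.gz`, `t2.nii.gz` and, if given, `mask.nii.gz` in `dir`.
#'
#' @param vol `volume_pair`
#' @param dir output directory (created if missing)
#' @param mask optional `label_volume`
#' @return invisibly, the file paths
#' @export
write_volume <- function(vol, dir, mask = NULL) {
  stopifnot(inherits(vol, "volume_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "t1.nii.gz"); p2 <- file.path(dir, "t2.nii.gz")
  write_nifti(vol$t1, p1, vol$spacing, vol$affine, "float32")
  write_nifti(vol$t2, p2, vol$spacing, vol$affine, "float32")
  paths <- c(t1 = p1, t2 = p2)
  if (!is.null(mask)) {
    pm <- file.path(dir, "mask.nii.gz")
    write_nifti(mask$labels, pm, mask$spacing, vol$affine, "int16")
    paths <- c(paths, mask = pm)
  }
  invisible(paths)
}

#' Read a volume pair (and mask when present) from a directory
#'
#' Expects the layout written by [write_volume()].
#'
#' @param dir directory with t1.nii.gz / t2.nii.gz (and optional mask.nii.gz)
#' @return list with `volume` and (possibly NULL) `labels`
#' @export
read_volume <- function(dir) {
  p1 <- file.path(dir, "t1.nii.gz"); p2 <- file.path(dir, "t2.nii.gz")
  if (!file.exists(p1) || !file.exists(p2))
    stop("read_volume: expected t1.nii.gz and t2.nii.gz under ", dir)
  n1 <- read_nifti(p1); n2 <- read_nifti(p2)
  if (!identical(dim(n1$data), dim(n2$data)))
    stop("read_volume: modality shapes differ")
  vol <- structure(list(t1 = n1$data, t2 = n2$data, spacing = n1$spacing,
                        affine = n1$affine), class = "volume_pair")
  labels <- NULL
  pm <- file.path(dir, "mask.nii.gz")
  if (file.exists(pm)) {
    nm <- read_nifti(pm)
    arr <- array(as.integer(round(nm$data)), dim = dim(nm$data))
    nv <- 5L
    scheme <- if (max(arr) <= 2L) "THREE_CLASS" else "TEN_CLASS"
    labels <- structure(list(labels = arr, scheme = scheme, n_vertebrae = nv,
                             spacing = nm$spacing), class = "label_volume")
  }
  list(volume = vol, labels = labels)
}

#' Resample and standardize a volume pair
#'
#' Trilinear resampling to a fixed grid (48 slices, 256 x 256 in-plane by
#' default) followed by per-channel z-score standardization; spacing is
#' rescaled so physical extent is preserved.
#'
#' @param vol `volume_pair`
#' @param target_depth number of slices (default 48)
#' @param target_hw in-plane size (default 256)
#' @param standardize z-score each channel (default TRUE)
#' @return resampled `volume_pair`
#' @export
preprocess_volume <- function(vol, target_depth = 48L, target_hw = 256L,
                              standardize = TRUE) {
  stopifnot(inherits(vol, "volume_pair"))
  d <- dim(vol$t1)
  if (any(d < 2L)) stop("preprocess_volume: degenerate input (a dim < 2)")
  od <- as.integer(c(target_depth, target_hw, target_hw))
  rs <- function(x) .cpp_resize3d(x, as.integer(dim(x)), od, 1L)
  t1 <- rs(vol$t1); t2 <- rs(vol$t2)
  if (standardize) {
    zs <- function(x) (x - mean(x)) / (stats::sd(x) + 1e-12)
    t1 <- zs(t1); t2 <- zs(t2)
  }
  sp <- vol$spacing * d / od
  structure(list(t1 = t1, t2 = t2, spacing = sp,
                 affine = diag(c(sp, 1))), class = "volume_pair")
}

# rotate slices in the (H, W) plane about the center; bilinear for
# intensities, nearest for labels
rotate_inplane <- function(x, angle_deg, nearest = FALSE) {
  d <- dim(x)
  if (angle_deg == 0) return(x)
  th <- angle_deg * pi / 180
  H <- d[2]; W <- d[3]
  hc <- (H + 1) / 2; wc <- (W + 1) / 2
  hg <- matrix(seq_len(H), H, W) - hc
  wg <- matrix(seq_len(W), H, W, byrow = TRUE) - wc
  sh <- cos(th) * hg - sin(th) * wg + hc
  sw <- sin(th) * hg + cos(th) * wg + wc
  out <- array(if (nearest) 0L else 0, dim = d)
  pair <- function(a, b) cbind(as.vector(a), as.vector(b))
  if (nearest) {
    ih <- pmin(pmax(round(sh), 1), H)
    iw <- pmin(pmax(round(sw), 1), W)
    ok <- as.vector(sh >= 0.5 & sh <= H + 0.5 & sw >= 0.5 & sw <= W + 0.5)
    idx <- pair(ih, iw)
    for (dd in seq_len(d[1])) {
      sl <- x[dd, , ]
      res <- rep(0L, H * W)
      res[ok] <- sl[idx[ok, , drop = FALSE]]
      out[dd, , ] <- matrix(res, H, W)
    }
  } else {
    h0 <- pmin(pmax(floor(sh), 1), H); h1 <- pmin(h0 + 1, H)
    w0 <- pmin(pmax(floor(sw), 1), W); w1 <- pmin(w0 + 1, W)
    fh <- as.vector(pmin(pmax(sh - h0, 0), 1))
    fw <- as.vector(pmin(pmax(sw - w0, 0), 1))
    ok <- as.vector(sh >= 1 & sh <= H & sw >= 1 & sw <= W)
    i00 <- pair(h0, w0); i10 <- pair(h1, w0)
    i01 <- pair(h0, w1); i11 <- pair(h1, w1)
    for (dd in seq_len(d[1])) {
      sl <- x[dd, , ]
      v <- (1 - fh) * (1 - fw) * sl[i00] + fh * (1 - fw) * sl[i10] +
        (1 - fh) * fw * sl[i01] + fh * fw * sl[i11]
      v[!ok] <- 0
      out[dd, , ] <- matrix(v, H, W)
    }
  }
  out
}

#' Random rotation + crop augmentation of a paired volume and mask
#'
#' Applies one spatial transform to both: an in-plane rotation (bilinear for
#' intensities, nearest for labels) followed by a random crop that is resized
#' back to the original grid. With `max_angle = 0` and `min_crop = 1` the
#' transform is the identity.
#'
#' @param vol `volume_pair`
#' @param mask `label_volume` with matching shape
#' @param seed integer seed
#' @param max_angle maximum absolute in-plane rotation (degrees, default 10)
#' @param min_crop minimum retained fraction per axis (default 0.85)
#' @return list(volume, labels) with the same shapes as the inputs
#' @export
augment_pair <- function(vol, mask, seed = 1L, max_angle = 10, min_crop = 0.85) {
  stopifnot(inherits(vol, "volume_pair"), inherits(mask, "label_volume"))
  d <- dim(vol$t1)
  if (!identical(d, dim(mask$labels))) stop("augment_pair: shape mismatch")
  with_seed(seed, {
    angle <- if (max_angle > 0) runif(1, -max_angle, max_angle) else 0
    frac <- if (min_crop < 1) runif(3, min_crop, 1) else rep(1, 3)
    size <- pmax(2L, as.integer(round(d * frac)))
    start <- integer(3)
    for (i in 1:3) start[i] <- if (size[i] < d[i])
      sample.int(d[i] - size[i] + 1L, 1L) else 1L
    idx <- lapply(1:3, function(i) start[i] + seq_len(size[i]) - 1L)
    tf_int <- function(x) {
      x <- rotate_inplane(x, angle, nearest = FALSE)
      x <- x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      if (!identical(dim(x), d))
        x <- .cpp_resize3d(x, as.integer(dim(x)), as.integer(d), 1L)
      x
    }
    tf_lab <- function(x) {
      x <- rotate_inplane(x, angle, nearest = TRUE)
      x <- x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      if (!identical(dim(x), d))
        x <- array(as.integer(.cpp_resize3d(x, as.integer(dim(x)),
                                            as.integer(d), 0L)), dim = d)
      array(as.integer(x), dim = d)
    }
    volume <- structure(list(t1 = tf_int(vol$t1), t2 = tf_int(vol$t2),
                             spacing = vol$spacing, affine = vol$affine),
                        class = "volume_pair")
    labels <- structure(list(labels = tf_lab(mask$labels),
                             scheme = mask$scheme,
                             n_vertebrae = mask$n_vertebrae %||% 5L,
                             spacing = mask$spacing), class = "label_volume")
    list(volume = volume, labels = labels)
  })
}
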