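# Minimal reverse-mode autodiff tape over base-R numeric arrays.
#
# Every network block in the package is expressed through these primitives, so
# the same code path serves both the plain numeric operations exposed to users
# (constants in, value out) and CPU training (parameters in, gradients out).
# Nodes are environments carrying a value, the parent nodes, and a vector-
# Jacobian closure; ad_backward() walks the tape in reverse topological order.

.ad_state <- new.env(parent = emptyenv())
.ad_state$counter <- 0L

new_ad <- function(value, parents = list(), backward = NULL,
                   requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backward <- backward
  e$requires_grad <- requires_grad ||
    any(vapply(parents, function(p) p$requires_grad, logical(1)))
  e$grad <- NULL
  .ad_state$counter <- .ad_state$counter + 1L
  e$id <- .ad_state$counter
  class(e) <- "adtensor"
  e
}

#' Wrap a numeric array as a constant (no gradient) autodiff node
#' @param x numeric array or scalar
#' @keywords internal
ad_const <- function(x) {
  if (inherits(x, "adtensor")) return(x)
  new_ad(x)
}

#' Wrap a numeric array as a trainable parameter node
#' @param x numeric array or scalar
#' @keywords internal
ad_param <- function(x) new_ad(x, requires_grad = TRUE)

ad_value <- function(x) if (inherits(x, "adtensor")) x$value else x

is_ad <- function(x) inherits(x, "adtensor")

#' Reverse-mode sweep from a scalar (or seeded) root node
#'
#' Accumulates gradients into the `$grad` field of every reachable node with
#' `requires_grad = TRUE`. Gradients of parameter nodes must be reset (see
#' [ad_zero_grad()]) between tapes.
#' @param root adtensor; the loss node
#' @param grad seed gradient; defaults to 1 for scalars
#' @keywords internal
ad_backward <- function(root, grad = NULL) {
  if (is.null(grad)) {
    if (length(root$value) != 1L)
      stop("ad_backward: seed gradient required for non-scalar root")
    grad <- 1
  }
  # iterative DFS post-order for reverse topological order
  topo <- vector("list", 256L); nt <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L)); ns <- 1L
  while (ns > 0L) {
    fr <- stack[[ns]]
    node <- fr$node
    key <- as.character(node$id)
    if (fr$stage == 1L) {
      if (!is.null(seen[[key]]) || !node$requires_grad) { ns <- ns - 1L; next }
      seen[[key]] <- TRUE
      stack[[ns]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (p$requires_grad && is.null(seen[[as.character(p$id)]])) {
          ns <- ns + 1L
          stack[[ns]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      ns <- ns - 1L
      nt <- nt + 1L
      if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[nt]] <- node
    }
  }
  if (!root$requires_grad) return(invisible(NULL))
  root$grad <- grad
  for (i in seq_len(nt)) {
    node <- topo[[nt - i + 1L]]
    if (is.null(node$backward) || is.null(node$grad)) next
    grads <- node$backward(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (!p$requires_grad || is.null(grads[[j]])) next
      g <- grads[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    if (!identical(node, root) && is.null(node$backward_keep)) node$grad <- NULL
  }
  invisible(NULL)
}

ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# --- shape helpers ---------------------------------------------------------

dim_of <- function(x) { d <- dim(x); if (is.null(d)) length(x) else d }

# sum a gradient over trailing axes so it matches a head-broadcast operand
head_reduce <- function(g, head_len, head_dim) {
  gm <- matrix(as.vector(g), nrow = head_len)
  out <- rowSums(gm)
  if (length(head_dim) > 1L) dim(out) <- head_dim
  out
}

# --- elementwise arithmetic -------------------------------------------------
# b may equal a's shape, be a scalar, or match the leading dims of a
# (column-major recycling makes leading-dim broadcast exact in base R).

ad_add <- function(a, b) {
  a <- ad_const(a); b <- ad_const(b)
  la <- length(a$value); lb <- length(b$value)
  if (lb > la) stop("ad_add: second operand larger than first")
  val <- a$value + as.vector(b$value)
  dim(val) <- dim(a$value)
  new_ad(val, list(a, b), function(g) {
    gb <- if (lb == la) { gg <- g; dim(gg) <- dim(b$value); gg }
          else if (lb == 1L) sum(g)
          else head_reduce(g, lb, dim_of(b$value))
    list(g, gb)
  })
}

ad_neg <- function(a) {
  a <- ad_const(a)
  new_ad(-a$value, list(a), function(g) list(-g))
}

ad_sub <- function(a, b) ad_add(a, ad_neg(ad_const(b)))

ad_mul <- function(a, b) {
  a <- ad_const(a); b <- ad_const(b)
  la <- length(a$value); lb <- length(b$value)
  if (lb > la) stop("ad_mul: second operand larger than first")
  bv <- as.vector(b$value)
  val <- a$value * bv
  dim(val) <- dim(a$value)
  new_ad(val, list(a, b), function(g) {
    ga <- g * bv; dim(ga) <- dim(a$value)
    gb <- if (lb == la) { gg <- g * a$value; dim(gg) <- dim(b$value); gg }
          else if (lb == 1L) sum(g * a$value)
          else head_reduce(g * a$value, lb, dim_of(b$value))
    list(ga, gb)
  })
}

ad_div <- function(a, b) {
  a <- ad_const(a); b <- ad_const(b)
  if (length(b$value) != length(a$value) && length(b$value) != 1L)
    stop("ad_div: shape mismatch")
  val <- a$value / as.vector(b$value)
  dim(val) <- dim(a$value)
  new_ad(val, list(a, b), function(g) {
    ga <- g / as.vector(b$value); dim(ga) <- dim(a$value)
    gb <- -g * a$value / (as.vector(b$value)^2)
    if (length(b$value) == 1L) gb <- sum(gb) else dim(gb) <- dim(b$value)
    list(ga, gb)
  })
}

# --- elementwise nonlinearities --------------------------------------------

ad_unary <- function(a, code) {
  a <- ad_const(a)
  r <- .cpp_unary(a$value, code)
  new_ad(r$y, list(a), function(g) list(g * r$d))
}

ad_sigmoid <- function(a) ad_unary(a, 1L)
ad_relu <- function(a) ad_unary(a, 2L)
ad_silu <- function(a) ad_unary(a, 3L)
ad_softplus <- function(a) ad_unary(a, 4L)

ad_exp <- function(a) {
  a <- ad_const(a)
  v <- exp(a$value)
  new_ad(v, list(a), function(g) list(g * v))
}

ad_abs <- function(a) {
  a <- ad_const(a)
  sg <- sign(a$value)
  new_ad(abs(a$value), list(a), function(g) list(g * sg))
}

ad_square <- function(a) { a <- ad_const(a); ad_mul(a, a) }

# --- reductions -------------------------------------------------------------

ad_sum <- function(a) {
  a <- ad_const(a)
  d <- dim_of(a$value)
  new_ad(sum(a$value), list(a), function(g) {
    out <- array(g, dim = d); list(out)
  })
}

ad_mean <- function(a) {
  a <- ad_const(a)
  n <- length(a$value)
  d <- dim_of(a$value)
  new_ad(mean(a$value), list(a), function(g) list(array(g / n, dim = d)))
}

# mean over all axes after the first `nkeep` (for (B,C,D,H,W) feature maps:
# nkeep = 2 is global average pooling, nkeep = 3 pools height and width)
ad_mean_trailing <- function(a, nkeep) {
  a <- ad_const(a)
  d <- dim_of(a$value)
  stopifnot(length(d) > nkeep)
  hd <- d[seq_len(nkeep)]
  nh <- prod(hd)
  ntr <- prod(d[-seq_len(nkeep)])
  v <- rowMeans(matrix(as.vector(a$value), nrow = nh))
  dim(v) <- hd
  new_ad(v, list(a), function(g) {
    out <- array(as.vector(g) / ntr, dim = d)  # recycles over trailing axes
    list(out)
  })
}

# --- structural ops ---------------------------------------------------------

ad_reshape <- function(a, newdim) {
  a <- ad_const(a)
  d <- dim_of(a$value)
  v <- a$value
  dim(v) <- newdim
  new_ad(v, list(a), function(g) { dim(g) <- d; list(g) })
}

ad_aperm <- function(a, perm) {
  a <- ad_const(a)
  inv <- order(perm)
  new_ad(aperm(a$value, perm), list(a), function(g) list(aperm(g, inv)))
}

# concatenate along an arbitrary axis
ad_concat <- function(xs, axis) {
  xs <- lapply(xs, ad_const)
  dims <- lapply(xs, function(x) dim_of(x$value))
  nd <- length(dims[[1]])
  sizes <- vapply(dims, function(d) d[axis], numeric(1))
  od <- dims[[1]]; od[axis] <- sum(sizes)
  perm <- c(setdiff(seq_len(nd), axis), axis)
  mats <- lapply(xs, function(x) {
    m <- aperm(x$value, perm)
    matrix(as.vector(m), ncol = dim_of(x$value)[axis])
  })
  big <- do.call(cbind, mats)
  vd <- od[perm]
  v <- array(as.vector(big), dim = vd)
  v <- aperm(v, order(perm))
  new_ad(v, xs, function(g) {
    gm <- aperm(g, perm)
    gm <- matrix(as.vector(gm), ncol = od[axis])
    out <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      cols <- at + seq_len(sizes[i]); at <- at + sizes[i]
      gi <- array(as.vector(gm[, cols, drop = FALSE]), dim = dims[[i]][perm])
      out[[i]] <- aperm(gi, order(perm))
    }
    out
  })
}

# select channels (axis 2 of a (B,C,...) array), keeping the axis
ad_slice_ch <- function(a, idx) {
  a <- ad_const(a)
  d <- dim_of(a$value)
  args <- c(list(a$value, TRUE), list(idx),
            rep(list(TRUE), length(d) - 2L), list(drop = FALSE))
  v <- do.call(`[`, args)
  new_ad(v, list(a), function(g) {
    out <- array(0, dim = d)
    args2 <- c(list(out, TRUE), list(idx), rep(list(TRUE), length(d) - 2L))
    eval_call <- as.call(c(list(as.name("[<-")), args2, list(g)))
    out <- eval(eval_call)
    list(out)
  })
}

# replicate a (B,1,D,H,W) map across C channels
ad_expand_ch <- function(a, C) {
  a <- ad_const(a)
  d <- dim_of(a$value)
  stopifnot(d[2] == 1L)
  v <- a$value[, rep(1L, C), , , , drop = FALSE]
  new_ad(v, list(a), function(g) {
    gm <- aperm(g, c(1, 3, 4, 5, 2))
    gs <- rowSums(matrix(as.vector(gm), ncol = C))
    dim(gs) <- d
    list(gs)
  })
}

# --- linear algebra ---------------------------------------------------------

ad_matmul <- function(a, b) {
  a <- ad_const(a); b <- ad_const(b)
  new_ad(a$value %*% b$value, list(a, b), function(g) {
    list(tcrossprod(g, b$value), crossprod(a$value, g))
  })
}

# X (n x k) %*% W (k x m) + bias (m), bias recycled over rows
ad_linear <- function(x, w, b = NULL) {
  x <- ad_const(x); w <- ad_const(w)
  y <- x$value %*% w$value
  if (is.null(b)) {
    return(new_ad(y, list(x, w), function(g)
      list(tcrossprod(g, w$value), crossprod(x$value, g))))
  }
  b <- ad_const(b)
  y <- sweep(y, 2L, as.vector(b$value), `+`)
  new_ad(y, list(x, w, b), function(g)
    list(tcrossprod(g, w$value), crossprod(x$value, g), colSums(g)))
}

# --- convolution / resampling ----------------------------------------------

#' 3D convolution autodiff op
#' @param x (B,C,D,H,W) node; w (Cout,Cin/groups,k,k,k) node; b bias node or NULL
#' @keywords internal
ad_conv3d <- function(x, w, b = NULL, stride = 1L, pad = NULL, dilation = 1L,
                      groups = 1L) {
  x <- ad_const(x); w <- ad_const(w)
  wd <- dim_of(w$value)
  if (is.null(pad)) pad <- as.integer((wd[3] - 1L) * dilation / 2L)
  bias <- if (is.null(b)) numeric(0) else as.vector(ad_value(b))
  xd <- dim_of(x$value)
  if (xd[2] != wd[2] * groups)
    stop(sprintf("conv3d: input has %d channels, kernel expects %d",
                 xd[2], wd[2] * groups))
  y <- .cpp_conv3d_fwd(x$value, as.integer(xd), w$value, as.integer(wd),
                       bias, as.integer(stride), as.integer(pad),
                       as.integer(dilation), as.integer(groups))
  parents <- list(x, w)
  if (!is.null(b)) parents <- c(parents, list(ad_const(b)))
  new_ad(y, parents, function(g) {
    need_gx <- x$requires_grad
    bw <- .cpp_conv3d_bwd(x$value, as.integer(xd), w$value, as.integer(wd), g,
                          as.integer(stride), as.integer(pad),
                          as.integer(dilation), as.integer(groups), need_gx)
    out <- list(if (need_gx) bw$gx else NULL, bw$gw)
    if (!is.null(b)) out <- c(out, list(bw$gb))
    out
  })
}

ad_upsample2 <- function(x) {
  x <- ad_const(x)
  xd <- dim_of(x$value)
  y <- .cpp_upsample2_fwd(x$value, as.integer(xd))
  new_ad(y, list(x), function(g) list(.cpp_upsample2_bwd(g, as.integer(xd))))
}

# --- normalization / softmax over the channel axis --------------------------

# layer norm across channels per voxel, learnable per-channel gamma/beta
ad_layernorm_ch <- function(x, gamma, beta, eps = 1e-5) {
  x <- ad_const(x); gamma <- ad_const(gamma); beta <- ad_const(beta)
  d <- dim_of(x$value)
  C <- d[2]
  perm <- c(1, 3, 4, 5, 2)
  xp <- aperm(x$value, perm)
  m <- matrix(as.vector(xp), ncol = C)
  mu <- rowMeans(m)
  xc <- m - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  y <- sweep(sweep(xhat, 2L, as.vector(gamma$value), `*`), 2L,
             as.vector(beta$value), `+`)
  ya <- array(as.vector(y), dim = d[perm])
  ya <- aperm(ya, order(perm))
  new_ad(ya, list(x, gamma, beta), function(g) {
    gp <- aperm(g, perm)
    gm <- matrix(as.vector(gp), ncol = C)
    ggamma <- colSums(gm * xhat)
    gbeta <- colSums(gm)
    gxhat <- sweep(gm, 2L, as.vector(gamma$value), `*`)
    # d/dx of (x - mu) * istd with mu, istd per row
    gx <- istd * (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat))
    gxa <- array(as.vector(gx), dim = d[perm])
    list(aperm(gxa, order(perm)), ggamma, gbeta)
  })
}

ad_softmax_ch <- function(x) {
  x <- ad_const(x)
  d <- dim_of(x$value)
  C <- d[2]
  perm <- c(1, 3, 4, 5, 2)
  xp <- aperm(x$value, perm)
  m <- matrix(as.vector(xp), ncol = C)
  m <- m - m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m)
  p <- e / rowSums(e)
  pa <- aperm(array(as.vector(p), dim = d[perm]), order(perm))
  new_ad(pa, list(x), function(g) {
    gp <- aperm(g, perm)
    gm <- matrix(as.vector(gp), ncol = C)
    dot <- rowSums(gm * p)
    gx <- p * (gm - dot)
    gxa <- array(as.vector(gx), dim = d[perm])
    list(aperm(gxa, order(perm)))
  })
}

# plain softmax over the columns of a (n x C) matrix (used for kernel
# attention and node assignment logits)
ad_softmax_rows <- function(x) {
  x <- ad_const(x)
  m <- x$value - x$value[cbind(seq_len(nrow(x$value)),
                               max.col(x$value, ties.method = "first"))]
  e <- exp(m)
  p <- e / rowSums(e)
  new_ad(p, list(x), function(g) {
    dot <- rowSums(g * p)
    list(p * (g - dot))
  })
}

# --- finite differences along a spatial axis (for the gradient loss) --------

# central differences in the interior, one-sided at the boundaries, along
# spatial axis `axis` (3, 4 or 5) of a (B,C,D,H,W) array
ad_diff_axis <- function(x, axis) {
  x <- ad_const(x)
  d <- dim_of(x$value)
  nd <- length(d)
  perm <- c(setdiff(seq_len(nd), axis), axis)
  L <- d[axis]
  fwd <- function(v) {
    m <- matrix(as.vector(aperm(v, perm)), ncol = L)
    y <- matrix(0, nrow(m), L)
    if (L >= 2L) {
      y[, 1] <- m[, 2] - m[, 1]
      y[, L] <- m[, L] - m[, L - 1]
      if (L > 2L) y[, 2:(L - 1)] <- (m[, 3:L] - m[, 1:(L - 2)]) / 2
    }
    aperm(array(as.vector(y), dim = d[perm]), order(perm))
  }
  v <- fwd(x$value)
  new_ad(v, list(x), function(g) {
    gm <- matrix(as.vector(aperm(g, perm)), ncol = L)
    gx <- matrix(0, nrow(gm), L)
    if (L >= 2L) {
      gx[, 1] <- gx[, 1] - gm[, 1]
      gx[, 2] <- gx[, 2] + gm[, 1]
      gx[, L - 1] <- gx[, L - 1] - gm[, L]
      gx[, L] <- gx[, L] + gm[, L]
      if (L > 2L) {
        for (i in 2:(L - 1)) {
          gx[, i - 1] <- gx[, i - 1] - gm[, i] / 2
          gx[, i + 1] <- gx[, i + 1] + gm[, i] / 2
        }
      }
    }
    ga <- aperm(array(as.vector(gx), dim = d[perm]), order(perm))
    list(ga)
  })
}

# --- selective scan ---------------------------------------------------------

# u, delta: (M,T,C); A: (C,N); B, Cc: (M,T,N). Returns (M,T,C).
ad_scan <- function(u, delta, A, B, Cc) {
  u <- ad_const(u); delta <- ad_const(delta); A <- ad_const(A)
  B <- ad_const(B); Cc <- ad_const(Cc)
  md <- dim_of(u$value)
  N <- dim_of(A$value)[2]
  mdims <- as.integer(c(md[1], md[2], md[3], N))
  fw <- .cpp_scan_fwd(u$value, delta$value, A$value, B$value, Cc$value, mdims)
  new_ad(fw$y, list(u, delta, A, B, Cc), function(g) {
    bw <- .cpp_scan_bwd(u$value, delta$value, A$value, B$value, Cc$value,
                        fw$h, fw$abar, g, mdims)
    list(bw$gu, bw$gdelta, bw$gA, bw$gB, bw$gC)
  })
}

# depthwise 1D convolution along the T axis of (M,T,C) sequences,
# same padding; kernel (k, C), bias (C)
ad_conv1d_dw <- function(x, w, b) {
  x <- ad_const(x); w <- ad_const(w); b <- ad_const(b)
  d <- dim_of(x$value)
  v <- .cpp_conv1d_dw_fwd(x$value, as.integer(d), w$value, as.vector(b$value))
  new_ad(v, list(x, w, b), function(g) {
    bw <- .cpp_conv1d_dw_bwd(x$value, as.integer(d), w$value, g)
    list(bw$gx, bw$gw, bw$gb)
  })
}

# outer additive combination of per-axis positional scores:
# a_d (B,D), a_h (B,H), a_w (B,W) -> (B,1,D,H,W)
ad_outer_sum3 <- function(ad_, ah, aw) {
  ad_ <- ad_const(ad_); ah <- ad_const(ah); aw <- ad_const(aw)
  B <- dim_of(ad_$value)[1]
  D <- dim_of(ad_$value)[2]; H <- dim_of(ah$value)[2]; W <- dim_of(aw$value)[2]
  v <- array(0, dim = c(B, 1L, D, H, W))
  for (b in seq_len(B)) {
    m <- outer(ad_$value[b, ], ah$value[b, ], `+`) # D x H
    v[b, 1L, , , ] <- outer(m, aw$value[b, ], `+`)  # D x H x W
  }
  new_ad(v, list(ad_, ah, aw), function(g) {
    gd <- matrix(0, B, D); gh <- matrix(0, B, H); gw <- matrix(0, B, W)
    for (b in seq_len(B)) {
      gb <- g[b, 1L, , , ]
      dim(gb) <- c(D, H, W)
      gd[b, ] <- apply(gb, 1L, sum)
      gh[b, ] <- apply(gb, 2L, sum)
      gw[b, ] <- apply(gb, 3L, sum)
    }
    list(gd, gh, gw)
  })
}

# multiply (M,T,C) sequences by a per-channel vector s (length C, last axis)
ad_scale_last <- function(x, s) {
  x <- ad_const(x); s <- ad_const(s)
  d <- dim_of(x$value)
  C <- d[length(d)]
  nh <- prod(d[-length(d)])
  v <- x$value * rep(as.vector(s$value), each = nh)
  new_ad(v, list(x, s), function(g) {
    gx <- g * rep(as.vector(s$value), each = nh)
    gs <- colSums(matrix(as.vector(g * x$value), ncol = C))
    list(gx, gs)
  })
}

# reverse the sequence (T) axis of an (M,T,C) array
ad_rev_t <- function(x) {
  x <- ad_const(x)
  T_ <- dim_of(x$value)[2]
  new_ad(x$value[, T_:1, , drop = FALSE], list(x), function(g)
    list(g[, T_:1, , drop = FALSE]))
}

# keep-dims row selection from a matrix
ad_slice_rows <- function(a, i) {
  a <- ad_const(a)
  d <- dim_of(a$value)
  v <- a$value[i, , drop = FALSE]
  new_ad(v, list(a), function(g) {
    out <- matrix(0, d[1], d[2])
    out[i, ] <- g
    list(out)
  })
}

# keep-dims batch selection from a (B,C,D,H,W) array
ad_slice_batch <- function(a, b) {
  a <- ad_const(a)
  d <- dim_of(a$value)
  v <- a$value[b, , , , , drop = FALSE]
  new_ad(v, list(a), function(g) {
    out <- array(0, dim = d)
    out[b, , , , ] <- g
    list(out)
  })
}

# multiply a (B,C,...) feature map by a per-channel vector s (length C)
ad_scale_ch <- function(x, s) {
  x <- ad_const(x); s <- ad_const(s)
  d <- dim_of(x$value)
  B <- d[1]; C <- d[2]
  sv <- rep(as.vector(s$value), each = B)   # (B,C) head, recycled over rest
  v <- x$value * sv
  new_ad(v, list(x, s), function(g) {
    gx <- g * sv; dim(gx) <- d
    per_bc <- rowSums(matrix(as.vector(g * x$value), nrow = B * C))
    gs <- colSums(matrix(per_bc, nrow = B))
    list(gx, gs)
  })
}

# add a per-channel bias vector (length C) to a (B,C,...) map
ad_add_ch <- function(x, b) {
  x <- ad_const(x); b <- ad_const(b)
  d <- dim_of(x$value)
  B <- d[1]; C <- d[2]
  bv <- rep(as.vector(b$value), each = B)
  v <- x$value + bv
  new_ad(v, list(x, b), function(g) {
    per_bc <- rowSums(matrix(as.vector(g), nrow = B * C))
    gb <- colSums(matrix(per_bc, nrow = B))
    list(g, gb)
  })
}

# instance normalization: standardize each (batch, channel) slice over its
# spatial extent, with learnable per-channel gain/shift. (B,C) are the
# leading axes, so the spatial fold is a plain matrix reduction.
ad_instnorm_ch <- function(x, gamma, beta, eps = 1e-5) {
  x <- ad_const(x); gamma <- ad_const(gamma); beta <- ad_const(beta)
  d <- dim_of(x$value)
  B <- d[1]; C <- d[2]; S <- prod(d[-(1:2)])
  m <- matrix(as.vector(x$value), nrow = B * C)
  mu <- rowMeans(m)
  xc <- m - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  gv <- rep(as.vector(gamma$value), each = B)
  y <- array(xhat * gv + rep(as.vector(beta$value), each = B), dim = d)
  new_ad(y, list(x, gamma, beta), function(g) {
    gm <- matrix(as.vector(g), nrow = B * C)
    per_bc_g <- rowSums(gm * xhat)
    ggamma <- colSums(matrix(per_bc_g, nrow = B))
    gbeta <- colSums(matrix(rowSums(gm), nrow = B))
    gxhat <- gm * gv
    gx <- istd * (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat))
    list(array(gx, dim = d), ggamma, gbeta)
  })
}

# leaky rectifier (slope 0.01): used in very narrow bottlenecks where a hard
# rectifier can kill the whole branch at initialization
ad_leakyrelu <- function(a, slope = 0.01) {
  a <- ad_const(a)
  m <- a$value > 0
  v <- a$value * (m + slope * !m)
  new_ad(v, list(a), function(g) list(g * (m + slope * !m)))
}
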