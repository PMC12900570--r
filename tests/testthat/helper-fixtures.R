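# Shared fixtures and independent oracles used across the suite. Everything
# is generated in code; no stored data.

rand_fmap <- function(dims, seed = 1L) {
  spineseg:::with_seed(seed, array(rnorm(prod(dims)), dim = dims))
}

# naive scalar-loop 3D convolution oracle (same padding unless given)
naive_conv3d <- function(x, w, b = NULL, stride = 1L, pad = NULL,
                         dil = 1L, groups = 1L) {
  xd <- dim(x); wd <- dim(w)
  k <- wd[3]
  if (is.null(pad)) pad <- (k - 1L) * dil / 2L
  if (is.null(b)) b <- rep(0, wd[1])
  out_sz <- function(n) floor((n + 2 * pad - ((k - 1) * dil + 1)) / stride) + 1
  B <- xd[1]; Do <- out_sz(xd[3]); Ho <- out_sz(xd[4]); Wo <- out_sz(xd[5])
  Cog <- wd[1] / groups
  y <- array(0, c(B, wd[1], Do, Ho, Wo))
  for (bb in 1:B) for (co in 1:wd[1]) {
    g <- ceiling(co / Cog)
    for (od in 1:Do) for (oh in 1:Ho) for (ow in 1:Wo) {
      acc <- b[co]
      for (i in 1:wd[2]) for (a in 1:k) for (p in 1:k) for (q in 1:k) {
        id <- (od - 1) * stride - pad + (a - 1) * dil + 1
        ih <- (oh - 1) * stride - pad + (p - 1) * dil + 1
        iw <- (ow - 1) * stride - pad + (q - 1) * dil + 1
        if (id >= 1 && id <= xd[3] && ih >= 1 && ih <= xd[4] &&
            iw >= 1 && iw <= xd[5])
          acc <- acc + x[bb, (g - 1) * wd[2] + i, id, ih, iw] *
            w[co, i, a, p, q]
      }
      y[bb, co, od, oh, ow] <- acc
    }
  }
  y
}

# brute-force surface metrics oracles in plain R
oracle_surface <- function(mask) {
  d <- dim(mask)
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    is_surf <- FALSE
    for (r in seq_len(6)) {
      p <- nb[r, ]
      if (any(p < 1) || any(p > d) || !mask[p[1], p[2], p[3]]) {
        is_surf <- TRUE; break
      }
    }
    if (is_surf) out <- rbind(out, c(i, j, k))
  }
  if (is.null(out)) matrix(numeric(0), 0, 3) else out
}

oracle_dists <- function(a, b, spacing) {
  am <- sweep(a - 1, 2, spacing, `*`)
  bm <- sweep(b - 1, 2, spacing, `*`)
  sapply(seq_len(nrow(am)), function(i)
    min(sqrt(colSums((t(bm) - am[i, ])^2))))
}

oracle_hd95 <- function(gt, pred, spacing) {
  a <- oracle_surface(gt); b <- oracle_surface(pred)
  max(quantile(oracle_dists(a, b, spacing), 0.95, names = FALSE, type = 7),
      quantile(oracle_dists(b, a, spacing), 0.95, names = FALSE, type = 7))
}

oracle_assd <- function(gt, pred, spacing) {
  a <- oracle_surface(gt); b <- oracle_surface(pred)
  (sum(oracle_dists(a, b, spacing)) + sum(oracle_dists(b, a, spacing))) /
    (nrow(a) + nrow(b))
}

# random small non-empty binary mask
rand_mask <- function(n = 12L, p = 0.3, seed = 1L) {
  spineseg:::with_seed(seed, {
    m <- array(runif(n^3) < p, dim = rep(n, 3))
    if (!any(m)) m[1, 1, 1] <- TRUE
    m
  })
}

# finite-difference gradient of f at x for a few random indices
fd_grad_check <- function(f, x, grad, idx, eps = 1e-5, tol = 1e-3) {
  for (j in idx) {
    xp <- x; xp[j] <- xp[j] + eps
    xm <- x; xm[j] <- xm[j] - eps
    fd <- (f(xp) - f(xm)) / (2 * eps)
    expect_lt(abs(fd - grad[j]), tol * max(1, abs(fd)))
  }
}
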