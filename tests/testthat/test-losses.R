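# The hybrid frequency-domain-aware Tversky loss family.

make_pg <- function(seed = 1, dims = c(1, 3, 4, 4, 4)) {
  spineseg:::with_seed(seed, {
    logits <- array(rnorm(prod(dims)), dims)
    p <- exp(logits)
    tot <- apply(p, c(1, 3, 4, 5), sum)[1, , , ]
    for (c in seq_len(dims[2])) p[1, c, , , ] <- p[1, c, , , ] / tot
    labs <- array(sample(0:(dims[2] - 1), prod(dims[-2]), TRUE), dims[-2])
    list(p = p, g = spineseg:::one_hot(labs[1, , , ], dims[2]), labs = labs)
  })
}

test_that("tversky_loss reproduces hand-computed values", {
  # single class, w = 1, eps ~ 0: g = (1,1,0,0), p = (1,0,1,0)
  # TP = 1, FP = 1, FN = 1 -> TI = 1/(1 + .25 + .75) = 0.5 -> loss 0.5
  p <- array(0, c(1, 1, 1, 1, 4)); p[1, 1, 1, 1, ] <- c(1, 0, 1, 0)
  g <- array(0, c(1, 1, 1, 1, 4)); g[1, 1, 1, 1, ] <- c(1, 1, 0, 0)
  cfg <- loss_config(class_weights = 1, eps = 1e-12)
  # bypass the simplex check via the internal node (single non-normalized ch)
  got <- spineseg:::ad_value(spineseg:::tversky_node(p, g, cfg, classes = 1L))
  expect_equal(got, 0.5, tolerance = 1e-9)

  # perfect hard prediction -> loss below 1e-6
  pg <- make_pg(2)
  hard <- spineseg:::one_hot(pg$labs[1, , , ], 3)
  expect_lt(tversky_loss(hard, pg$g), 1e-6)

  # alpha = beta = 0.5 equals soft Dice
  cfg_d <- loss_config(alpha = 0.5, beta = 0.5, disc_beta_uplift = 1,
                       class_weights = c(1, 1, 1), eps = 1e-16)
  pv <- pg$p[, 2, , , , drop = FALSE]; gv <- pg$g[, 2, , , , drop = FALSE]
  ti <- 1 - spineseg:::ad_value(spineseg:::tversky_node(pg$p, pg$g, cfg_d, 2L))
  dice <- 2 * sum(pv * gv) / (sum(pv) + sum(gv))
  expect_equal(ti, dice, tolerance = 1e-9)

  expect_error(tversky_loss(pg$p * 0.5, pg$g), "sum to 1")
})

test_that("default config carries the tuned parameter set", {
  cfg <- loss_config()
  expect_equal(cfg$alpha, rep(0.25, 3))
  expect_equal(cfg$beta, c(0.75, 0.75, 0.9))   # disc beta raised 20%
  expect_equal(cfg$w, c(0.2, 1.2, 1.6))
  expect_equal(cfg$omega, 0.07)
  expect_equal(cfg$lambda, 0.55)
  expect_error(loss_config(lambda = 1.2), "lambda")
})

test_that("frequency gradient loss matches a 1D hand computation", {
  # 1x1x8 step edge vs shifted step edge
  gv <- c(0, 0, 0, 1, 1, 1, 1, 1)
  pv <- c(0, 0, 0, 0, 1, 1, 1, 1)
  gp <- array(pv, c(1, 1, 1, 1, 8)); gg <- array(gv, c(1, 1, 1, 1, 8))
  # gradient magnitude = |width-axis central diff| / 3 (other axes flat)
  cdiff <- function(v) {
    n <- length(v)
    c(v[2] - v[1], (v[3:n] - v[1:(n - 2)]) / 2, v[n] - v[n - 1])
  }
  expected <- mean(abs(abs(cdiff(pv)) / 3 - abs(cdiff(gv)) / 3))
  expect_equal(freq_gradient_loss(gp, gg), expected, tolerance = 1e-12)
  # identical and constant inputs give zero
  expect_equal(freq_gradient_loss(gg, gg), 0)
  expect_equal(freq_gradient_loss(gp * 0 + 0.4, gg * 0 + 0.9), 0)
})

test_that("fd and hybrid losses satisfy their composition identities", {
  pg <- make_pg(3)
  cfg <- loss_config()
  # omega = 0 -> vertebra-only Tversky
  cfg0 <- loss_config(omega = 0)
  expect_equal(fd_tversky_loss(pg$p, pg$g, cfg0),
               spineseg:::ad_value(spineseg:::tversky_node(pg$p, pg$g, cfg0, 2L)),
               tolerance = 1e-12)
  # linear combination: components (0.2, 0.5) at omega 0.07 -> 0.235
  expect_equal(0.2 + 0.07 * 0.5, 0.235)
  # lambda = 1 reduces to the all-class Tversky; lambda = 0 to FD
  cfg1 <- loss_config(lambda = 1)
  expect_equal(hfd_tversky_loss(pg$p, pg$g, cfg1),
               tversky_loss(pg$p, pg$g, cfg1), tolerance = 1e-12)
  cfgz <- loss_config(lambda = 0)
  expect_equal(hfd_tversky_loss(pg$p, pg$g, cfgz),
               fd_tversky_loss(pg$p, pg$g, cfgz), tolerance = 1e-12)
  # recombination at the default lambda
  expect_equal(hfd_tversky_loss(pg$p, pg$g, cfg),
               0.55 * tversky_loss(pg$p, pg$g, cfg) +
                 0.45 * fd_tversky_loss(pg$p, pg$g, cfg), tolerance = 1e-9)
  # perfect prediction
  hard <- spineseg:::one_hot(pg$labs[1, , , ], 3)
  expect_lt(hfd_tversky_loss(hard, pg$g), 1e-6)
  # affine in lambda
  l25 <- hfd_tversky_loss(pg$p, pg$g, loss_config(lambda = 0.25))
  l75 <- hfd_tversky_loss(pg$p, pg$g, loss_config(lambda = 0.75))
  l50 <- hfd_tversky_loss(pg$p, pg$g, loss_config(lambda = 0.5))
  expect_equal((l25 + l75) / 2, l50, tolerance = 1e-12)
})

test_that("loss increases monotonically with label corruption", {
  spineseg:::with_seed(9, {
    labs <- array(sample(0:2, 6 * 6 * 6, TRUE, prob = c(.6, .25, .15)),
                  c(6, 6, 6))
    g <- spineseg:::one_hot(labs, 3)
    losses <- sapply(seq(0, 0.5, by = 0.1), function(q) {
      labc <- labs
      n <- length(labs)
      flip <- sample(n, round(q * n))
      labc[flip] <- (labc[flip] + sample(1:2, length(flip), TRUE)) %% 3
      # soften so probabilities are interior
      p <- spineseg:::one_hot(labc, 3) * 0.94 + 0.02
      hfd_tversky_loss(p, g)
    })
    expect_true(all(diff(losses) > -1e-9))
  })
})

test_that("autodiff loss gradients pass a finite-difference check", {
  pg <- make_pg(5, dims = c(1, 3, 3, 3, 3))
  # interior probabilities (simplex interior keeps everything smooth)
  p <- pg$p * 0.9 + 0.1 / 3
  for (wh in c("tversky", "fd", "hfd")) {
    gr <- loss_gradient(p, pg$g, which = wh)
    expect_true(all(is.finite(gr)))
    f <- function(pp) switch(wh,
      tversky = spineseg:::ad_value(spineseg:::tversky_node(pp, pg$g, loss_config())),
      fd = spineseg:::ad_value(spineseg:::fd_tversky_node(pp, pg$g, loss_config())),
      hfd = spineseg:::ad_value(spineseg:::hfd_tversky_node(pp, pg$g, loss_config())))
    idx <- spineseg:::with_seed(10, sample(length(p), 6))
    fd_grad_check(f, p, gr, idx, eps = 1e-6, tol = 1e-3)
  }
})
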