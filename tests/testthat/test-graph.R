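# Anatomical graph construction, normalization, projections and GCN.

test_that("the spine graph matches the anatomical rule exactly", {
  g <- build_spine_graph()
  expect_identical(g$n_nodes, 10L)
  expect_identical(dim(g$A), c(10L, 10L))
  expect_true(isSymmetric(unname(g$A)))
  expect_true(all(diag(g$A) == 0))
  expect_identical(sum(g$A) / 2, 8)          # 8 undirected edges

  # independent reconstruction from the rule: vertebra i (1..5) adjacent to
  # disc above (i-1 -> node 4+i) and below (node 5+i), when those exist
  A2 <- matrix(0, 10, 10)
  for (v in 1:5) {
    above <- 5 + v - 1; below <- 5 + v
    if (above >= 6) { A2[v + 1, above + 1] <- 1; A2[above + 1, v + 1] <- 1 }
    if (below <= 9) { A2[v + 1, below + 1] <- 1; A2[below + 1, v + 1] <- 1 }
  }
  expect_identical(unname(g$A), A2)
  # L1 (node 1) only adjacent to node 6; L2 adjacent to 6 and 7
  expect_identical(unname(which(g$A[2, ] == 1)), 7L)
  expect_identical(unname(which(g$A[3, ] == 1)), c(7L, 8L))
  expect_identical(sum(g$A[1, ]), 0)         # background isolated
})

test_that("symmetric normalization satisfies its algebraic identities", {
  g <- build_spine_graph()
  An <- g$A_norm
  expect_lt(max(abs(An - t(An))), 1e-12)
  # A_norm D^{1/2} 1 = D^{1/2} 1
  dhalf <- sqrt(diag(g$D))
  expect_lt(max(abs(An %*% dhalf - dhalf)), 1e-10)
  # hand value: entry (L1, disc L1/L2) = 1/sqrt(deg(1)*deg(6)) = 1/sqrt(2*3)
  expect_equal(An[2, 7], 1 / sqrt(6), tolerance = 1e-12)
  # isolated node: only the self-loop survives with weight 1
  expect_equal(An[1, 1], 1)
  # spectrum inside [-1, 1]
  ev <- eigen(An, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1 - 1e-10 & ev <= 1 + 1e-10))
  expect_error(normalize_adjacency(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("features_to_graph pools globally and S rows are simplex points", {
  m <- new_graph_module(channels = 4, h_dim = 6, seed = 3)
  F_ <- rand_fmap(c(1, 4, 3, 4, 5), seed = 2)
  r <- features_to_graph(F_, m)
  expect_identical(dim(r$G), c(10L, 6L))
  expect_identical(dim(r$S), c(1L, 10L, 3L, 4L, 5L))
  sums <- apply(r$S[1, , , , , drop = FALSE], c(3, 4, 5), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  expect_true(all(r$S > 0))

  # zero features with zero projection bias give zero node embeddings
  r0 <- features_to_graph(array(0, dim(F_)), m)
  expect_true(all(r0$G == 0))

  # spatial permutation invariance of the pooled embedding
  perm <- spineseg:::with_seed(5, sample(3 * 4 * 5))
  Fp <- F_
  for (c in 1:4)
    Fp[1, c, , , ] <- array(as.vector(F_[1, c, , , ])[perm], c(3, 4, 5))
  expect_equal(features_to_graph(Fp, m)$G, r$G, tolerance = 1e-9)
})

test_that("gcn_forward equals three explicit matrix products", {
  g <- build_spine_graph()
  H <- 5
  W <- spineseg:::with_seed(6, lapply(1:3, function(i) matrix(rnorm(H * H), H)))
  G0 <- spineseg:::with_seed(7, matrix(rnorm(10 * H), 10, H))
  oracle <- G0
  for (l in 1:3) oracle <- pmax(g$A_norm %*% oracle %*% W[[l]], 0)
  expect_lt(max(abs(gcn_forward(G0, g$A_norm, W) - oracle)), 1e-6)
  expect_true(all(gcn_forward(matrix(0, 10, H), g$A_norm, W) == 0))
  expect_error(gcn_forward(G0, g$A_norm, W[1:2]), "3")

  # with identity weights the isolated background node mixes only itself
  Wi <- lapply(1:3, function(i) diag(H))
  G0n <- abs(G0)
  out1 <- gcn_forward(G0n, g$A_norm, Wi)
  G0z <- G0n; G0z[1, ] <- 0
  out2 <- gcn_forward(G0z, g$A_norm, Wi)
  expect_equal(out1[2:10, ], out2[2:10, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(out1[1, ], out2[1, ])))
})

test_that("graph_to_features is a residual map with S-weighted projections", {
  m <- new_graph_module(channels = 3, h_dim = 3, seed = 8)
  F_ <- rand_fmap(c(1, 3, 2, 3, 4), seed = 9)
  r <- features_to_graph(F_, m)
  # zero node features -> exact identity
  out0 <- graph_to_features(matrix(0, 10, 3), r$S, F_)
  expect_equal(out0, F_, tolerance = 1e-12)
  # one-hot S picks exactly one node's projection per voxel
  G <- spineseg:::with_seed(10, matrix(rnorm(30), 10, 3))
  S1 <- array(0, dim(r$S))
  picks <- spineseg:::with_seed(11, sample(10, 2 * 3 * 4, replace = TRUE))
  i <- 0
  for (w in 1:4) for (h in 1:3) for (d in 1:2) {
    i <- i + 1
    S1[1, picks[i], d, h, w] <- 1
  }
  out <- graph_to_features(G, S1, F_, w_proj = diag(3))
  i <- 0
  for (w in 1:4) for (h in 1:3) for (d in 1:2) {
    i <- i + 1
    expect_equal(out[1, , d, h, w], F_[1, , d, h, w] + G[picks[i], ],
                 tolerance = 1e-12)
  }
  expect_error(graph_to_features(G, r$S, rand_fmap(c(1, 3, 4, 3, 4))),
               "disagree")
})
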