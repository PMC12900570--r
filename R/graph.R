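# Anatomical spine graph and graph-convolution enhancement.
#
# The lumbar column is modeled as a 10-node graph: node 0 background,
# nodes 1-5 the vertebrae L1..L5, nodes 6-9 the discs L1/L2..L4/L5. Each
# vertebra is adjacent exactly to its neighbouring discs (bipartite chain);
# the background has no anatomical neighbour and participates only through
# the self-loop added during symmetric normalization.

SPINE_EDGES <- cbind(v = c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L),
                     d = c(6L, 6L, 7L, 7L, 8L, 8L, 9L, 9L))

SPINE_NODE_LABELS <- c("background", paste0("L", 1:5),
                       c("L1/L2", "L2/L3", "L3/L4", "L4/L5"))

#' Symmetric normalization with self-loop augmentation
#'
#' Returns D^{-1/2} (A + I) D^{-1/2} with D_ii = sum_j (A + I)_ij.
#'
#' @param A symmetric binary adjacency matrix without self-loops
#' @return normalized adjacency of the same dimension
#' @export
normalize_adjacency <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A) || !isTRUE(all.equal(A, t(A))))
    stop("normalize_adjacency: A must be a symmetric square matrix")
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  dinv * At * rep(dinv, each = nrow(A))
}

#' Build the 10-node lumbar anatomy graph
#'
#' @return object of class `spine_graph` with fields `A` (raw adjacency),
#'   `A_norm` (Eq.-style symmetric normalization), `D` (degree matrix of
#'   A + I), `node_labels`, `edges`
#' @export
build_spine_graph <- function() {
  A <- matrix(0, 10L, 10L, dimnames = list(SPINE_NODE_LABELS,
                                           SPINE_NODE_LABELS))
  for (i in seq_len(nrow(SPINE_EDGES))) {
    a <- SPINE_EDGES[i, 1] + 1L; b <- SPINE_EDGES[i, 2] + 1L
    A[a, b] <- 1; A[b, a] <- 1
  }
  D <- diag(rowSums(A + diag(10L)))
  structure(list(A = A, A_norm = normalize_adjacency(A), D = D,
                 node_labels = SPINE_NODE_LABELS, edges = SPINE_EDGES,
                 n_nodes = 10L), class = "spine_graph")
}

#' @export
print.spine_graph <- function(x, ...) {
  cat("Lumbar spine anatomy graph:", x$n_nodes, "nodes,",
      nrow(x$edges), "undirected edges\n")
  cat("edges (vertebra - disc):",
      paste(sprintf("%s-%s", x$node_labels[x$edges[, 1] + 1L],
                    x$node_labels[x$edges[, 2] + 1L]), collapse = ", "), "\n")
  invisible(x)
}

#' Instantiate the graph enhancement module
#'
#' @param channels bottleneck feature channels C
#' @param h_dim graph node feature width (default 128)
#' @param n_nodes number of graph nodes (default 10)
#' @param seed initialization seed
#' @return module list of class `graph_module`
#' @export
new_graph_module <- function(channels, h_dim = 128L, n_nodes = 10L, seed = 1L) {
  C <- as.integer(channels); H <- as.integer(h_dim)
  with_seed(seed, {
    structure(list(
      channels = C, h_dim = H, n_nodes = as.integer(n_nodes),
      graph = build_spine_graph(),
      w_f2g = init_linear_w(C, n_nodes * H),
      s_w = init_conv_w(n_nodes, C, 1L), s_b = init_zeros(n_nodes),
      gcn_w = lapply(1:3, function(i) init_linear_w(H, H)),
      w_g2f = init_linear_w(H, C)
    ), class = "graph_module")
  })
}

features_to_graph_node <- function(m, f) {
  d <- dim_of(ad_value(f))
  if (d[1] != 1L) stop("graph module supports batch size 1")
  gap <- ad_mean_trailing(f, 2L)                       # (1, C)
  G <- ad_reshape(ad_linear(gap, m$w_f2g), c(m$n_nodes, m$h_dim))
  S <- ad_softmax_ch(ad_conv3d(f, m$s_w, m$s_b))       # (1, nodes, D,H,W)
  list(G = G, S = S)
}

gcn_node <- function(G, A_norm, weights) {
  for (w in weights) G <- ad_relu(ad_matmul(ad_matmul(ad_const(A_norm), G), w))
  G
}

graph_to_features_node <- function(m, G, S, f) {
  d <- dim_of(ad_value(f))
  D <- d[3]; H <- d[4]; W <- d[5]
  Sf <- ad_reshape(ad_aperm(S, c(1, 3, 4, 5, 2)), c(D * H * W, m$n_nodes))
  R <- ad_matmul(ad_matmul(Sf, G), m$w_g2f)            # (DHW, C)
  Rmap <- ad_reshape(ad_aperm(ad_reshape(R, c(D, H, W, d[2])), c(4, 1, 2, 3)),
                     d)
  ad_add(f, Rmap)
}

graph_enhance_node <- function(m, f) {
  fg <- features_to_graph_node(m, f)
  G3 <- gcn_node(fg$G, m$graph$A_norm, m$gcn_w)
  graph_to_features_node(m, G3, fg$S, f)
}

#' Project bottleneck features to graph node embeddings
#'
#' Global average pooling followed by a linear projection to
#' (n_nodes, h_dim) node features, plus a voxel-to-node soft assignment map
#' S (softmax over nodes per voxel) used for back-projection.
#'
#' @param F_ (1,C,D,H,W) bottleneck map
#' @param module a [new_graph_module()], or NULL for a seeded default
#' @param seed seed when `module` is NULL
#' @return list(G = node feature matrix, S = (1, n_nodes, D, H, W) array)
#' @export
features_to_graph <- function(F_, module = NULL, seed = 1L) {
  F_ <- as_feature_map(F_)
  if (is.null(module)) module <- new_graph_module(dim(F_)[2], seed = seed)
  r <- features_to_graph_node(module, ad_const(F_))
  list(G = ad_value(r$G), S = ad_value(r$S))
}

#' Three-layer graph convolution
#'
#' Applies G <- ReLU(A_norm G W_l) for l = 1..3.
#'
#' @param G0 (n_nodes, h_dim) node feature matrix
#' @param A_norm normalized adjacency
#' @param weights list of exactly 3 (h_dim x h_dim) matrices
#' @return updated node feature matrix
#' @export
gcn_forward <- function(G0, A_norm, weights) {
  if (length(weights) != 3L) stop("gcn_forward: exactly 3 layer weights")
  ad_value(gcn_node(ad_const(G0), A_norm,
                    lapply(weights, ad_const)))
}

#' Back-project node features to the voxel grid with a residual
#'
#' Each voxel receives sum_node S[voxel, node] * proj(G[node]), added to F.
#'
#' @param G (n_nodes, h_dim) node features
#' @param S (1, n_nodes, D, H, W) soft assignment from [features_to_graph()]
#' @param F_ original (1,C,D,H,W) map
#' @param w_proj (h_dim x C) projection; identity when h_dim = C, else a
#'   seeded random projection
#' @return (1,C,D,H,W) array
#' @export
graph_to_features <- function(G, S, F_, w_proj = NULL) {
  F_ <- as_feature_map(F_)
  d <- dim(F_)
  if (!identical(dim(S)[c(1, 3, 4, 5)], d[c(1, 3, 4, 5)]))
    stop("graph_to_features: S and F shapes disagree")
  H <- ncol(G)
  if (is.null(w_proj)) {
    w_proj <- if (H == d[2]) diag(H) else with_seed(1L, glorot(c(H, d[2]), H, d[2]))
  }
  m <- list(n_nodes = dim(S)[2], h_dim = H, w_g2f = ad_const(w_proj))
  ad_value(graph_to_features_node(m, ad_const(G), ad_const(S), ad_const(F_)))
}
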