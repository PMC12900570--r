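# State-space sequence layers.
#
# The discrete linear state-space recurrence
#   h_t = A h_{t-1} + B x_t,   y_t = C h_t,   h_0 = 0
# is implemented twice on purpose: `ssm_recurrence()` is the literal
# sequential reference written in plain R (the oracle), and
# `selective_scan()` is the O(T) evaluation used in anger. The network
# blocks additionally use an input-dependent (selective) parameterization
# with per-channel diagonal state and zero-order-hold discretization; see
# tdmamba.R.

#' Bundle LTI state-space parameters
#'
#' @param A state matrix: d_state x d_state matrix, or a length-d_state
#'   vector interpreted as a diagonal, or a scalar
#' @param B input matrix (d_state x d_in), vector or scalar
#' @param C output matrix (d_out x d_state), vector or scalar
#' @return list of class `ssm_params`
#' @export
ssm_params <- function(A, B, C) {
  if (is.null(dim(A))) A <- diag(as.numeric(A), nrow = length(A))
  d_state <- nrow(A)
  if (ncol(A) != d_state) stop("ssm_params: A must be square")
  if (is.null(dim(B))) B <- matrix(as.numeric(B), nrow = d_state)
  if (nrow(B) != d_state) stop("ssm_params: B must have d_state rows")
  if (is.null(dim(C))) C <- matrix(as.numeric(C), ncol = d_state)
  if (ncol(C) != d_state) stop("ssm_params: C must have d_state columns")
  if (!all(is.finite(A), is.finite(B), is.finite(C)))
    stop("ssm_params: parameters must be finite")
  structure(list(A = A, B = B, C = C, d_state = d_state,
                 d_in = ncol(B), d_out = nrow(C)), class = "ssm_params")
}

as_seq_matrix <- function(x, d_in) {
  if (is.null(dim(x))) {
    if (d_in != 1L) stop("ssm: input dimension mismatch")
    x <- matrix(as.numeric(x), nrow = 1L)
  }
  if (nrow(x) != d_in) stop("ssm: input dimension mismatch")
  x
}

#' Literal state-space recurrence (reference implementation)
#'
#' Sequentially iterates h_t = A h_{t-1} + B x_t, y_t = C h_t from h_0 = 0.
#' This is the module's correctness oracle; use [selective_scan()] for
#' anything long.
#'
#' @param params an [ssm_params()]
#' @param x input sequence: (d_in x T) matrix, or a plain vector when
#'   d_in = 1
#' @return (d_out x T) matrix of outputs
#' @export
ssm_recurrence <- function(params, x) {
  stopifnot(inherits(params, "ssm_params"))
  x <- as_seq_matrix(x, params$d_in)
  T_ <- ncol(x)
  if (T_ < 1L) stop("ssm_recurrence: empty sequence")
  h <- matrix(0, params$d_state, 1)
  y <- matrix(0, params$d_out, T_)
  for (t in seq_len(T_)) {
    h <- params$A %*% h + params$B %*% x[, t, drop = FALSE]
    y[, t] <- params$C %*% h
  }
  y
}

#' O(T) evaluation of the state-space recurrence
#'
#' Numerically equivalent to [ssm_recurrence()] (compiled, vectorized over
#' the state dimension) with linear cost in the sequence length.
#'
#' @inheritParams ssm_recurrence
#' @return (d_out x T) matrix
#' @export
selective_scan <- function(params, x) {
  stopifnot(inherits(params, "ssm_params"))
  x <- as_seq_matrix(x, params$d_in)
  if (ncol(x) < 1L) stop("selective_scan: empty sequence")
  .cpp_lti_scan(params$A, params$B, params$C, x)
}

AXIS_CODES <- c(depth = 3L, height = 4L, width = 5L)

#' Flatten a feature map into axis-directed sequences
#'
#' Rearranges a (B,C,D,H,W) array so that the chosen spatial axis becomes
#' the sequence axis; every other position becomes an independent sequence.
#'
#' @param X 5-axis feature map
#' @param axis one of "depth", "height", "width"
#' @param reversed scan the axis in descending order
#' @return list with `seq` ((M, T, C) array) and `unflatten`, a function
#'   mapping an (M, T, C) array back to the original layout
#' @export
directional_flatten <- function(X, axis = c("depth", "height", "width"),
                                reversed = FALSE) {
  axis <- match.arg(axis)
  X <- as_feature_map(X)
  d <- dim(X)
  ax <- AXIS_CODES[[axis]]
  others <- setdiff(3:5, ax)
  perm <- c(1L, others, ax, 2L)
  M <- d[1] * prod(d[others]); T_ <- d[ax]; C <- d[2]
  s <- aperm(X, perm)
  dim(s) <- c(M, T_, C)
  if (reversed) s <- s[, T_:1, , drop = FALSE]
  unflatten <- function(seq_arr) {
    stopifnot(all(dim(seq_arr) == c(M, T_, C)))
    if (reversed) seq_arr <- seq_arr[, T_:1, , drop = FALSE]
    dim(seq_arr) <- c(d[1], d[others], T_, C)
    aperm(seq_arr, order(perm))
  }
  list(seq = s, unflatten = unflatten, axis = axis, reversed = reversed)
}

#' Inverse of [directional_flatten()]
#'
#' @param flat the list returned by [directional_flatten()]
#' @param seq_arr (M, T, C) array (defaults to the flattened input)
#' @return (B,C,D,H,W) array
#' @export
directional_unflatten <- function(flat, seq_arr = flat$seq) {
  flat$unflatten(seq_arr)
}

# tape-level flatten/unflatten used inside network blocks (single-pass
# permutation kernels; the backward of each is the other)
ad_dir_flatten <- function(x, axis) {
  x <- ad_const(x)
  d <- as.integer(dim_of(x$value))
  ax <- AXIS_CODES[[axis]]
  v <- .cpp_dirflat(x$value, d, ax)
  new_ad(v, list(x), function(g) list(.cpp_dirunflat(g, d, ax)))
}

ad_dir_unflatten <- function(s, xdim, axis) {
  s <- ad_const(s)
  d <- as.integer(xdim)
  ax <- AXIS_CODES[[axis]]
  v <- .cpp_dirunflat(s$value, d, ax)
  new_ad(v, list(s), function(g) list(.cpp_dirflat(g, d, ax)))
}
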