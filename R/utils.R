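# Shared helpers: seeded RNG scoping and parameter initialization.

# Run `code` under a temporary RNG state so library calls are reproducible
# without clobbering the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Glorot-uniform initialization for an array with given fan-in/fan-out
glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

# kernel init for conv weights (Cout, Cig, k, k, k)
init_conv_w <- function(cout, cig, k) {
  fan_in <- cig * k^3
  ad_param(glorot(c(cout, cig, k, k, k), fan_in, cout * k^3 / max(1, 1)))
}

init_zeros <- function(dims) ad_param(array(0, dim = dims))

init_linear_w <- function(k_in, k_out) ad_param(glorot(c(k_in, k_out), k_in, k_out))

# recursively collect adtensor parameters from nested module lists
collect_params <- function(x) {
  if (is_ad(x)) return(if (x$requires_grad) list(x) else list())
  if (is.list(x)) return(do.call(c, lapply(unname(x), collect_params)))
  list()
}

as_feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 5L)
    stop("expected a 5-axis (batch, channel, depth, height, width) array")
  if (any(!is.finite(x))) stop("feature map contains non-finite values")
  x
}

check_mask_pair <- function(gt, pred) {
  if (!identical(dim(gt), dim(pred))) stop("mask shapes differ")
  invisible(TRUE)
}
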