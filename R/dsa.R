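# Dynamic sparse attention (DSA).
#
# The bottleneck feature map (H, W, C, N) is projected by a 1x1 convolution,
# flattened to tokens (S = H*W), scored element-wise against a learnable
# external memory unit K, normalized by a softmax over the token axis,
# filtered by a random Bernoulli 0/1 mask with keep-probability p (the
# sparsity ratio), multiplied element-wise by a second memory unit V, and
# projected back by another 1x1 convolution. K and V are sample-independent:
# they are shared across all inputs and learned end-to-end, which lets the
# block model correlations across samples, not only within one image.
#
# Flat features are arrays of dim (S, C, N): tokens x channels x batch.
# Memory units are S x C matrices.

#' Sample a Bernoulli sparsity mask
#'
#' Draws independent 0/1 entries with keep-probability `p`. `p = 1` and
#' `p = 0` return all-ones / all-zeros deterministically.
#'
#' @param dims integer vector of positive extents.
#' @param p keep-probability in `[0, 1]`.
#' @param seed optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return array of 0/1 values with `dim = dims`.
#' @export
#' @examples
#' mean(sample_bernoulli_mask(c(100, 100), 0.9, seed = 1))
sample_bernoulli_mask <- function(dims, p, seed = NULL) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("keep-probability p must be a single value in [0, 1]", call. = FALSE)
  dims <- as.integer(dims)
  if (length(dims) == 0L || any(dims < 1L))
    stop("mask dims must all be positive", call. = FALSE)
  n <- prod(dims)
  draw <- function() {
    if (p == 1) rep(1, n) else if (p == 0) rep(0, n)
    else as.double(stats::rbinom(n, 1L, p))
  }
  v <- if (is.null(seed)) draw() else with_seed(seed, draw())
  array(v, dims)
}

expectation_mask <- function(dims, p) array(p, as.integer(dims))

as_flat <- function(q) {
  if (is.matrix(q)) dim(q) <- c(dim(q), 1L)
  if (length(dim(q)) != 3L)
    stop("flat feature must have dim (S, C, N)", call. = FALSE)
  q
}

# Column-wise softmax over the token axis for (S, C*N)-shaped data.
softmax_tokens <- function(m) {
  S <- nrow(m)
  mx <- apply(m, 2L, max)
  e <- exp(m - rep(mx, each = S))
  e / rep(colSums(e), each = S)
}

#' Element-wise external attention with a sparsity mask
#'
#' Computes, per batch element: scores `M = Q * K` (element-wise), attention
#' `A = softmax(M)` over the token axis, sparse attention `alpha = A * mask`,
#' and output `O = alpha * V`. All products are element-wise; no matrix
#' multiplication is involved.
#'
#' @param q flat feature: array (S, C, N) or matrix (S, C).
#' @param K,V memory units, S x C matrices.
#' @param mask 0/1 (or expectation-valued) mask of dim (S, C, N) or (S, C).
#' @return array of dim (S, C, N) (an attribute `alpha` is not attached; use
#'   the internal API for caches).
#' @export
dsa_attend <- function(q, K, V, mask) {
  dsa_attend_fwd(q, K, V, mask)$out
}

dsa_attend_fwd <- function(q, K, V, mask) {
  q <- as_flat(q)
  mask <- as_flat(mask)
  d <- dim(q)
  if (!identical(dim(K), d[1:2]) || !identical(dim(V), d[1:2]))
    stop("memory units K/V must match the flat feature shape (S, C)",
         call. = FALSE)
  if (!identical(dim(mask), d))
    stop("mask shape must match the flat feature shape", call. = FALSE)
  if (anyNA(q) || any(!is.finite(q)))
    stop("non-finite values in the attention input", call. = FALSE)
  M <- q * c(K)
  dim(M) <- c(d[1], d[2] * d[3])
  A <- softmax_tokens(M)
  dim(A) <- d
  alpha <- A * mask
  out <- alpha * c(V)
  list(out = out, A = A, alpha = alpha, q = q, mask = mask)
}

dsa_attend_bwd <- function(cache, K, V, dout) {
  d <- dim(cache$q)
  dalpha <- dout * c(V)
  dV <- rowSums(dout * cache$alpha, dims = 2L)
  dA <- dalpha * cache$mask
  # softmax jacobian along the token axis, per (channel, sample) column
  A <- cache$A; dim(A) <- c(d[1], d[2] * d[3])
  dAm <- dA; dim(dAm) <- c(d[1], d[2] * d[3])
  dM <- A * (dAm - rep(colSums(dAm * A), each = d[1]))
  dim(dM) <- d
  dq <- dM * c(K)
  dK <- rowSums(dM * cache$q, dims = 2L)
  list(dq = dq, dK = dK, dV = dV)
}

#' Apply the full DSA bottleneck block
#'
#' 1x1 convolution, flatten, masked element-wise external attention,
#' unflatten, 1x1 convolution. Output shape equals input shape. In train
#' mode a fresh Bernoulli mask is drawn for the call; in eval mode the mask
#' is replaced by its expectation (every entry equal to the sparsity ratio),
#' so inference is deterministic.
#'
#' @param model an `hds_model`.
#' @param x bottleneck feature map (H, W, C, N) at the configured resolution.
#' @param mode `"train"` or `"eval"`.
#' @param p sparsity ratio; defaults to the configured value.
#' @param seed optional seed for the train-mode mask draw.
#' @return feature map with the same dim as `x`.
#' @export
dsa_block <- function(model, x, mode = c("eval", "train"), p = NULL,
                      seed = NULL) {
  mode <- match.arg(mode)
  dsa_block_fwd(model$params, model$cfg, as_nchw(x), mode, p, seed)$out
}

dsa_block_fwd <- function(params, cfg, x, mode, p = NULL, seed = NULL,
                          mask = NULL) {
  if (is.null(p)) p <- cfg$sparse_ratio
  d <- dim(x)
  S <- d[1] * d[2]
  if (S != nrow(params$dsa.K))
    stop(sprintf(paste0(
      "DSA memory units were built for %d bottleneck tokens but the feature",
      " map has %dx%d = %d; build the model with input_size = spatial dims",
      " x 16"), nrow(params$dsa.K), d[1], d[2], S), call. = FALSE)
  f <- conv2d_forward(x, params$dsa.conv_in.W, params$dsa.conv_in.b, 1L)
  q <- f
  dim(q) <- c(S, d[3], d[4])
  if (is.null(mask)) {
    mask <- if (mode == "train") sample_bernoulli_mask(dim(q), p, seed)
            else expectation_mask(dim(q), p)
  }
  Keff <- params$dsa.K * params$dsa.sK
  Veff <- params$dsa.V * params$dsa.sV
  at <- dsa_attend_fwd(q, Keff, Veff, mask)
  g <- at$out
  dim(g) <- d
  out <- conv2d_forward(g, params$dsa.conv_out.W, params$dsa.conv_out.b, 1L)
  list(out = out, cache = list(x = x, f = f, at = at, g = g, d = d),
       mask = mask)
}

dsa_block_bwd <- function(params, cache, dout, grads) {
  d <- cache$d
  bo <- conv2d_backward(cache$g, params$dsa.conv_out.W, dout, 1L,
                        has_bias = TRUE)
  grads$add("dsa.conv_out.W", bo$dW)
  grads$add("dsa.conv_out.b", bo$db)
  dg <- bo$dx
  dim(dg) <- c(d[1] * d[2], d[3], d[4])
  Keff <- params$dsa.K * params$dsa.sK
  Veff <- params$dsa.V * params$dsa.sV
  ab <- dsa_attend_bwd(cache$at, Keff, Veff, dg)
  grads$add("dsa.K", ab$dK * params$dsa.sK)
  grads$add("dsa.sK", ab$dK * params$dsa.K)
  grads$add("dsa.V", ab$dV * params$dsa.sV)
  grads$add("dsa.sV", ab$dV * params$dsa.V)
  dq <- ab$dq
  dim(dq) <- d
  bi <- conv2d_backward(cache$x, params$dsa.conv_in.W, dq, 1L,
                        has_bias = TRUE)
  grads$add("dsa.conv_in.W", bi$dW)
  grads$add("dsa.conv_in.b", bi$db)
  bi$dx
}
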