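#' @useDynLib hdsnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Activation tensors throughout the package are numeric arrays with
# dim (H, W, C, N). Conv weights are (C_out) x (C_in*kh*kw) matrices,
# transpose-conv weights (C_out*4) x (C_in); see src/conv_ops.cpp for the
# tap ordering.

as_nchw <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L)
    stop("expected a 4-D array (H, W, C, N)", call. = FALSE)
  x
}

conv2d_forward <- function(x, W, b = NULL, k, stride = 1L, pad = 0L) {
  conv2d_fwd_cpp(as_nchw(x), W, if (is.null(b)) numeric(0) else b,
                 k, k, as.integer(stride), as.integer(pad))
}

conv2d_backward <- function(x, W, dy, k, stride = 1L, pad = 0L,
                            need_dx = TRUE, has_bias = FALSE) {
  conv2d_bwd_cpp(x, W, dy, k, k, as.integer(stride), as.integer(pad),
                 need_dx, has_bias)
}

convt2x2_forward <- function(x, W, b = NULL) {
  convt2x2_fwd_cpp(as_nchw(x), W, if (is.null(b)) numeric(0) else b)
}

convt2x2_backward <- function(x, W, dy, has_bias = FALSE) {
  convt2x2_bwd_cpp(x, W, dy, has_bias)
}

relu_forward <- function(x) x * (x > 0)
relu_backward <- function(dy, x) dy * (x > 0)

sigmoid <- function(z) stats::plogis(z)

# ---- group normalization ----------------------------------------------------
# Normalizes each (sample, channel-group) slab to zero mean / unit variance,
# then applies a per-channel affine. Uses no batch statistics, so outputs are
# independent of batch composition and identical in train and eval mode.

gn_groups_for <- function(channels, max_groups) {
  g <- min(max_groups, channels)
  while (channels %% g != 0L) g <- g - 1L
  g
}

groupnorm_forward <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  cg <- C %/% groups
  m <- x
  dim(m) <- c(H * W * cg, groups * N)
  mu <- colMeans(m)
  va <- colMeans(m * m) - mu * mu
  istd <- 1 / sqrt(va + eps)
  xhat <- (m - rep(mu, each = H * W * cg)) * rep(istd, each = H * W * cg)
  y <- xhat
  dim(y) <- c(H * W * C, N)
  gfull <- rep(gamma, each = H * W)
  bfull <- rep(beta, each = H * W)
  y <- y * gfull + bfull
  dim(y) <- d
  dim(xhat) <- d
  list(y = y, xhat = xhat, istd = istd, dims = d, groups = groups)
}

groupnorm_backward <- function(cache, gamma, dy) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  groups <- cache$groups
  cg <- C %/% groups
  xhat <- cache$xhat
  # per-channel affine grads
  m <- dy * xhat
  dim(m) <- c(H * W, C * N)
  cs <- colSums(m); dim(cs) <- c(C, N)
  dgamma <- rowSums(cs)
  m <- dy
  dim(m) <- c(H * W, C * N)
  cs <- colSums(m); dim(cs) <- c(C, N)
  dbeta <- rowSums(cs)
  # normalized-input grad
  dxhat <- dy
  dim(dxhat) <- c(H * W * C, N)
  dxhat <- dxhat * rep(gamma, each = H * W)
  dim(dxhat) <- c(H * W * cg, groups * N)
  xh <- xhat
  dim(xh) <- c(H * W * cg, groups * N)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xh)
  npg <- H * W * cg
  dx <- (dxhat - rep(m1, each = npg) - xh * rep(m2, each = npg)) *
    rep(cache$istd, each = npg)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- channel concatenation --------------------------------------------------

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (any(da[c(1, 2, 4)] != db[c(1, 2, 4)]))
    stop("cannot concatenate feature maps with different spatial/batch dims",
         call. = FALSE)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_channels <- function(dy, c1) {
  d <- dim(dy)
  list(a = dy[, , seq_len(c1), , drop = FALSE],
       b = dy[, , (c1 + 1):d[3], , drop = FALSE])
}

# ---- weight initialization --------------------------------------------------

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}
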