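# Full network forward and backward passes. Backpropagation is hand-derived
# per layer; gradients are accumulated into a collector environment keyed by
# parameter name, mirroring model$params.

make_grads <- function() {
  e <- new.env(parent = emptyenv())
  e$g <- list()
  e$add <- function(name, val) {
    cur <- e$g[[name]]
    e$g[[name]] <- if (is.null(cur)) val else cur + val
  }
  e
}

conv_gn_relu_fwd <- function(P, cname, gname, x, k, stride, pad, gmax) {
  W <- P[[paste0(cname, ".W")]]
  y <- conv2d_forward(x, W, NULL, k, stride, pad)
  gn <- groupnorm_forward(y, P[[paste0(gname, ".gamma")]],
                          P[[paste0(gname, ".beta")]],
                          gn_groups_for(dim(y)[3], gmax))
  list(y = relu_forward(gn$y), x = x, gn = gn,
       cname = cname, gname = gname, k = k, stride = stride, pad = pad)
}

conv_gn_relu_bwd <- function(P, cache, dy, grads) {
  dgn <- relu_backward(dy, cache$gn$y)
  b <- groupnorm_backward(cache$gn, P[[paste0(cache$gname, ".gamma")]], dgn)
  grads$add(paste0(cache$gname, ".gamma"), b$dgamma)
  grads$add(paste0(cache$gname, ".beta"), b$dbeta)
  cb <- conv2d_backward(cache$x, P[[paste0(cache$cname, ".W")]], b$dx,
                        cache$k, cache$stride, cache$pad)
  grads$add(paste0(cache$cname, ".W"), cb$dW)
  cb$dx
}

# ---- residual bottleneck block ---------------------------------------------

block_fwd <- function(P, pre, x, stride, gmax) {
  g <- function(nm) P[[paste0(pre, ".", nm)]]
  c1 <- conv2d_forward(x, g("conv1.W"), NULL, 1L)
  gn1 <- groupnorm_forward(c1, g("gn1.gamma"), g("gn1.beta"),
                           gn_groups_for(dim(c1)[3], gmax))
  r1 <- relu_forward(gn1$y)
  c2 <- conv2d_forward(r1, g("conv2.W"), NULL, 3L, stride, 1L)
  gn2 <- groupnorm_forward(c2, g("gn2.gamma"), g("gn2.beta"),
                           gn_groups_for(dim(c2)[3], gmax))
  r2 <- relu_forward(gn2$y)
  c3 <- conv2d_forward(r2, g("conv3.W"), NULL, 1L)
  gn3 <- groupnorm_forward(c3, g("gn3.gamma"), g("gn3.beta"),
                           gn_groups_for(dim(c3)[3], gmax))
  down <- !is.null(g("down.conv.W"))
  if (down) {
    cd <- conv2d_forward(x, g("down.conv.W"), NULL, 1L, stride, 0L)
    gnd <- groupnorm_forward(cd, g("down.gn.gamma"), g("down.gn.beta"),
                             gn_groups_for(dim(cd)[3], gmax))
    sc <- gnd$y
  } else {
    gnd <- NULL
    sc <- x
  }
  s <- gn3$y + sc
  list(y = relu_forward(s),
       cache = list(pre = pre, x = x, r1 = r1, r2 = r2, gn1 = gn1,
                    gn2 = gn2, gn3 = gn3, gnd = gnd, s = s,
                    stride = stride, down = down))
}

block_bwd <- function(P, cache, dy, grads) {
  pre <- cache$pre
  g <- function(nm) P[[paste0(pre, ".", nm)]]
  ds <- relu_backward(dy, cache$s)
  b3 <- groupnorm_backward(cache$gn3, g("gn3.gamma"), ds)
  grads$add(paste0(pre, ".gn3.gamma"), b3$dgamma)
  grads$add(paste0(pre, ".gn3.beta"), b3$dbeta)
  cb3 <- conv2d_backward(cache$r2, g("conv3.W"), b3$dx, 1L)
  grads$add(paste0(pre, ".conv3.W"), cb3$dW)
  dgn2 <- relu_backward(cb3$dx, cache$gn2$y)
  b2 <- groupnorm_backward(cache$gn2, g("gn2.gamma"), dgn2)
  grads$add(paste0(pre, ".gn2.gamma"), b2$dgamma)
  grads$add(paste0(pre, ".gn2.beta"), b2$dbeta)
  cb2 <- conv2d_backward(cache$r1, g("conv2.W"), b2$dx, 3L, cache$stride, 1L)
  grads$add(paste0(pre, ".conv2.W"), cb2$dW)
  dgn1 <- relu_backward(cb2$dx, cache$gn1$y)
  b1 <- groupnorm_backward(cache$gn1, g("gn1.gamma"), dgn1)
  grads$add(paste0(pre, ".gn1.gamma"), b1$dgamma)
  grads$add(paste0(pre, ".gn1.beta"), b1$dbeta)
  cb1 <- conv2d_backward(cache$x, g("conv1.W"), b1$dx, 1L)
  grads$add(paste0(pre, ".conv1.W"), cb1$dW)
  dx <- cb1$dx
  if (cache$down) {
    bd <- groupnorm_backward(cache$gnd, g("down.gn.gamma"), ds)
    grads$add(paste0(pre, ".down.gn.gamma"), bd$dgamma)
    grads$add(paste0(pre, ".down.gn.beta"), bd$dbeta)
    cbd <- conv2d_backward(cache$x, g("down.conv.W"), bd$dx, 1L,
                           cache$stride, 0L)
    grads$add(paste0(pre, ".down.conv.W"), cbd$dW)
    dx + cbd$dx
  } else {
    dx + ds
  }
}

# ---- encoder ----------------------------------------------------------------

check_images <- function(x) {
  x <- as_nchw(x)
  if (dim(x)[3] != 3L)
    stop("images must have 3 channels (RGB), got ", dim(x)[3], call. = FALSE)
  x
}

encode_fwd <- function(P, cfg, x) {
  stem <- conv_gn_relu_fwd(P, "stem.conv", "stem.gn", x, 7L, 2L, 3L,
                           cfg$gn_groups)
  mp <- maxpool_fwd_cpp(stem$y, 3L, 2L, 1L)
  h <- mp$y
  stage_stride <- c(1L, 2L, 2L, 1L)
  blocks <- list()
  stage_out <- vector("list", 4L)
  for (s in 1:4) {
    for (b in seq_len(cfg$block_counts[s])) {
      pre <- sprintf("enc%d.b%d", s, b)
      bf <- block_fwd(P, pre, h, if (b == 1L) stage_stride[s] else 1L,
                      cfg$gn_groups)
      h <- bf$y
      blocks[[pre]] <- bf$cache
    }
    stage_out[[s]] <- h
  }
  list(pyr = list(half = stem$y, quarter = stage_out[[1]],
                  eighth = stage_out[[2]], bottleneck = stage_out[[4]]),
       cache = list(stem = stem, mp = mp, stem_dim = dim(stem$y),
                    blocks = blocks))
}

encode_bwd <- function(P, cfg, cache, d_bottleneck, d_skips, grads) {
  # d_skips: list(half, quarter, eighth) gradients (may be NULL)
  dh <- d_bottleneck
  stage_of <- rep(1:4, cfg$block_counts)
  names_all <- names(cache$blocks)
  for (i in rev(seq_along(names_all))) {
    s <- stage_of[i]
    dh <- block_bwd(P, cache$blocks[[names_all[i]]], dh, grads)
    # add skip gradients where decoder branches tap the encoder
    if (i > 1L && stage_of[i - 1L] != s) {
      if (s == 3L && !is.null(d_skips$eighth)) dh <- dh + d_skips$eighth
      if (s == 2L && !is.null(d_skips$quarter)) dh <- dh + d_skips$quarter
    }
  }
  dmp <- maxpool_bwd_cpp(dh, cache$mp$argmax, cache$stem_dim)
  if (!is.null(d_skips$half)) dmp <- dmp + d_skips$half
  conv_gn_relu_bwd(P, cache$stem, dmp, grads)
  invisible(NULL)
}

# ---- decoder ----------------------------------------------------------------

decode_fwd <- function(P, cfg, h, pyr) {
  skips <- list(pyr$eighth, pyr$quarter, pyr$half)
  ups <- list()
  for (i in 1:3) {
    pre <- sprintf("dec%d", i)
    u <- convt2x2_forward(h, P[[paste0(pre, ".convt.W")]])
    cat_in <- concat_channels(u, skips[[i]])
    cg <- conv_gn_relu_fwd(P, paste0(pre, ".conv"), paste0(pre, ".gn"),
                           cat_in, 3L, 1L, 1L, cfg$gn_groups)
    ups[[i]] <- list(h_in = h, u_c = dim(u)[3], cg = cg)
    h <- cg$y
  }
  u4 <- convt2x2_forward(h, P$dec4.convt.W)
  gn4 <- groupnorm_forward(u4, P$dec4.gn.gamma, P$dec4.gn.beta,
                           gn_groups_for(dim(u4)[3], cfg$gn_groups))
  r4 <- relu_forward(gn4$y)
  logits <- conv2d_forward(r4, P$head.conv.W, P$head.conv.b, 1L)
  list(logits = logits,
       cache = list(ups = ups, h3 = h, gn4 = gn4, r4 = r4))
}

decode_bwd <- function(P, cfg, cache, dlogits, grads) {
  cb <- conv2d_backward(cache$r4, P$head.conv.W, dlogits, 1L, has_bias = TRUE)
  grads$add("head.conv.W", cb$dW)
  grads$add("head.conv.b", cb$db)
  dgn4 <- relu_backward(cb$dx, cache$gn4$y)
  b4 <- groupnorm_backward(cache$gn4, P$dec4.gn.gamma, dgn4)
  grads$add("dec4.gn.gamma", b4$dgamma)
  grads$add("dec4.gn.beta", b4$dbeta)
  tb <- convt2x2_backward(cache$h3, P$dec4.convt.W, b4$dx)
  grads$add("dec4.convt.W", tb$dW)
  dh <- tb$dx
  d_skips <- list(half = NULL, quarter = NULL, eighth = NULL)
  skip_names <- c("eighth", "quarter", "half")
  for (i in 3:1) {
    pre <- sprintf("dec%d", i)
    up <- cache$ups[[i]]
    dcat <- conv_gn_relu_bwd(P, up$cg, dh, grads)
    sp <- split_channels(dcat, up$u_c)
    d_skips[[skip_names[i]]] <- sp$b
    tb <- convt2x2_backward(up$h_in, P[[paste0(pre, ".convt.W")]], sp$a)
    grads$add(paste0(pre, ".convt.W"), tb$dW)
    dh <- tb$dx
  }
  list(d_bottleneck = dh, d_skips = d_skips)
}

# ---- full model -------------------------------------------------------------

hds_forward <- function(model, x, mode = "eval", p = NULL, seed = NULL,
                        mask = NULL, want_cache = FALSE) {
  P <- model$params
  cfg <- model$cfg
  x <- check_images(x)
  enc <- encode_fwd(P, cfg, x)
  dsa <- dsa_block_fwd(P, cfg, enc$pyr$bottleneck, mode, p, seed, mask)
  dec <- decode_fwd(P, cfg, dsa$out, enc$pyr)
  if (!want_cache)
    return(list(logits = dec$logits, mask = dsa$mask))
  list(logits = dec$logits, mask = dsa$mask,
       cache = list(enc = enc, dsa = dsa, dec = dec))
}

hds_backward <- function(model, cache, dlogits) {
  P <- model$params
  cfg <- model$cfg
  grads <- make_grads()
  db <- decode_bwd(P, cfg, cache$dec$cache, dlogits, grads)
  d16 <- dsa_block_bwd(P, cache$dsa$cache, db$d_bottleneck, grads)
  encode_bwd(P, cfg, cache$enc$cache, d16, db$d_skips, grads)
  grads$g
}

#' Run the encoder
#'
#' @param model an `hds_model`.
#' @param images array (H, W, 3, N) with values in `[0, 1]`.
#' @return list of feature maps `half`, `quarter`, `eighth` (skip sources)
#'   and `bottleneck` (1/16 resolution, before attention).
#' @export
model_encode <- function(model, images) {
  encode_fwd(model$params, model$cfg, check_images(images))$pyr
}

#' Run the decoder
#'
#' @param model an `hds_model`.
#' @param pyramid list as returned by [model_encode()], with `bottleneck`
#'   already passed through [dsa_block()].
#' @return logits array (H, W, 1, N) at the input resolution.
#' @export
model_decode <- function(model, pyramid) {
  decode_fwd(model$params, model$cfg, pyramid$bottleneck, pyramid)$logits
}

#' Full forward pass
#'
#' Encoder, dynamic sparse attention bottleneck, decoder. In `"train"` mode
#' a fresh Bernoulli mask is drawn inside the attention block; `"eval"` mode
#' substitutes the expectation mask and is fully deterministic.
#'
#' @param model an `hds_model`.
#' @param images array (H, W, 3, N), values in `[0, 1]`.
#' @param mode `"eval"` or `"train"`.
#' @param seed optional seed for the train-mode mask.
#' @return logits array (H, W, 1, N); apply `stats::plogis` for
#'   probabilities.
#' @export
model_forward <- function(model, images, mode = c("eval", "train"),
                          seed = NULL) {
  mode <- match.arg(mode)
  hds_forward(model, images, mode = mode, seed = seed)$logits
}
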