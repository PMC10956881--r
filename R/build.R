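# Architecture layout: a flat list of parameterized layers in forward order.
# Each entry carries the geometry needed for initialization, parameter
# counting and FLOP profiling; `div` is the output resolution divisor
# relative to the network input.

hds_layout <- function(cfg) {
  w <- scaled_widths(cfg)
  S <- bottleneck_tokens(cfg)
  L <- list()
  add <- function(...) L[[length(L) + 1L]] <<- list(...)
  conv <- function(name, cin, cout, k, stride, pad, bias, div)
    add(name = name, kind = "conv", cin = cin, cout = cout, k = k,
        stride = stride, pad = pad, bias = bias, div = div)
  gn <- function(name, channels, div)
    add(name = name, kind = "gn", channels = channels, div = div)

  conv("stem.conv", 3L, w$stem, 7L, 2L, 3L, FALSE, 2L)
  gn("stem.gn", w$stem, 2L)

  stage_stride <- c(1L, 2L, 2L, 1L)  # stage 4 stays at 1/16 (bottleneck)
  stage_div <- c(4L, 8L, 16L, 16L)
  cin <- w$stem
  for (s in 1:4) {
    wid <- w$stages[s]; mid <- w$mids[s]
    div_in <- if (s == 1L) 4L else stage_div[s - 1L]
    for (b in seq_len(cfg$block_counts[s])) {
      p <- sprintf("enc%d.b%d", s, b)
      st <- if (b == 1L) stage_stride[s] else 1L
      din <- if (b == 1L) div_in else stage_div[s]
      conv(paste0(p, ".conv1"), cin, mid, 1L, 1L, 0L, FALSE, din)
      gn(paste0(p, ".gn1"), mid, din)
      conv(paste0(p, ".conv2"), mid, mid, 3L, st, 1L, FALSE, stage_div[s])
      gn(paste0(p, ".gn2"), mid, stage_div[s])
      conv(paste0(p, ".conv3"), mid, wid, 1L, 1L, 0L, FALSE, stage_div[s])
      gn(paste0(p, ".gn3"), wid, stage_div[s])
      if (b == 1L && (cin != wid || st != 1L)) {
        conv(paste0(p, ".down.conv"), cin, wid, 1L, st, 0L, FALSE, stage_div[s])
        gn(paste0(p, ".down.gn"), wid, stage_div[s])
      }
      cin <- wid
    }
  }

  cb <- w$stages[4]
  conv("dsa.conv_in", cb, cb, 1L, 1L, 0L, TRUE, 16L)
  # memory units stored as S x C matrices (one value per channel/token pair)
  add(name = "dsa.K", kind = "mem", dims = c(S, cb))
  add(name = "dsa.sK", kind = "scale", dims = c(S, cb))
  add(name = "dsa.V", kind = "mem", dims = c(S, cb))
  add(name = "dsa.sV", kind = "scale", dims = c(S, cb))
  add(name = "dsa.attend", kind = "dsa_ew", channels = cb, div = 16L)
  conv("dsa.conv_out", cb, cb, 1L, 1L, 0L, TRUE, 16L)

  d <- w$decoder
  skips <- c(w$stages[2], w$stages[1], w$stem)
  up_div <- c(8L, 4L, 2L)
  cin <- cb
  for (i in 1:3) {
    p <- sprintf("dec%d", i)
    add(name = paste0(p, ".convt"), kind = "convt", cin = cin, cout = d[i],
        div = up_div[i])
    conv(paste0(p, ".conv"), d[i] + skips[i], d[i], 3L, 1L, 1L, FALSE,
         up_div[i])
    gn(paste0(p, ".gn"), d[i], up_div[i])
    cin <- d[i]
  }
  add(name = "dec4.convt", kind = "convt", cin = d[3], cout = d[4], div = 1L)
  gn("dec4.gn", d[4], 1L)
  conv("head.conv", d[4], cfg$out_channels, 1L, 1L, 0L, TRUE, 1L)
  L
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Build a segmentation model
#'
#' Instantiates all trainable parameters of the network described by `cfg`:
#' the residual encoder, the dynamic sparse attention bottleneck (including
#' the two external memory units and their element-wise scalings), and the
#' transpose-convolution decoder. Convolution weights use He initialization;
#' group-norm affines start at identity; memory units are drawn from
#' N(0, 0.02) with unit scalings.
#'
#' @param cfg an [hds_config()].
#' @param seed integer seed making the initialization reproducible.
#' @return an object of class `hds_model`: a list with elements `cfg`,
#'   `layout` and `params` (named list of numeric matrices/vectors).
#' @export
#' @examples
#' m <- build_model(hds_config(input_size = c(64, 64), width_scale = 0.125))
#' count_parameters(m)
build_model <- function(cfg, seed = 42L) {
  stopifnot(inherits(cfg, "hds_config"))
  layout <- hds_layout(cfg)
  params <- with_seed(seed, {
    p <- list()
    for (l in layout) {
      switch(l$kind,
        conv = {
          fan_in <- l$cin * l$k^2
          p[[paste0(l$name, ".W")]] <- he_init(l$cout, fan_in, fan_in)
          if (l$bias) p[[paste0(l$name, ".b")]] <- numeric(l$cout)
        },
        convt = {
          p[[paste0(l$name, ".W")]] <- he_init(l$cout * 4L, l$cin, l$cin)
        },
        gn = {
          p[[paste0(l$name, ".gamma")]] <- rep(1, l$channels)
          p[[paste0(l$name, ".beta")]] <- numeric(l$channels)
        },
        mem = {
          p[[l$name]] <- matrix(stats::rnorm(prod(l$dims), sd = 0.02),
                                l$dims[1], l$dims[2])
        },
        scale = {
          p[[l$name]] <- matrix(1, l$dims[1], l$dims[2])
        },
        dsa_ew = NULL)
    }
    p
  })
  structure(list(cfg = cfg, layout = layout, params = params),
            class = "hds_model")
}

#' Number of trainable parameters
#'
#' @param model an `hds_model`.
#' @return integer count of trainable scalars.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "hds_model"))
  sum(vapply(model$params, length, numeric(1)))
}

#' Forward-pass cost in multiply-accumulate operations
#'
#' Counts the MACs of all convolution, transpose-convolution and attention
#' operations for one image at the given input size, following the
#' convention of common profilers: a k x k convolution costs
#' `k^2 * C_in * C_out` MACs per output pixel; normalization, pooling,
#' activations and biases are not counted. The three element-wise products
#' of the attention bottleneck contribute `3 * C * S` multiplies.
#'
#' @param model an `hds_model` (or an `hds_config`).
#' @param input_size integer (H, W); defaults to the configured size.
#' @return total MAC count (a double; divide by 1e9 for the usual "GFLOPs").
#' @export
count_flops <- function(model, input_size = NULL) {
  cfg <- if (inherits(model, "hds_model")) model$cfg else model
  stopifnot(inherits(cfg, "hds_config"))
  if (is.null(input_size)) input_size <- cfg$input_size
  H <- input_size[1]; W <- input_size[2]
  if (any(c(H, W) %% 16 != 0))
    stop("input size must be divisible by 16", call. = FALSE)
  total <- 0
  for (l in hds_layout(cfg)) {
    px <- (H / l$div) * (W / l$div)
    total <- total + switch(l$kind,
      conv = l$k^2 * l$cin * l$cout * px,
      convt = l$cin * l$cout * px,   # kernel 2 stride 2: one tap per output px
      dsa_ew = 3 * l$channels * px,
      0)
  }
  total
}
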