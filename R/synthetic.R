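# Synthetic dermoscopy generator. Emulates the features that make skin
# lesion segmentation hard: irregular star-convex lesion shapes, blurred
# lesion/skin boundaries, size variation, and hair-like curvilinear clutter.
# Every sample is deterministic given its seed, and the binary mask is the
# exact (un-blurred) lesion support.

#' Parameters of the synthetic lesion generator
#'
#' @param image_size integer (H, W) of generated images.
#' @param n_control_points number of radial control points of the lesion
#'   contour (more points, more irregular outlines).
#' @param radial_noise relative amplitude of the radial perturbation.
#' @param boundary_blur_sigma Gaussian blur (pixels) applied to the lesion
#'   alpha channel; 0 gives hard boundaries.
#' @param lesion_color,skin_color RGB means in `[0, 1]`.
#' @param color_jitter s.d. of the per-sample color perturbation.
#' @param hair_count integer range (min, max) of hair strokes per image.
#' @param hair_thickness range (pixels) of hair stroke radii.
#' @param area_fraction range of the lesion area as a fraction of the image;
#'   must lie inside (0, 0.9).
#' @return list of class `lesion_params`.
#' @export
lesion_params <- function(image_size = c(128, 128),
                          n_control_points = 12,
                          radial_noise = 0.3,
                          boundary_blur_sigma = 1.5,
                          lesion_color = c(0.36, 0.22, 0.18),
                          skin_color = c(0.82, 0.64, 0.56),
                          color_jitter = 0.05,
                          hair_count = c(0, 5),
                          hair_thickness = c(0.6, 1.4),
                          area_fraction = c(0.05, 0.4)) {
  if (any(area_fraction <= 0) || any(area_fraction >= 0.9) ||
      diff(area_fraction) <= 0)
    stop("area_fraction must be a non-degenerate range inside (0, 0.9)",
         call. = FALSE)
  if (boundary_blur_sigma < 0) stop("blur sigma must be >= 0", call. = FALSE)
  if (n_control_points < 3) stop("need at least 3 control points",
                                 call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 n_control_points = as.integer(n_control_points),
                 radial_noise = radial_noise,
                 boundary_blur_sigma = boundary_blur_sigma,
                 lesion_color = lesion_color, skin_color = skin_color,
                 color_jitter = color_jitter,
                 hair_count = as.integer(hair_count),
                 hair_thickness = hair_thickness,
                 area_fraction = area_fraction),
            class = "lesion_params")
}

# star-convex lesion mask from periodic radial noise
lesion_mask <- function(params, target_frac, cx, cy, radii_f) {
  H <- params$image_size[1]; W <- params$image_size[2]
  k <- params$n_control_points
  ang <- seq(0, 2 * pi, length.out = k + 1L)
  f <- c(radii_f, radii_f[1])
  rfun <- stats::splinefun(ang, f, method = "periodic")
  gx <- matrix(rep(seq_len(W), each = H), H, W)
  gy <- matrix(rep(seq_len(H), W), H, W)
  th <- atan2(gy - cy, gx - cx) %% (2 * pi)
  dd <- sqrt((gx - cx)^2 + (gy - cy)^2)
  r0 <- sqrt(target_frac * H * W / pi)
  mask <- NULL
  for (try in 1:8) {
    mask <- (dd <= r0 * rfun(th)) * 1
    ach <- mean(mask)
    if (ach >= params$area_fraction[1] && ach <= params$area_fraction[2])
      return(mask)
    if (ach <= 0) r0 <- r0 * 1.5
    else r0 <- r0 * sqrt(target_frac / ach)
  }
  stop("could not realize a lesion within the requested area_fraction range",
       call. = FALSE)
}

smooth_noise <- function(H, W, sigma, amp) {
  n <- matrix(stats::rnorm(H * W), H, W)
  amp * as.matrix(EBImage::gblur(n, sigma = sigma)) * sigma
}

draw_hairs <- function(img, params) {
  H <- nrow(img[, , 1]); W <- ncol(img[, , 1])
  n <- sample(seq(params$hair_count[1], params$hair_count[2]), 1L)
  if (n == 0) return(img)
  for (i in seq_len(n)) {
    # quadratic Bezier spanning the image with a bowed control point
    p0 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
    p2 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
    mid <- (p0 + p2) / 2 + stats::rnorm(2, sd = 0.25 * sqrt(H * W))
    t <- seq(0, 1, length.out = 4L * max(H, W))
    py <- (1 - t)^2 * p0[1] + 2 * t * (1 - t) * mid[1] + t^2 * p2[1]
    px <- (1 - t)^2 * p0[2] + 2 * t * (1 - t) * mid[2] + t^2 * p2[2]
    thick <- stats::runif(1, params$hair_thickness[1],
                          params$hair_thickness[2])
    shade <- stats::runif(1, 0.05, 0.25)
    rad <- max(0L, floor(thick - 0.5))
    off <- expand.grid(dy = -rad:rad, dx = -rad:rad)
    off <- off[off$dy^2 + off$dx^2 <= thick^2, , drop = FALSE]
    ys <- round(rep(py, nrow(off)) + rep(off$dy, each = length(py)))
    xs <- round(rep(px, nrow(off)) + rep(off$dx, each = length(px)))
    keep <- ys >= 1 & ys <= H & xs >= 1 & xs <= W
    idx <- unique(ys[keep] + (xs[keep] - 1L) * H)
    for (c in 1:3) {
      ch <- img[, , c]
      ch[idx] <- 0.15 * ch[idx] + 0.85 * shade
      img[, , c] <- ch
    }
  }
  img
}

#' Generate one synthetic lesion image with its exact mask
#'
#' The lesion is a star-convex polygon: radii at equally spaced angles are
#' perturbed multiplicatively and interpolated with a periodic spline. The
#' lesion is alpha-blended over a textured skin background with a Gaussian-
#' blurred boundary; hair strokes are drawn last so they occlude the lesion,
#' as in real dermoscopy. The returned mask is the un-blurred lesion
#' support.
#'
#' @param params a [lesion_params()] object.
#' @param seed integer seed; the same seed reproduces the sample exactly.
#' @return list with `image` (H, W, 3 array in `[0, 1]`) and `mask`
#'   (H x W binary matrix).
#' @export
#' @examples
#' s <- generate_sample(lesion_params(image_size = c(64, 64)), seed = 1)
#' range(s$image); mean(s$mask)
generate_sample <- function(params, seed) {
  stopifnot(inherits(params, "lesion_params"))
  with_seed(as.integer(seed), {
    H <- params$image_size[1]; W <- params$image_size[2]
    target <- stats::runif(1, params$area_fraction[1],
                           params$area_fraction[2])
    cx <- W / 2 + stats::runif(1, -0.12, 0.12) * W
    cy <- H / 2 + stats::runif(1, -0.12, 0.12) * H
    f <- pmax(0.35, 1 + params$radial_noise *
                stats::rnorm(params$n_control_points))
    mask <- lesion_mask(params, target, cx, cy, f)
    alpha <- if (params$boundary_blur_sigma > 0)
      as.matrix(EBImage::gblur(mask, sigma = params$boundary_blur_sigma))
    else mask
    alpha <- pmin(pmax(alpha, 0), 1)
    skin <- params$skin_color + stats::rnorm(3, sd = params$color_jitter)
    les <- params$lesion_color + stats::rnorm(3, sd = params$color_jitter)
    tex <- smooth_noise(H, W, sigma = max(2, round(min(H, W) / 16)),
                        amp = 0.015)
    img <- array(0, c(H, W, 3))
    for (c in 1:3) {
      base <- skin[c] + tex + stats::rnorm(H * W, sd = 0.008)
      img[, , c] <- base * (1 - alpha) + (les[c] + tex) * alpha
    }
    img <- draw_hairs(img, params)
    img <- pmin(pmax(img, 0), 1)
    list(image = img, mask = mask)
  })
}

#' Generate a dataset on disk in the ISIC challenge layout
#'
#' Writes `ISIC_<k>.jpg` images and `ISIC_<k>_segmentation.png` masks plus a
#' JSON manifest recording per-sample seeds, so any mask can be regenerated
#' byte-identically.
#'
#' @param n number of samples.
#' @param params a [lesion_params()] object.
#' @param out_dir output directory (created if missing).
#' @param seed base seed; sample k uses `seed + k`.
#' @return (invisibly) the manifest as a data frame with columns `id`,
#'   `image`, `mask`, `seed`.
#' @export
generate_dataset <- function(n, params, out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("ISIC_%07d", seq_len(n))
  manifest <- data.frame(id = ids,
                         image = paste0(ids, ".jpg"),
                         mask = paste0(ids, "_segmentation.png"),
                         seed = seed + seq_len(n))
  for (k in seq_len(n)) {
    s <- generate_sample(params, manifest$seed[k])
    EBImage::writeImage(EBImage::Image(aperm(s$image, c(2, 1, 3)),
                                       colormode = "Color"),
                        file.path(out_dir, manifest$image[k]), quality = 95)
    png::writePNG(s$mask, file.path(out_dir, manifest$mask[k]))
  }
  jsonlite::write_json(list(seed = seed, n = n, samples = manifest),
                       file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(manifest)
}
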