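# ISIC-layout dataset access: images `ISIC_<id>.jpg` (or .png) paired with
# masks `ISIC_<id>_segmentation.png`, a reproducible 8:2 split, and batch
# loading at the network input size.

#' Index an ISIC-layout dataset directory
#'
#' Pairs images with masks by the `ISIC_<id>` stem. Images without a mask
#' (or masks without an image) are not silently dropped: they are reported
#' in the `exclusions` attribute.
#'
#' @param image_dir directory containing the images.
#' @param mask_dir directory containing the masks (defaults to `image_dir`).
#' @return data frame of class `hds_index` with columns `id`, `image_path`,
#'   `mask_path`; unmatched files in `attr(, "exclusions")`.
#' @export
index_dataset <- function(image_dir, mask_dir = image_dir) {
  if (!dir.exists(image_dir)) stop("image_dir does not exist", call. = FALSE)
  if (!dir.exists(mask_dir)) stop("mask_dir does not exist", call. = FALSE)
  imgs <- list.files(image_dir, pattern = "^ISIC_.*\\.(jpg|jpeg|png)$",
                     ignore.case = TRUE)
  imgs <- imgs[!grepl("_segmentation", imgs)]
  masks <- list.files(mask_dir, pattern = "^ISIC_.*_segmentation\\.png$",
                      ignore.case = TRUE)
  img_ids <- sub("\\.(jpg|jpeg|png)$", "", imgs, ignore.case = TRUE)
  mask_ids <- sub("_segmentation\\.png$", "", masks, ignore.case = TRUE)
  if (anyDuplicated(img_ids) || anyDuplicated(mask_ids))
    stop("duplicate ISIC ids found in dataset directory", call. = FALSE)
  common <- intersect(img_ids, mask_ids)
  excl <- c(setdiff(img_ids, mask_ids), setdiff(mask_ids, img_ids))
  idx <- data.frame(id = sort(common),
                    image_path = file.path(image_dir,
                                           imgs[match(sort(common), img_ids)]),
                    mask_path = file.path(mask_dir,
                                          masks[match(sort(common), mask_ids)]),
                    stringsAsFactors = FALSE)
  attr(idx, "exclusions") <- excl
  class(idx) <- c("hds_index", "data.frame")
  idx
}

#' Random train/test split
#'
#' Deterministic given the seed and a pure function of the id set: records
#' are sorted by id before permuting, so the partition does not depend on
#' directory listing order. The train size is `floor(ratio * N)`.
#'
#' @param index an `hds_index` (see [index_dataset()]).
#' @param ratio train fraction (default 0.8).
#' @param seed split seed.
#' @return the index with an added `split` column (`"train"` / `"test"`).
#' @export
split_dataset <- function(index, ratio = 0.8, seed = 1L) {
  index <- index[order(index$id), , drop = FALSE]
  n <- nrow(index)
  n_train <- floor(ratio * n)
  perm <- with_seed(as.integer(seed), sample.int(n))
  split <- rep("test", n)
  split[perm[seq_len(n_train)]] <- "train"
  index$split <- split
  attr(index, "split_seed") <- seed
  class(index) <- c("hds_index", "data.frame")
  index
}

read_rgb <- function(path) {
  img <- try(EBImage::readImage(path), silent = TRUE)
  if (inherits(img, "try-error"))
    stop("could not read image file: ", path, call. = FALSE)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  a  # (x, y, c) in [0, 1]
}

#' Load a batch of image/mask pairs at the network input size
#'
#' Images are bilinearly resized and kept in `[0, 1]`; masks are resized
#' with nearest-neighbor interpolation and re-binarized at 0.5 (ISIC masks
#' are 0/255 PNGs).
#'
#' @param records rows of an `hds_index` (columns `image_path`, `mask_path`).
#' @param input_size integer (H, W), default `c(224, 224)`.
#' @return list with `images` (H, W, 3, N) and `masks` (H, W, 1, N).
#' @export
load_batch <- function(records, input_size = c(224, 224)) {
  n <- nrow(records)
  H <- input_size[1]; W <- input_size[2]
  images <- array(0, c(H, W, 3L, n))
  masks <- array(0, c(H, W, 1L, n))
  for (i in seq_len(n)) {
    a <- read_rgb(records$image_path[i])
    a <- EBImage::resize(a, w = W, h = H)           # bilinear
    images[, , , i] <- aperm(a, c(2, 1, 3))
    m <- try(png::readPNG(records$mask_path[i]), silent = TRUE)
    if (inherits(m, "try-error"))
      stop("could not read mask file: ", records$mask_path[i], call. = FALSE)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m <- EBImage::resize(t(m), w = W, h = H, filter = "none")
    masks[, , 1L, i] <- (t(m) > 0.5) * 1
  }
  list(images = pmin(pmax(images, 0), 1), masks = masks)
}
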