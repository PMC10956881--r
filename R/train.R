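# SGD training on the compound Dice + cross-entropy loss, with evaluation,
# the sparsity-ratio sweep protocol, and checkpointing.

#' Training configuration
#'
#' Defaults: SGD with initial learning rate 0.01, momentum 0.9, weight decay
#' 1e-4, batch size 24, 300 epochs. The learning rate is constant (no
#' schedule); `lr_schedule` is a hook taking `(lr, epoch)` and returning the
#' epoch's learning rate, identity by default.
#'
#' @param lr learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty coefficient applied to all parameters.
#' @param batch_size minibatch size.
#' @param epochs number of passes over the training set.
#' @param seed master seed; weight init, shuffling and mask draws all derive
#'   from it.
#' @param lr_schedule optional `function(lr, epoch)`.
#' @return list of class `hds_train_config`.
#' @export
train_config <- function(lr = 0.01, momentum = 0.9, weight_decay = 1e-4,
                         batch_size = 24L, epochs = 300L, seed = 1L,
                         lr_schedule = NULL) {
  stopifnot(lr >= 0, batch_size >= 1, epochs >= 1)
  structure(list(lr = lr, momentum = momentum, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 lr_schedule = lr_schedule),
            class = "hds_train_config")
}

sgd_update <- function(params, grads, vel, lr, momentum, wd) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(dim(params[[nm]]))) g <- as.vector(g)
    g <- g + wd * params[[nm]]
    v <- vel[[nm]]
    v <- if (is.null(v)) g else momentum * v + g
    vel[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * v
  }
  list(params = params, vel = vel)
}

batch_loss_and_grads <- function(model, images, masks, mask_seed) {
  fw <- hds_forward(model, images, mode = "train", seed = mask_seed,
                    want_cache = TRUE)
  probs <- sigmoid(fw$logits)
  loss <- combined_loss(probs, masks)
  dprob <- combined_loss_grad(probs, masks)
  dlogits <- dprob * probs * (1 - probs)
  grads <- hds_backward(model, fw$cache, dlogits)
  list(loss = loss, grads = grads, probs = probs)
}

#' Train a model with minibatch SGD
#'
#' Optimizes the compound Dice + binary cross-entropy loss. All randomness
#' (shuffling, Bernoulli attention masks) is derived from the configured
#' seed, so a run is bit-reproducible on one CPU. Training aborts with a
#' diagnostic if the loss becomes non-finite.
#'
#' @param model an `hds_model` (see [build_model()]).
#' @param data list with `images` (H, W, 3, N) and `masks` (H, W, 1, N),
#'   e.g. from [load_batch()].
#' @param train_cfg an [train_config()].
#' @param max_steps optional cap on optimizer steps (overrides `epochs`
#'   when reached first); useful for short CPU runs.
#' @param eval_data optional held-out list like `data`; when given, Dice is
#'   evaluated on it after every epoch and the best-Dice parameters are
#'   retained in the result.
#' @param verbose print per-epoch progress.
#' @return list with `model` (final parameters), `best_model` (best
#'   held-out Dice, or final if no `eval_data`), `history` (one row per
#'   step: epoch, step, lr, loss and terms, batch train Dice) and
#'   `eval_history`.
#' @export
hds_train <- function(model, data, train_cfg = train_config(),
                      max_steps = NULL, eval_data = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "hds_model"),
            inherits(train_cfg, "hds_train_config"))
  n <- dim(data$images)[4]
  if (is.null(n) || n < 1) stop("empty training set", call. = FALSE)
  vel <- list()
  step <- 0L
  hist <- list()
  eval_hist <- list()
  best <- list(dice = -Inf, params = NULL)
  done <- FALSE
  for (epoch in seq_len(train_cfg$epochs)) {
    lr <- if (is.null(train_cfg$lr_schedule)) train_cfg$lr
          else train_cfg$lr_schedule(train_cfg$lr, epoch)
    ord <- with_seed((train_cfg$seed + epoch) %% .Machine$integer.max,
                     sample.int(n))
    starts <- seq(1L, n, by = train_cfg$batch_size)
    for (st in starts) {
      sel <- ord[st:min(st + train_cfg$batch_size - 1L, n)]
      step <- step + 1L
      mask_seed <- (train_cfg$seed + 7919L * step) %% .Machine$integer.max
      bl <- batch_loss_and_grads(
        model,
        data$images[, , , sel, drop = FALSE],
        data$masks[, , , sel, drop = FALSE],
        mask_seed)
      if (!is.finite(bl$loss$total))
        stop(sprintf("non-finite loss at step %d (dice=%g, bce=%g)",
                     step, bl$loss$dice_term, bl$loss$bce_term),
             call. = FALSE)
      upd <- sgd_update(model$params, bl$grads, vel, lr,
                        train_cfg$momentum, train_cfg$weight_decay)
      model$params <- upd$params
      vel <- upd$vel
      bdice <- seg_metrics(confusion(
        binarize(bl$probs, model$cfg$threshold),
        data$masks[, , , sel, drop = FALSE]))$dice
      hist[[step]] <- data.frame(epoch = epoch, step = step, lr = lr,
                                 loss = bl$loss$total,
                                 dice_term = bl$loss$dice_term,
                                 bce_term = bl$loss$bce_term,
                                 batch_dice = bdice)
      if (!is.null(max_steps) && step >= max_steps) { done <- TRUE; break }
    }
    if (!is.null(eval_data)) {
      ev <- hds_evaluate(model, eval_data$images, eval_data$masks)
      eval_hist[[length(eval_hist) + 1L]] <-
        data.frame(epoch = epoch, step = step, dice = ev$summary$dice,
                   iou = ev$summary$iou)
      if (ev$summary$dice > best$dice)
        best <- list(dice = ev$summary$dice, params = model$params)
    }
    if (verbose)
      message(sprintf("epoch %d/%d step %d loss %.4f", epoch,
                      train_cfg$epochs, step, hist[[step]]$loss))
    if (done) break
  }
  best_model <- model
  if (!is.null(best$params)) best_model$params <- best$params
  list(model = model, best_model = best_model,
       history = do.call(rbind, hist),
       eval_history = if (length(eval_hist)) do.call(rbind, eval_hist))
}

#' Evaluate a model on image/mask arrays
#'
#' Runs deterministic (expectation-mask) forward passes, binarizes at the
#' configured threshold, and reports Dice/IoU/sensitivity/specificity per
#' image plus their means over images (metrics are averaged per image, not
#' pooled over pixels).
#'
#' @param model an `hds_model`.
#' @param images array (H, W, 3, N).
#' @param masks array (H, W, 1, N) of 0/1.
#' @param batch_size forward-pass batch size.
#' @param csv,json optional paths; when given, the per-image table (plus a
#'   `mean` summary row) is written as CSV and/or JSON.
#' @return list with `per_image` (data frame) and `summary` (named list of
#'   mean metrics).
#' @export
hds_evaluate <- function(model, images, masks, batch_size = 8L,
                         csv = NULL, json = NULL) {
  n <- dim(images)[4]
  rows <- vector("list", n)
  for (st in seq(1L, n, by = batch_size)) {
    sel <- st:min(st + batch_size - 1L, n)
    logits <- model_forward(model, images[, , , sel, drop = FALSE])
    probs <- sigmoid(logits)
    for (j in seq_along(sel)) {
      i <- sel[j]
      cm <- confusion(binarize(probs[, , , j], model$cfg$threshold),
                      masks[, , 1L, i])
      met <- seg_metrics(cm)
      rows[[i]] <- data.frame(image = i, dice = met$dice, iou = met$iou,
                              sen = met$sen, spe = met$spe)
    }
  }
  per_image <- do.call(rbind, rows)
  summary <- as.list(colMeans(per_image[, c("dice", "iou", "sen", "spe")]))
  out <- rbind(per_image,
               data.frame(image = NA, dice = summary$dice, iou = summary$iou,
                          sen = summary$sen, spe = summary$spe))
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(list(per_image = per_image, summary = summary),
                         json, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  list(per_image = per_image, summary = summary)
}

#' Sparsity-ratio ablation sweep
#'
#' Re-runs the train/evaluate protocol once per sparsity ratio and tabulates
#' mean test Dice and IoU against the ratio, mirroring the ablation design
#' used to select the default ratio of 0.9. Model initialization and data
#' are identical across ratios; only the Bernoulli keep-probability changes.
#'
#' @param ratios numeric vector of keep-probabilities in `[0, 1]`.
#' @param model_cfg an [hds_config()] (its `sparse_ratio` is overridden).
#' @param train_cfg an [train_config()].
#' @param train_data,test_data lists with `images`/`masks` arrays.
#' @param max_steps optional step cap per ratio.
#' @param init_seed weight-init seed shared by all runs.
#' @param csv optional output path for the table.
#' @return data frame with columns `ratio`, `dice`, `iou`.
#' @export
hds_sweep <- function(ratios, model_cfg, train_cfg, train_data, test_data,
                      max_steps = NULL, init_seed = 42L, csv = NULL) {
  rows <- lapply(ratios, function(r) {
    cfg <- model_cfg
    cfg$sparse_ratio <- r
    model <- build_model(cfg, seed = init_seed)
    tr <- hds_train(model, train_data, train_cfg, max_steps = max_steps)
    ev <- hds_evaluate(tr$model, test_data$images, test_data$masks)
    data.frame(ratio = r, dice = ev$summary$dice, iou = ev$summary$iou)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  tab
}

#' Predict binary masks for image files
#'
#' Images are resized to the model's input size for the forward pass; the
#' probability map is bilinearly resized back to the original resolution
#' before thresholding, so output masks match the input images pixel for
#' pixel. Masks are written as 0/255 PNG files named `<stem>_segmentation.png`.
#'
#' @param model an `hds_model`.
#' @param image_paths character vector of image files.
#' @param out_dir output directory.
#' @param threshold binarization cutoff (defaults to the configured one).
#' @return (invisibly) character vector of written mask paths.
#' @export
hds_predict <- function(model, image_paths, out_dir,
                        threshold = model$cfg$threshold) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  H <- model$cfg$input_size[1]; W <- model$cfg$input_size[2]
  outs <- character(length(image_paths))
  for (i in seq_along(image_paths)) {
    a <- read_rgb(image_paths[i])              # (x, y, c)
    ow <- dim(a)[1]; oh <- dim(a)[2]
    r <- EBImage::resize(a, w = W, h = H)
    x <- array(aperm(r, c(2, 1, 3)), c(H, W, 3, 1))
    probs <- sigmoid(model_forward(model, x))[, , 1, 1]
    back <- EBImage::resize(t(probs), w = ow, h = oh)   # back to (x, y)
    mask <- (t(back) > threshold) * 1
    stem <- sub("\\.[A-Za-z]+$", "", basename(image_paths[i]))
    outs[i] <- file.path(out_dir, paste0(stem, "_segmentation.png"))
    png::writePNG(mask, outs[i])
  }
  invisible(outs)
}

#' Save / load a checkpoint
#'
#' A checkpoint is a single RDS file holding the configuration, parameters
#' and (optionally) the training history.
#'
#' @param model an `hds_model`.
#' @param path file path.
#' @param history optional training history to embed.
#' @export
save_checkpoint <- function(model, path, history = NULL) {
  saveRDS(list(cfg = unclass(model$cfg), params = model$params,
               history = history, package_version = "hdsnet"), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns an `hds_model` with the stored history
#'   in `attr(, "history")`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$cfg) || is.null(obj$params))
    stop("not a valid checkpoint file: ", path, call. = FALSE)
  cfg <- do.call(hds_config, obj$cfg[setdiff(names(obj$cfg), NULL)])
  model <- structure(list(cfg = cfg, layout = hds_layout(cfg),
                          params = obj$params), class = "hds_model")
  attr(model, "history") <- obj$history
  model
}

#' Print a parameter / FLOP profile of a configuration
#'
#' @param cfg an [hds_config()].
#' @return (invisibly) list with `parameters` and `macs`.
#' @export
hds_summary <- function(cfg = hds_config()) {
  model <- build_model(cfg, seed = 0L)
  p <- count_parameters(model)
  f <- count_flops(model)
  w <- scaled_widths(cfg)
  cat(sprintf("input size      : %d x %d\n", cfg$input_size[1],
              cfg$input_size[2]))
  cat(sprintf("encoder widths  : stem %d | stages %s\n", w$stem,
              paste(w$stages, collapse = "/")))
  cat(sprintf("decoder widths  : %s\n", paste(w$decoder, collapse = "/")))
  cat(sprintf("sparsity ratio  : %.2f\n", cfg$sparse_ratio))
  cat(sprintf("parameters      : %.2f M (%d)\n", p / 1e6, p))
  cat(sprintf("forward MACs    : %.2f G\n", f / 1e9))
  invisible(list(parameters = p, macs = f))
}
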