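small_train_fixture <- function() {
  memo("small_train_fixture", {
    d <- tiny_dataset()
    sub <- list(images = d$images[, , , 1:4, drop = FALSE],
                masks = d$masks[, , , 1:4, drop = FALSE])
    list(data = sub, model = build_model(tiny_cfg(), seed = 7))
  })
}

test_that("a zero learning rate leaves the weights unchanged", {
  fx <- small_train_fixture()
  tc <- train_config(lr = 0, epochs = 1, batch_size = 4, seed = 1)
  tr <- hds_train(fx$model, fx$data, tc)
  expect_identical(tr$model$params, fx$model$params)
})

test_that("training is bit-reproducible given the seeds", {
  fx <- small_train_fixture()
  tc <- train_config(epochs = 2, batch_size = 2, seed = 3)
  t1 <- hds_train(fx$model, fx$data, tc)
  t2 <- hds_train(fx$model, fx$data, tc)
  expect_identical(t1$history$loss, t2$history$loss)
  expect_identical(t1$model$params, t2$model$params)
  t3 <- hds_train(fx$model, fx$data, train_config(epochs = 2, batch_size = 2,
                                                  seed = 4))
  expect_false(identical(t1$history$loss, t3$history$loss))
})

test_that("training descends the loss and respects max_steps", {
  fx <- small_train_fixture()
  tc <- train_config(epochs = 50, batch_size = 4, seed = 1)
  tr <- hds_train(fx$model, fx$data, tc, max_steps = 12)
  expect_equal(nrow(tr$history), 12)
  expect_lt(tr$history$loss[12], tr$history$loss[1])
})

test_that("training defaults mirror the published optimizer settings", {
  tc <- train_config()
  expect_equal(tc$lr, 0.01)
  expect_equal(tc$momentum, 0.9)
  expect_equal(tc$weight_decay, 1e-4)
  expect_equal(tc$batch_size, 24L)
  expect_equal(tc$epochs, 300L)
})

test_that("evaluation reports per-image rows plus a summary and is deterministic", {
  fx <- small_train_fixture()
  csv <- tempfile(fileext = ".csv")
  ev <- hds_evaluate(fx$model, fx$data$images, fx$data$masks, csv = csv)
  expect_equal(nrow(ev$per_image), 4)
  expect_true(all(unlist(ev$summary) >= 0 & unlist(ev$summary) <= 1))
  tab <- utils::read.csv(csv)
  expect_equal(nrow(tab), 5)             # per-image rows + summary row
  ev2 <- hds_evaluate(fx$model, fx$data$images, fx$data$masks)
  expect_identical(ev$per_image, ev2$per_image)
})

test_that("checkpoints round-trip the model", {
  fx <- small_train_fixture()
  f <- tempfile(fileext = ".rds")
  save_checkpoint(fx$model, f, history = data.frame(step = 1, loss = 0.5))
  m2 <- load_checkpoint(f)
  x <- tiny_images(1)
  expect_identical(model_forward(fx$model, x), model_forward(m2, x))
  expect_equal(attr(m2, "history")$loss, 0.5)
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_checkpoint(bad), "checkpoint")
})

test_that("prediction writes binary PNG masks at the original resolution", {
  fx <- small_train_fixture()
  idx <- index_dataset(tiny_dataset_dir())
  out <- withr::local_tempdir()
  paths <- hds_predict(fx$model, idx$image_path[1:3], out)
  expect_length(paths, 3)
  expect_true(all(file.exists(paths)))
  expect_identical(basename(paths),
                   paste0(idx$id[1:3], "_segmentation.png"))
  m <- png::readPNG(paths[1])
  expect_identical(dim(m), c(64L, 64L))
  expect_true(all(m %in% c(0, 1)))       # 0/255 bytes
  paths2 <- hds_predict(fx$model, idx$image_path[1:3],
                        withr::local_tempdir())
  expect_identical(readBin(paths[1], "raw", file.size(paths[1])),
                   readBin(paths2[1], "raw", file.size(paths2[1])))
})

test_that("the sparsity sweep tabulates one row per requested ratio", {
  fx <- small_train_fixture()
  tc <- train_config(epochs = 1, batch_size = 4, seed = 1)
  csv <- tempfile(fileext = ".csv")
  tab <- hds_sweep(c(0.5, 1), tiny_cfg(), tc, fx$data, fx$data,
                   max_steps = 2, csv = csv)
  expect_equal(nrow(tab), 2)
  expect_identical(tab$ratio, c(0.5, 1))
  expect_true(all(tab$dice >= 0 & tab$dice <= 1))
  expect_true(file.exists(csv))
})

test_that("the command-line surface covers synth and summary", {
  out <- file.path(withr::local_tempdir(), "ds")
  expect_output(hds_cli(c("synth", "--out", out, "--n", "2", "--size", "48")),
                "2 image/mask pairs")
  expect_length(list.files(out, pattern = "\\.jpg$"), 2)
  expect_output(hds_cli(c("summary", "--input-size", "64",
                          "--width-scale", "0.125")),
                "parameters")
})
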