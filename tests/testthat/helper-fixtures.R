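# Shared fixtures. Heavyweight objects are built once per test run and
# memoised in this environment.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

tiny_cfg <- function(width_scale = 0.125, input = 64) {
  hds_config(input_size = c(input, input), width_scale = width_scale)
}

tiny_model <- function() memo("tiny_model", build_model(tiny_cfg(), seed = 7))

tiny_images <- function(n = 2, size = 64, seed = 11) {
  with_seed <- hdsnet:::with_seed
  with_seed(seed, array(stats::runif(size * size * 3 * n),
                        c(size, size, 3, n)))
}

# 8-sample synthetic training set at 64x64, written to disk once
tiny_dataset_dir <- function() {
  memo("tiny_dataset_dir", {
    dir <- file.path(tempdir(), "hdsnet-tiny-data")
    generate_dataset(8, lesion_params(image_size = c(64, 64)), dir, seed = 5)
    dir
  })
}

tiny_dataset <- function() {
  memo("tiny_dataset",
       load_batch(index_dataset(tiny_dataset_dir()), input_size = c(64, 64)))
}

# straight-line scalar-loop re-implementation of the masked element-wise
# attention, independent of the vectorized path
dsa_oracle <- function(q, K, V, mask) {
  d <- dim(q)
  out <- array(0, d)
  for (n in seq_len(d[3])) {
    for (c in seq_len(d[2])) {
      M <- numeric(d[1])
      for (s in seq_len(d[1])) M[s] <- q[s, c, n] * K[s, c]
      A <- exp(M - max(M))
      A <- A / sum(A)
      for (s in seq_len(d[1])) out[s, c, n] <- A[s] * mask[s, c, n] * V[s, c]
    }
  }
  out
}
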