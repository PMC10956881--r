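test_that("degenerate Bernoulli masks are deterministic all-ones/all-zeros", {
  expect_equal(sample_bernoulli_mask(c(2, 3), 1), array(1, c(2, 3)))
  expect_equal(sample_bernoulli_mask(c(2, 3), 0), array(0, c(2, 3)))
})

test_that("mask entries are valid, reproducible, and keep-fraction tracks p", {
  m <- sample_bernoulli_mask(c(100, 10), 0.7, seed = 3)
  expect_true(all(m %in% c(0, 1)))
  expect_identical(m, sample_bernoulli_mask(c(100, 10), 0.7, seed = 3))
  for (p in c(0.1, 0.5, 0.9)) {
    n <- 1e4
    frac <- mean(sample_bernoulli_mask(n, p, seed = 17))
    halfwidth <- 2.576 * sqrt(p * (1 - p) / n)   # 99% binomial interval
    expect_lt(abs(frac - p), halfwidth)
  }
})

test_that("mask sampling rejects invalid probabilities and shapes", {
  expect_error(sample_bernoulli_mask(c(2, 2), -0.1), "\\[0, 1\\]")
  expect_error(sample_bernoulli_mask(c(2, 2), 1.5), "\\[0, 1\\]")
  expect_error(sample_bernoulli_mask(integer(0), 0.5), "positive")
  expect_error(sample_bernoulli_mask(c(0, 3), 0.5), "positive")
})

test_that("attention of uniform scores splits mass evenly over tokens", {
  q <- matrix(c(1, 1), 2, 1)
  K <- matrix(0, 2, 1)
  V <- matrix(c(4, 8), 2, 1)
  out <- dsa_attend(q, K, V, matrix(1, 2, 1))
  expect_equal(drop(out), c(2, 4))
})

test_that("vectorized attention equals a scalar-loop oracle on small inputs", {
  set.seed(71)
  worst <- 0
  for (i in 1:100) {
    S <- sample(1:4, 1); C <- sample(1:2, 1)
    q <- array(rnorm(S * C), c(S, C, 1))
    K <- matrix(rnorm(S * C), S, C)
    V <- matrix(rnorm(S * C), S, C)
    mask <- sample_bernoulli_mask(c(S, C, 1), runif(1))
    worst <- max(worst, max(abs(dsa_attend(q, K, V, mask) -
                                  dsa_oracle(q, K, V, mask))))
  }
  expect_lte(worst, 1e-6)
})

test_that("all-ones mask reproduces unmasked attention exactly; all-zeros kills it", {
  set.seed(5)
  q <- array(rnorm(24), c(4, 3, 2))
  K <- matrix(rnorm(12), 4, 3)
  V <- matrix(rnorm(12), 4, 3)
  ones <- array(1, dim(q))
  unmasked <- hdsnet:::dsa_attend_fwd(q, K, V, ones)
  expect_identical(dsa_attend(q, K, V, ones),
                   unmasked$A * c(V))   # mask term removed
  expect_equal(dsa_attend(q, K, V, array(0, dim(q))), array(0, dim(q)))
})

test_that("pre-mask attention normalizes to 1 along the token axis", {
  set.seed(6)
  q <- array(rnorm(4 * 3 * 2, sd = 3), c(4, 3, 2))
  K <- matrix(rnorm(12), 4, 3)
  V <- matrix(rnorm(12), 4, 3)
  fw <- hdsnet:::dsa_attend_fwd(q, K, V, array(1, dim(q)))
  sums <- apply(fw$A, c(2, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  # masked scores never exceed their pre-mask value and stay non-negative
  mask <- sample_bernoulli_mask(dim(q), 0.5, seed = 2)
  fw2 <- hdsnet:::dsa_attend_fwd(q, K, V, mask)
  expect_true(all(fw2$alpha >= 0 & fw2$alpha <= fw2$A))
})

test_that("attention rejects mismatched shapes and non-finite input", {
  q <- array(rnorm(8), c(4, 2, 1))
  K <- matrix(rnorm(8), 4, 2)
  expect_error(dsa_attend(q, K[1:3, ], K, array(1, dim(q))), "memory units")
  expect_error(dsa_attend(q, K, K, array(1, c(4, 2, 2))), "mask shape")
  q[1] <- NaN
  expect_error(dsa_attend(q, K, K, array(1, dim(q))), "non-finite")
})

test_that("the DSA block preserves shape and is deterministic in eval mode", {
  m <- tiny_model()
  pyr <- model_encode(m, tiny_images(2))
  x16 <- pyr$bottleneck
  y1 <- dsa_block(m, x16, mode = "eval")
  expect_identical(dim(y1), dim(x16))
  expect_identical(y1, dsa_block(m, x16, mode = "eval"))
  # train mode with p = 1 equals eval mode with p = 1 (mask == expectation)
  expect_equal(dsa_block(m, x16, mode = "train", p = 1, seed = 1),
               dsa_block(m, x16, mode = "eval", p = 1))
  # fresh masks in train mode generally change the output
  expect_false(identical(dsa_block(m, x16, mode = "train", p = 0.5, seed = 1),
                         dsa_block(m, x16, mode = "train", p = 0.5, seed = 2)))
})

test_that("the DSA block reports a token-count mismatch actionably", {
  m <- tiny_model()
  bad <- array(0.1, c(8, 8, dim(m$params$dsa.K)[2], 1))
  expect_error(dsa_block(m, bad), "input_size")
})
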