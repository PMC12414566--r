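test_that("BIC follows -2ll + p log n and its penalty property", {
  expect_equal(bic(0, 0, 10), 0)
  expect_equal(bic(-100, 8, 650), 200 + 8 * log(650))
  ll <- -321.4
  expect_equal(bic(ll, 6, 300) - bic(ll, 5, 300), log(300))
  expect_error(bic(0, 1, 0))
})

test_that("scaled entropy spans [0, 1] with hand-computed interior value", {
  one_hot <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(scaled_entropy(one_hot), 1)
  expect_equal(scaled_entropy(matrix(0.25, 5, 4)), 0)
  # N=2, K=2 rows (.9,.1) and (.6,.4): direct summation oracle
  p <- rbind(c(0.9, 0.1), c(0.6, 0.4))
  h <- -sum(p * log(p))
  expect_equal(scaled_entropy(p), 1 - h / (2 * log(2)))
  expect_equal(scaled_entropy(p), 1 - (0.3251 + 0.6730) / (2 * log(2)),
               tolerance = 1e-4)
  expect_error(scaled_entropy(matrix(1, 4, 1)), "single class")
  # property: any valid posterior matrix stays inside [0, 1]
  set.seed(1)
  for (i in 1:20) {
    m <- matrix(rexp(6 * 3), 6)
    m <- m / rowSums(m)
    e <- scaled_entropy(m)
    expect_gte(e, 0); expect_lte(e, 1)
  }
})

test_that("APPA equals per-class mean posterior among modally assigned", {
  expect_equal(appa(diag(2)[c(1, 1, 2), ]), c(1, 1))
  p <- rbind(c(0.8, 0.2), c(0.6, 0.4), c(0.3, 0.7))
  expect_equal(appa(p), c(0.7, 0.7))
  # brute-force oracle on random matrices
  set.seed(2)
  for (i in 1:10) {
    m <- matrix(rexp(8 * 3), 8); m <- m / rowSums(m)
    modal <- apply(m, 1, which.max)
    expected <- sapply(1:3, function(k)
      if (any(modal == k)) mean(m[modal == k, k]) else NA_real_)
    expect_equal(appa(m), expected)
  }
  # empty class is undefined, not an error
  p2 <- rbind(c(0.9, 0.1), c(0.8, 0.2))
  expect_true(is.na(appa(p2)[2]))
})
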