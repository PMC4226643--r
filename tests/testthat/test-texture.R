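test_that("first-order stats are the histogram mean and variance of the region", {
  g <- matrix(7, 4, 4); m <- matrix(1L, 4, 4)
  fo <- first_order_stats(g, m)
  expect_equal(fo$mu, 7); expect_equal(fo$var, 0)

  g2 <- matrix(c(0, 10), 1, 2); m2 <- matrix(1L, 1, 2)
  fo2 <- first_order_stats(g2, m2)
  expect_equal(fo2$mu, 5); expect_equal(fo2$var, 25)

  set.seed(2)
  g3 <- matrix(runif(100, 0, 255), 10, 10)
  m3 <- matrix(rbinom(100, 1, 0.6), 10, 10)
  fo3 <- first_order_stats(g3, m3)
  expect_equal(sum(fo3$h), 1, tolerance = 1e-9)
  expect_true(all(fo3$h >= 0))
  # only masked pixels contribute
  g4 <- g3; g4[m3 == 0] <- 999
  expect_equal(first_order_stats(g4, m3)$mu, fo3$mu)
  expect_error(first_order_stats(g3, matrix(0L, 10, 10)), "empty")
})

test_that("GLCM of tiny fixtures matches hand enumeration", {
  # [[0,1],[0,1]]: single (+1,+1) pair, value pair (0, max) -> P[1, 2] = 1
  g <- matrix(c(0, 0, 1, 1), 2, 2)
  gl <- compute_glcm(g, matrix(1L, 2, 2), levels = 2)
  expect_equal(gl$P, matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
  # constant image: all mass on one diagonal cell
  glc <- compute_glcm(matrix(5, 3, 3), matrix(1L, 3, 3), levels = 4)
  expect_equal(glc$P[1, 1], 1)
  expect_equal(sum(glc$P), 1)
  # 1-pixel mask: no valid pair
  m1 <- matrix(0L, 3, 3); m1[2, 2] <- 1L
  expect_error(compute_glcm(matrix(1:9, 3, 3), m1, levels = 2), "degenerate")
})

test_that("GLCM equals the brute-force pair-enumeration oracle", {
  set.seed(31)
  for (k in 1:6) {
    g <- matrix(round(runif(256, 0, 255)), 16, 16)
    m <- matrix(1L, 16, 16)
    if (k > 3) m <- matrix(rbinom(256, 1, 0.7), 16, 16)
    for (L in c(2, 8, 16)) {
      gl <- compute_glcm(g, m, levels = L)
      expect_lt(max(abs(gl$P - oracle_glcm(g, m, L))), 1e-12)
    }
  }
})

test_that("quantization maps the masked range onto bins 0 .. L-1 and is shift-invariant", {
  set.seed(5)
  g <- matrix(runif(144, 50, 180), 12, 12)
  m <- matrix(1L, 12, 12)
  for (L in c(4, 16)) {
    gl <- compute_glcm(g, m, levels = L)
    f1 <- glcm_features(gl)
    f2 <- glcm_features(compute_glcm(g + 31.7, m, levels = L))
    expect_equal(f1, f2, tolerance = 1e-12)  # range-relative quantization
  }
})

test_that("co-occurrence features match hand values and the summation oracle", {
  P <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)  # all mass at (0, 1)
  f <- glcm_features(P)
  expect_equal(f$uniformity, 1)
  expect_equal(f$entropy, 0)
  expect_equal(f$homogeneity, 0.5)
  expect_equal(f$inertia, 1)
  # uniform over k cells: entropy log k, uniformity 1/k
  k <- 9
  Pu <- matrix(1 / k, 3, 3)
  fu <- glcm_features(Pu)
  expect_equal(fu$entropy, log(k))
  expect_equal(fu$uniformity, 1 / k)
  set.seed(13)
  for (t in 1:10) {
    L <- sample(c(4, 8, 16), 1)
    M <- matrix(rexp(L * L), L, L); M <- M / sum(M)
    expect_equal(glcm_features(M), oracle_glcm_features(M), tolerance = 1e-12)
  }
})

test_that("feature extremes pin the degenerate cases", {
  set.seed(17)
  for (t in 1:20) {
    L <- 8
    M <- matrix(rexp(L * L) * rbinom(L * L, 1, 0.3), L, L)
    if (sum(M) == 0) next
    M <- M / sum(M)
    f <- glcm_features(M)
    expect_equal(f$uniformity == 1, f$entropy == 0)  # single cell <=> zero entropy
    ondiag <- sum(diag(M)) == 1
    expect_equal(abs(f$homogeneity - 1) < 1e-12, ondiag)
    expect_equal(f$inertia == 0, ondiag)
  }
})
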