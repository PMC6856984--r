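test_that("Matern 3/2 kernel evaluates its closed form", {
  expect_equal(matern32Kernel(c(0, 0), c(0, 0), 2, 1), 4)
  expect_equal(matern32Kernel(0, 1, 1, 1), (1 + sqrt(3)) * exp(-sqrt(3)))
  r <- seq(0, 5, by = 0.25)
  k <- vapply(r, function(ri) matern32Kernel(0, ri, 1, 1.3), 0)
  expect_true(all(diff(k) < 0))
  expect_error(matern32Kernel(0, 1, 1, -1), "positive")
})

test_that("default length scale is the exact pairwise maximum", {
  two <- rbind(rep(0.1, 4), rep(5, 4))
  expect_equal(defaultLengthScale(two), sqrt(4 * 4.9^2))
  expect_error(defaultLengthScale(two[1, , drop = FALSE]), "2 rows")
  expect_error(defaultLengthScale(rbind(c(1, 1), c(1, 1))), "degenerate")
  set.seed(31)
  X <- matrix(runif(40 * 4), 40, 4)
  brute <- max(as.matrix(dist(X)))
  expect_equal(defaultLengthScale(X), brute)
})

test_that("truncated eigendecomposition matches a dense solver", {
  e <- truncatedEigendecomposition(diag(5), 5)
  expect_equal(e$values, rep(1, 5))
  v <- c(1, 2, 3)
  e1 <- truncatedEigendecomposition(v %*% t(v), 1)
  expect_equal(e1$values, sum(v^2))
  expect_equal(abs(drop(e1$vectors)), abs(v / sqrt(sum(v^2))),
               tolerance = 1e-12)
  set.seed(12)
  C <- crossprod(matrix(rnorm(50 * 50), 50))
  tk <- truncatedEigendecomposition(C, 10)
  dense <- eigen(C, symmetric = TRUE)
  expect_equal(tk$values, dense$values[1:10], tolerance = 1e-8)
  expect_equal(crossprod(tk$vectors), diag(10), tolerance = 1e-10)
  resid <- vapply(1:10, function(i)
    sqrt(sum((C %*% tk$vectors[, i] - tk$values[i] * tk$vectors[, i])^2)) /
      abs(tk$values[i]), 0)
  expect_lt(max(resid), 1e-6)
  expect_error(truncatedEigendecomposition(matrix(rnorm(9), 3), 2),
               "symmetric")
  expect_error(truncatedEigendecomposition(diag(3), 4), "exceed")
})

test_that("low-rank fit reproduces exact GP regression at full rank", {
  set.seed(7)
  Theta <- matrix(runif(40 * 4, 0.1, 5), 40, 4)
  y <- cos(Theta[, 1]) + 1 / Theta[, 2]
  fit <- fitLowRank(Theta, y, nr = 40, k = 40, seed = 3,
                    hyper = list(s2 = 2, sigma2 = 1e-4))
  Xq <- rbind(c(2, 3, 1, 4), c(0.5, 0.5, 4, 4), Theta[5, ])
  ref <- summed_gp_oracle(Theta, y, Xq, 2, 1e-4)
  p <- predictLowRank(fit, Xq)
  expect_equal(p$mean, ref, tolerance = 1e-6)
  expect_true(all(p$var >= 0))
})

test_that("low-rank fit is seeded, interpolatory and accurate on smooth targets", {
  set.seed(19)
  Theta <- matrix(runif(200 * 4, 0.1, 5), 200, 4)
  y <- sin(Theta[, 1]) + 0.5 / Theta[, 2] + 0.2 * Theta[, 3]
  f1 <- fitLowRank(Theta, y, nr = 200, k = 200, seed = 4)
  f2 <- fitLowRank(Theta, y, nr = 200, k = 200, seed = 4)
  expect_identical(f1$col, f2$col)
  pr <- predictLowRank(f1, Theta)
  r2 <- 1 - sum((pr$mean - y)^2) / sum((y - mean(y))^2)
  expect_gt(r2, 0.99)
  expect_lt(max(abs(pr$mean - y)), 0.01 * diff(range(y)))

  # continuity of the predictor
  th <- c(2, 2, 2, 2)
  deltas <- 10^seq(-2, -6)
  gaps <- vapply(deltas, function(d)
    abs(predictLowRank(f1, th + d)$mean - predictLowRank(f1, th)$mean), 0)
  expect_true(all(diff(gaps) < 0))

  expect_error(fitLowRank(Theta, y, nr = 100, k = 150), "exceed")
  expect_error(fitLowRank(Theta, y[-1]), "nrow")
})

test_that("spectral truncation error shrinks and accuracy grows with rank", {
  set.seed(23)
  Theta <- matrix(runif(120 * 4, 0.1, 5), 120, 4)
  lt <- defaultLengthScale(Theta)
  C <- matern32Kernel(Theta, Theta, 1, lt)
  errs <- vapply(c(5, 20, 60, 120), function(k) {
    e <- truncatedEigendecomposition(C, k)
    norm(C - e$vectors %*% (e$values * t(e$vectors)), "F")
  }, 0)
  expect_true(all(diff(errs) < 1e-10))

  ds <- toy_data(500, 20)
  Ytr <- outputMatrix(ds$train)[, 25]
  rmse <- vapply(c(50, 150, 400), function(k) {
    f <- fitLowRank(designMatrix(ds$train), Ytr, nr = 400, k = k, seed = 2)
    p <- predictLowRank(f, designMatrix(ds$test))
    sqrt(mean((p$mean - outputMatrix(ds$test)[, 25])^2))
  }, 0)
  expect_lt(rmse[3], rmse[1] * 1.05)
})
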