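test_that("ARD-SE kernel evaluates its closed form", {
  h <- list(outputScale = 1.5, lengthScales = rep(1, 4))
  x <- c(1, 2, 3, 4)
  expect_equal(ardSeKernel(x, x, h), 1.5^2)
  h1 <- list(outputScale = 1, lengthScales = rep(1, 4))
  expect_equal(ardSeKernel(c(1, 0, 0, 0), c(0, 0, 0, 0), h1), exp(-0.5))
  set.seed(2)
  for (rep in 1:5) {
    a <- runif(4); b <- runif(4)
    h2 <- list(outputScale = runif(1, 0.5, 2),
               lengthScales = runif(4, 0.2, 3))
    expect_equal(ardSeKernel(a, b, h2), ardSeKernel(b, a, h2))
  }
})

test_that("neighbour search matches a brute-force distance sort", {
  set.seed(6)
  Theta <- matrix(runif(200 * 4, 0.1, 5), 200, 4)
  expect_true(17L %in% findNeighbors(Theta[17, ], Theta, 5))
  expect_setequal(findNeighbors(c(1, 1, 1, 1), Theta, 200), seq_len(200))
  expect_error(findNeighbors(c(1, 1, 1, 1), Theta, 201), "exceed")
  for (rep in 1:5) {
    q <- runif(4, 0.1, 5)
    d <- sqrt(colSums((t(Theta) - q)^2))
    expect_identical(findNeighbors(q, Theta, 12), order(d)[1:12])
  }
})

test_that("hyperparameter estimation honours its optimizer contract", {
  set.seed(11)
  X <- matrix(runif(80 * 4, 0.1, 5), 80, 4)
  y <- sin(X[, 1]) + 0.5 * X[, 2]
  h <- fitHyperparameters(X, y)
  expect_true(all(h$lengthScales > 0))
  expect_gt(h$outputScale, 0)
  expect_gte(h$noiseSd, 1e-6 * sd(y) * 0.999)
  # the fit never ends worse than its initialisation (standardised scale)
  ys <- (y - mean(y)) / sd(y)
  init <- c(log(0.5 * apply(X, 2, function(v) diff(range(v)))), 0,
            log(1e-2))
  nll0 <- lvemu:::cpp_nll_ard_se(init, X, ys, -1)$value
  expect_lte(h$nll, nll0 + 1e-6)

  # constant outputs degrade gracefully to the constant
  hc <- fitHyperparameters(X, rep(3.3, 80))
  expect_equal(hc$meanConst, 3.3)
  pc <- predictLocal(c(2, 2, 2, 2), X, rep(3.3, 80), K = 40)
  expect_equal(pc$mean, 3.3, tolerance = 1e-8)
})

test_that("length scales of a known GP are recovered", {
  set.seed(11)
  ok <- 0
  for (rep in 1:20) {
    X <- matrix(runif(100 * 2), 100, 2)
    ls <- c(0.3, 0.6)
    K <- lvemu:::cpp_cov_ard_se(X, X, ls, 1) + diag(1e-6, 100)
    y <- drop(t(chol(K)) %*% rnorm(100))
    h <- fitHyperparameters(X, y)
    r <- h$lengthScales / ls
    if (all(r > 0.5 & r < 2)) ok <- ok + 1
  }
  expect_gte(ok, 16)
})

test_that("local prediction interpolates and reduces to the full GP", {
  set.seed(8)
  Theta <- matrix(runif(120 * 4, 0.1, 5), 120, 4)
  y <- cos(Theta[, 1]) + 0.3 * Theta[, 2] * Theta[, 3]

  # near-interpolation with the noise pinned at 1e-6 (compared on the
  # scale of the response, not of one near-zero value)
  idx <- which.max(abs(y))
  pr <- predictLocal(Theta[idx, ], Theta, y, K = 60, fixNoise = 1e-6)
  expect_equal(pr$mean, y[idx], tolerance = 1e-4)

  # K = N with shared hyperparameters equals the textbook GP equations
  hyp <- list(outputScale = 1.2, lengthScales = c(1.5, 2, 2.5, 3),
              noiseSd = 0.05, meanConst = 0)
  fac <- lvemu:::.localFactor(Theta, y, hyp)
  q <- c(2.2, 3.1, 0.7, 4.2)
  mine <- lvemu:::.localPredict(fac, matrix(q, 1))
  ref <- full_gp_oracle(Theta, y, q, hyp$lengthScales, hyp$outputScale,
                        hyp$noiseSd)
  expect_equal(mine$mean, ref$mean, tolerance = 1e-8)
  expect_equal(mine$var, ref$var, tolerance = 1e-8)

  # variance grows away from the data
  pt <- predictLocal(Theta[3, ], Theta, y, K = 60)
  corner <- rep(5, 4)
  pc <- predictLocal(corner, Theta, y, K = 60)
  expect_lt(pt$var, pc$var)
})

test_that("predictions are translation-equivariant in the outputs", {
  set.seed(14)
  Theta <- matrix(runif(60 * 4, 0.1, 5), 60, 4)
  y <- sin(Theta[, 1] * 2)
  hyp <- list(outputScale = 1, lengthScales = rep(1.5, 4), noiseSd = 0.01,
              meanConst = 0)
  q <- matrix(c(1, 2, 3, 4), 1)
  f1 <- lvemu:::.localPredict(lvemu:::.localFactor(Theta, y, hyp), q)
  f2 <- lvemu:::.localPredict(lvemu:::.localFactor(Theta, y + 10, hyp), q)
  expect_equal(f2$mean, f1$mean + 10, tolerance = 1e-9)
  expect_equal(f2$var, f1$var, tolerance = 1e-12)
})

test_that("the analytic mean gradient matches finite differences", {
  set.seed(15)
  Theta <- matrix(runif(50 * 4, 0.1, 5), 50, 4)
  y <- Theta[, 1]^2 + exp(-Theta[, 2])
  hyp <- fitHyperparameters(Theta, y)
  fac <- lvemu:::.localFactor(Theta, y, hyp)
  th <- c(2, 3, 1.5, 4)
  g <- lvemu:::.localMeanGrad(fac, th)
  gn <- vapply(1:4, function(i) {
    e <- numeric(4); e[i] <- 1e-4
    (lvemu:::.localPredict(fac, matrix(th + e, 1), FALSE)$mean -
     lvemu:::.localPredict(fac, matrix(th - e, 1), FALSE)$mean) / 2e-4
  }, 0)
  expect_equal(unname(g$grad), gn, tolerance = 1e-3)
})
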