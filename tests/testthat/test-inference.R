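test_that("multistart minimisation finds global minima within bounds", {
  ctr <- c(2, 3, 1, 4)
  quad <- function(th) sum((th - ctr)^2)
  r <- multistartMinimize(quad, optimConfig(nStarts = 10L))
  expect_equal(r$par, ctr, tolerance = 1e-6)
  expect_gte(r$nStartsConverged, 1L)

  # two separated basins: the deeper one must win
  a <- rep(1, 4); b <- rep(4, 4)
  f2 <- function(th) -exp(-sum((th - a)^2) / 0.5) -
    2 * exp(-sum((th - b)^2) / 0.5)
  r2 <- multistartMinimize(f2, optimConfig(nStarts = 50L))
  expect_equal(r2$par, b, tolerance = 1e-4)
  expect_true(all(r2$par >= 0.1 & r2$par <= 5))

  # starts inside a found basin are skipped, not re-descended
  expect_true(any(r2$diagnostics$status == "skipped"))
  expect_error(multistartMinimize(function(th) stop("boom"),
                                  optimConfig(nStarts = 4L)), "failed")
})

test_that("output emulator bundles predict the training rows", {
  ds <- toy_data(500, 4)
  for (interp in c("local_gp", "lowrank_gp")) {
    b <- buildOutputEmulator(ds$train, interp,
                             control = list(K = 60L, nr = 300L, k = 200L))
    expect_length(b@emulators, 25L)
    th <- designMatrix(ds$train)[17, ]
    p <- predictOutputs(b, th)
    rel <- abs(p$mean - outputMatrix(ds$train)[17, ]) /
      pmax(abs(outputMatrix(ds$train)[17, ]), 1e-8)
    expect_lt(max(rel), 0.01)
    y0 <- outputMatrix(ds$test)[1, ]
    expect_equal(surrogateOutputLoss(th, b, y0),
                 euclideanLoss(p$mean, y0), tolerance = 1e-10)
    # zero loss against the emulator's own prediction
    expect_equal(surrogateOutputLoss(th, b, p$mean), 0, tolerance = 1e-12)
    # finite over a scan of the box
    set.seed(3)
    scan <- matrix(runif(40, 0.1, 5), 10, 4)
    vals <- apply(scan, 1, function(q) surrogateOutputLoss(q, b, y0))
    expect_true(all(is.finite(vals)))
  }
  expect_error(buildOutputEmulator(toy_data(500, 4)$train, "spline"),
               "arg")
})

test_that("loss emulators train on the definitional losses", {
  ds <- toy_data(500, 4)
  y0 <- outputMatrix(ds$test)[2, ]
  spec <- lossSpec("euclidean")
  b <- buildLossEmulator(ds$train, y0, spec, "local_gp",
                         control = list(K = 60L))
  ln <- b@cache$trainingLosses
  Y <- outputMatrix(ds$train)
  expect_equal(ln, rowSums(sweep(Y, 2, y0)^2) / 2, tolerance = 1e-12)

  # with y0 equal to a training output the minimum loss sits at that row
  yk <- Y[123, ]
  bk <- buildLossEmulator(ds$train, yk, spec, "local_gp",
                          control = list(K = 60L))
  expect_equal(which.min(bk@cache$trainingLosses), 123L)

  # emulated losses track the true losses tightly at the design points
  bl <- buildLossEmulator(ds$train, y0, spec, "lowrank_gp",
                          control = list(nr = 300L, k = 200L))
  idx <- seq(1, 500, by = 10)
  pred <- vapply(idx, function(i)
    emulatedLossMean(designMatrix(ds$train)[i, ], bl), 0)
  expect_gt(cor(pred, ln[idx], method = "spearman"), 0.95)
  expect_lt(sqrt(mean((pred - ln[idx])^2)), sd(ln))

  expect_error(buildLossEmulator(ds$train, y0[-1], spec, "local_gp"),
               "length")
  expect_error(emulatedLossMean(c(1, 1, 1, 1),
                                buildOutputEmulator(ds$train, "lowrank_gp",
                                  control = list(nr = 200L, k = 100L))),
               "loss-strategy")
})

test_that("end-to-end estimation recovers parameters and is deterministic", {
  ds <- toy_data(800, 4)
  y0 <- outputMatrix(ds$test)[1, ]
  tru <- designMatrix(ds$test)[1, ]
  cfg <- optimConfig(nStarts = 8L, seed = 5L)
  r1 <- estimateParameters(y0, ds$train, "output", "local_gp",
                           config = cfg, control = list(K = 60L),
                           uq = FALSE)
  # coarse sanity at this reduced scale; the full-protocol recovery bound
  # is asserted at 2000 training points in the acceptance suite
  expect_lt(parameterMSE(thetaHat(r1), tru), 0.5)
  expect_true(all(thetaHat(r1) >= 0.1 & thetaHat(r1) <= 5))
  r2 <- estimateParameters(y0, ds$train, "output", "local_gp",
                           config = cfg, control = list(K = 60L),
                           uq = FALSE)
  expect_identical(thetaHat(r1), thetaHat(r2))
  # the optimum is at least as good as the best training point seen
  # through the emulator
  b <- buildOutputEmulator(ds$train, "local_gp", control = list(K = 60L))
  tl <- lvemu:::.trainingLosses(outputMatrix(ds$train), y0, b@lossSpec)
  bestRow <- designMatrix(ds$train)[which.min(tl), ]
  expect_lte(lossMin(r1), surrogateOutputLoss(bestRow, b, y0) + 1e-8)
  expect_error(estimateParameters(y0[-1], ds$train, "output", "local_gp"),
               "length")
})

test_that("Hessian UQ inverts a known quadratic and bands behave", {
  A <- matrix(c(40, 10, 0, 0,
                10, 30, 5, 0,
                0, 5, 20, 2,
                0, 0, 2, 10), 4, 4)
  ctr <- c(2.5, 2.5, 2.5, 2.5)
  obj <- function(th) 0.5 * drop(t(th - ctr) %*% A %*% (th - ctr))
  u <- hessianUncertainty(obj, ctr, nSamples = 2000, seed = 2)
  Ai <- solve(A)
  expect_equal(u$covariance, Ai, tolerance = 1e-4)
  expect_equal(u$hessian, A, tolerance = 1e-4)

  # CLT convergence of the (barely truncated) sample mean
  sds <- sqrt(diag(Ai))
  expect_lt(sqrt(sum((colMeans(u$samples) - ctr)^2)),
            3 * max(sds) / sqrt(2000) * 4)
  expect_true(all(u$samples >= 0.1 & u$samples <= 5))

  # bands: zero stress at unit stretch, point curve contained everywhere
  for (cv in u$curves) {
    expect_identical(cv@lower[1], 0)
    expect_identical(cv@upper[1], 0)
    expect_true(all(cv@lower <= cv@stresses & cv@stresses <= cv@upper))
  }
  expect_error(hessianUncertainty(function(th) 0, ctr, nSamples = 10),
               "zero")
})
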