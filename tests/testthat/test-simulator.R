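test_that("the forward map is deterministic, monotone and load-consistent", {
  y1 <- simulateOutput(c(1, 1, 1, 1))
  expect_identical(y1, simulateOutput(c(1, 1, 1, 1)))
  expect_length(y1, 25L)
  expect_named(y1, c(sprintf("strain%02d", 1:24), "volume"))

  soft <- simulateOutput(rep(0.1, 4))
  stiff <- simulateOutput(rep(5, 4))
  expect_true(all(stiff < soft))

  # strictly decreasing along every axis, on a grid of base points
  base <- scaleToBounds(sobolUnitSequence(designSpec(6, upper = 4.4)),
                        0.1, 4.4)
  for (r in seq_len(nrow(base))) {
    y0 <- simulateOutput(base[r, ])
    for (i in 1:4) {
      e <- numeric(4); e[i] <- 0.5
      expect_true(all(simulateOutput(base[r, ] + e) < y0))
    }
  }

  # recovered stretches reproduce their loads to high precision
  cfg <- simulatorConfig()
  lam <- lvemu:::.solveStretches(matrix(c(0.7, 2.2, 1.4, 3.0), 1), cfg)
  p <- reduceParameters(c(0.7, 2.2, 1.4, 3.0), cfg@refs)
  resid <- abs(lvemu:::.segmentStress(
    drop(lam), p[["a"]], p[["b"]], p[["af"]], p[["bf"]], p[["as"]],
    p[["bs"]], p[["afs"]], p[["bfs"]], cfg@shearCoupling, cfg@sheetMix) -
    cfg@segmentLoads)
  expect_lt(max(resid), 1e-8)

  # the reported strain is the Green strain of the recovered stretch
  y <- simulateOutput(c(0.7, 2.2, 1.4, 3.0), cfg)
  expect_equal(unname(y[1:24]), drop((lam^2 - 1) / 2), tolerance = 1e-12)

  # unbracketable load errors and names the segment
  bad <- simulatorConfig(segmentLoads = c(rep(1, 23), 1e4))
  expect_error(simulateOutput(rep(0.1, 4), bad), "segment 24")
})

test_that("outputs are mutually correlated and sensitivities collinear", {
  ds <- toy_data(512, 4)
  Y <- outputMatrix(ds$train)
  cors <- cor(Y[, 1:24])
  expect_true(all(cors > 0))

  # weak identifiability: locally estimated sensitivities of the outputs to
  # the four parameters are strongly correlated across parameters
  set.seed(5)
  pts <- scaleToBounds(sobolUnitSequence(designSpec(8, lower = 0.5,
                                                    upper = 4.5)), 0.5, 4.5)
  J <- NULL
  for (r in seq_len(nrow(pts))) {
    Jr <- sapply(1:4, function(i) {
      e <- numeric(4); e[i] <- 1e-4
      (simulateOutput(pts[r, ] + e) - simulateOutput(pts[r, ] - e)) / 2e-4
    })
    J <- rbind(J, Jr)
  }
  sc <- cor(J)
  expect_gt(max(abs(sc[upper.tri(sc)])), 0.5)
})

test_that("datasets generate, round-trip and validate", {
  t0 <- Sys.time()
  ds <- generateDataset(8, 2)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
  expect_equal(dim(outputMatrix(ds$train)), c(8L, 25L))
  expect_equal(dim(outputMatrix(ds$test)), c(2L, 25L))
  ds2 <- generateDataset(8, 2)
  expect_equal(outputMatrix(ds$train), outputMatrix(ds2$train))

  path <- tempfile(fileext = ".csv")
  writeDataset(ds$train, path)
  back <- readDataset(path)
  expect_equal(designMatrix(back), designMatrix(ds$train),
               tolerance = 1e-12)
  expect_equal(outputMatrix(back), outputMatrix(ds$train),
               tolerance = 1e-12)

  # missing volume column is a parse error
  df <- read.csv(path)
  df$volume <- NULL
  path2 <- tempfile(fileext = ".csv")
  write.csv(df, path2, row.names = FALSE)
  expect_error(readDataset(path2), "volume")
  # non-numeric cell is reported with its location
  df2 <- read.csv(path)
  df2$strain03 <- as.character(df2$strain03)
  df2$strain03[2] <- "oops"
  path3 <- tempfile(fileext = ".csv")
  write.csv(df2, path3, row.names = FALSE)
  expect_error(readDataset(path3), "strain03")
  expect_error(readDataset(tempfile()), "not found")
})

test_that("observation noise is seeded, scaled and restores the RNG", {
  y <- simulateOutput(c(1, 1, 1, 1))
  expect_identical(addObservationNoise(y, 0, 0, seed = 1), y)
  n1 <- addObservationNoise(y, 0.01, 1, seed = 7)
  n2 <- addObservationNoise(y, 0.01, 1, seed = 7)
  expect_identical(n1, n2)
  expect_gt(max(abs(n1 - y)), 0)

  # empirical strain sd over many replicates matches the nominal sd
  reps <- vapply(seq_len(10000), function(s)
    addObservationNoise(y, 0.02, 0.5, seed = s)[1], 0)
  expect_equal(sd(reps - y[1]), 0.02, tolerance = 0.05)

  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(addObservationNoise(y, 0.01, 1, seed = 99))
  expect_identical(runif(1), before)
})
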