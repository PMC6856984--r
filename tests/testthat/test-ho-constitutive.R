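test_that("reduced parameterization maps theta onto the reference values", {
  refs <- referenceValues()
  p <- reduceParameters(c(1, 1, 1, 1))
  expect_equal(p[["a"]], 0.22)
  expect_equal(p[["b"]], 1.62)
  expect_equal(p[["af"]], 2.43)
  expect_equal(p[["as"]], 0.56)
  expect_equal(p[["bf"]], 1.83)
  expect_equal(p[["bs"]], 0.77)
  expect_equal(p[["afs"]], 0.39)
  expect_equal(p[["bfs"]], 1.70)

  p2 <- reduceParameters(c(2, 1, 1, 1))
  expect_equal(p2[["a"]], 0.44)
  expect_equal(p2[["b"]], 3.24)
  expect_equal(p2[-(1:2)], p[-(1:2)])

  # linear in each component: scaling theta scales the mapped pairs
  th <- c(0.8, 1.7, 2.2, 0.4)
  expect_equal(reduceParameters(2 * th), 2 * reduceParameters(th))

  expect_error(reduceParameters(c(0.05, 1, 1, 1)), "theta1")
  expect_error(reduceParameters(c(1, 1, 5.4, 1)), "theta3")
  expect_error(reduceParameters(c(1, 1, 1)), "length")
})

test_that("invariants match their definitions and a dense oracle", {
  st <- deformationState(diag(3))
  inv <- computeInvariants(st)
  expect_equal(inv$I1, 3)
  expect_equal(inv$I4f, 1)
  expect_equal(inv$I4s, 1)
  expect_equal(inv$I8fs, 0)

  lam <- 1.23
  st <- deformationState(diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam))))
  inv <- computeInvariants(st)
  expect_equal(inv$I1, lam^2 + 2 / lam, tolerance = 1e-12)
  expect_equal(inv$I4f, lam^2, tolerance = 1e-12)
  expect_equal(inv$I4s, 1 / lam, tolerance = 1e-12)
  expect_equal(inv$I8fs, 0)

  set.seed(4)
  for (rep in 1:10) {
    F <- diag(3) + 0.3 * matrix(rnorm(9), 3)
    if (det(F) <= 0) next
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    st <- deformationState(F, q[, 1], q[, 2])
    inv <- computeInvariants(st)
    C <- t(F) %*% F
    expect_equal(inv$I1, sum(diag(C)), tolerance = 1e-12)
    expect_equal(inv$I4f, drop(q[, 1] %*% C %*% q[, 1]), tolerance = 1e-12)
    expect_equal(inv$I4s, drop(q[, 2] %*% C %*% q[, 2]), tolerance = 1e-12)
    expect_equal(inv$I8fs, drop(q[, 1] %*% C %*% q[, 2]), tolerance = 1e-12)
  }

  expect_error(deformationState(matrix(0, 3, 3)), "determinant")
})

test_that("strain energy vanishes at identity, isolates terms, stays non-negative", {
  set.seed(9)
  for (rep in 1:5) {
    params <- reduceParameters(runif(4, 0.1, 5))
    expect_identical(strainEnergy(params, deformationState(diag(3))), 0)
  }

  # with the anisotropic stiffnesses zeroed only the isotropic term remains
  params <- c(a = 0.3, b = 1.1, af = 0, bf = 1, as = 0, bs = 1,
              afs = 0, bfs = 1)
  lam <- 1.2
  st <- deformationState(diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam))))
  I1 <- lam^2 + 2 / lam
  expect_equal(strainEnergy(params, st),
               0.3 / (2 * 1.1) * (exp(1.1 * (I1 - 3)) - 1),
               tolerance = 1e-12)

  # non-negativity on random isochoric deformations
  set.seed(21)
  for (rep in 1:20) {
    params <- reduceParameters(runif(4, 0.1, 5))
    F <- diag(3) + 0.2 * matrix(rnorm(9), 3)
    F <- F / det(F)^(1 / 3)
    if (det(F) <= 0) next
    expect_gte(strainEnergy(params, deformationState(F)), 0)
  }
})

test_that("uniaxial Cauchy stress equals the energy-derivative oracle", {
  expect_identical(uniaxialCauchyStress(reduceParameters(rep(1, 4)), 1,
                                        "fibre"), 0)
  expect_identical(uniaxialCauchyStress(reduceParameters(rep(1, 4)), 1,
                                        "sheet"), 0)
  set.seed(3)
  for (rep in 1:5) {
    params <- reduceParameters(runif(4, 0.2, 4))
    for (dir in c("fibre", "sheet")) {
      for (lam in c(1.01, 1.05, 1.1, 1.2, 1.3)) {
        ana <- uniaxialCauchyStress(params, lam, dir)
        num <- fd_uniaxial_stress(params, lam, dir)
        expect_equal(ana, num, tolerance = 1e-4)
      }
    }
  }
  # fibres are stiffer than sheets at the reference values
  p <- reduceParameters(rep(1, 4))
  lam <- seq(1.05, 1.3, by = 0.05)
  expect_true(all(uniaxialCauchyStress(p, lam, "fibre") >=
                  uniaxialCauchyStress(p, lam, "sheet")))
  expect_error(uniaxialCauchyStress(p, 0.9, "fibre"), "compression")
})

test_that("stretch-stress curves are monotone and respond non-linearly", {
  c0 <- stretchStressCurve(rep(1, 4), grid = 1)
  expect_equal(c0@stresses, 0)

  cv <- stretchStressCurve(rep(1, 4), direction = "fibre",
                           grid = seq(1, 1.3, by = 0.01))
  expect_true(all(diff(cv@stresses) > 0))
  expect_equal(cv@stresses[1], 0)

  # doubling theta does not double the stress (exponential law)
  c2 <- stretchStressCurve(rep(2, 4), direction = "fibre",
                           grid = seq(1, 1.3, by = 0.01))
  expect_gt(max(abs(c2@stresses - 2 * cv@stresses)), 1e-3)

  expect_error(stretchStressCurve(rep(1, 4), grid = c(1.1, 1.0)),
               "increasing")
  expect_error(stretchStressCurve(rep(1, 4), grid = c(0.9, 1.0)), ">= 1")

  path <- tempfile(fileext = ".csv")
  writeCurve(cv, path)
  df <- read.csv(path)
  expect_equal(df$stress, cv@stresses)
  expect_equal(df$direction[1], "fibre")
})
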