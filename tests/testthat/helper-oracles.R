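# Shared fixtures and independent oracles for the test suite. Datasets are
# generated once per test run and memoised here; all oracles are plain-R
# implementations kept independent of the package code paths they check.

.fixtures <- new.env(parent = emptyenv())

toy_data <- function(n_train, n_test, key = paste0("d", n_train, "_", n_test)) {
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generateDataset(n_train, n_test)
  .fixtures[[key]]
}

# textbook GP regression (ordinary-kriging constant mean) in plain R,
# used as the full-GP oracle for the local module
full_gp_oracle <- function(X, y, xstar, ls, sf, sigma) {
  n <- nrow(X)
  K <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    sf^2 * exp(-0.5 * sum(((X[i, ] - X[j, ]) / ls)^2))))
  A <- K + diag(sigma^2, n)
  Ai <- solve(A)
  cc <- sum(Ai %*% y) / sum(Ai)
  kv <- apply(X, 1, function(r)
    sf^2 * exp(-0.5 * sum(((r - xstar) / ls)^2)))
  list(mean = cc + sum(kv * (Ai %*% (y - cc))),
       var = sf^2 - drop(t(kv) %*% Ai %*% kv))
}

# exact GP regression with the summed Matern 3/2 kernel over (theta, 1/theta),
# the oracle for the low-rank module in its nr = N, k = N limit
summed_gp_oracle <- function(Theta, y, Xq, s2, sigma2) {
  lt <- defaultLengthScale(Theta)
  lta <- defaultLengthScale(1 / Theta)
  K <- matern32Kernel(Theta, Theta, 1, lt) +
    matern32Kernel(1 / Theta, 1 / Theta, 1, lta)
  kq <- matern32Kernel(Xq, Theta, 1, lt) +
    matern32Kernel(1 / Xq, 1 / Theta, 1, lta)
  beta <- mean(y)
  drop(beta + kq %*% solve(K + diag(sigma2 / s2, nrow(Theta)), y - beta))
}

# centred L2 discrepancy (Hickernell), closed form; lower = more uniform
centered_l2_discrepancy <- function(X) {
  n <- nrow(X)
  d <- ncol(X)
  z <- abs(X - 0.5)
  t1 <- prod(rep(13 / 12, d))^1  # (13/12)^d
  t1 <- (13 / 12)^d
  t2 <- mean(apply(1 + 0.5 * z - 0.5 * z^2, 1, prod))
  s3 <- 0
  for (i in seq_len(n)) {
    zi <- z[i, ]
    M <- 1 + 0.5 * matrix(zi, n, d, byrow = TRUE) + 0.5 * z -
      0.5 * abs(sweep(X, 2, X[i, ]))
    s3 <- s3 + sum(apply(M, 1, prod))
  }
  t1 - 2 * t2 + s3 / n^2
}

# finite-difference stretch derivative of the isochoric strain energy,
# the independent oracle for the analytic uniaxial Cauchy stress
fd_uniaxial_stress <- function(params, lam, direction, h = 1e-6) {
  en <- function(l) {
    F <- if (direction == "fibre") diag(c(l, 1 / sqrt(l), 1 / sqrt(l)))
    else diag(c(1 / sqrt(l), l, 1 / sqrt(l)))
    strainEnergy(params, deformationState(F))
  }
  lam * (en(lam + h) - en(lam - h)) / (2 * h)
}
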