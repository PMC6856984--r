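#' Isotropic Matern 3/2 kernel
#'
#' k(x, x') = scale^2 (1 + sqrt(3) r / length) exp(-sqrt(3) r / length) with
#' r the Euclidean distance.
#'
#' @param x,xp numeric vectors (or matrices with matching column count, in
#'   which case the full cross-covariance is returned).
#' @param scale output scale (default 1).
#' @param length length scale, > 0.
#' @return Scalar covariance or cross-covariance matrix.
#' @examples
#' matern32Kernel(0, 1, length = 1)  # (1 + sqrt(3)) * exp(-sqrt(3))
#' @export
matern32Kernel <- function(x, xp, scale = 1, length) {
  if (length <= 0) stop("length scale must be positive")
  if (is.matrix(x) || is.matrix(xp))
    return(cpp_cov_matern32(rbind(x), rbind(xp), length, scale^2))
  r <- sqrt(sum((x - xp)^2)) * sqrt(3) / length
  scale^2 * (1 + r) * exp(-r)
}

#' Default Matern length scale
#'
#' The maximum pairwise Euclidean distance among the design rows (the
#' Kammann-Wand default), computed exactly by the O(n^2) pairwise scan.
#'
#' @param Theta matrix of design rows (>= 2 rows).
#' @return Positive scalar.
#' @export
defaultLengthScale <- function(Theta) {
  Theta <- as.matrix(Theta)
  if (nrow(Theta) < 2L) stop("need at least 2 rows for a length scale")
  m <- max(dist(Theta))
  if (m <= 0) stop("degenerate design: all rows identical (length scale 0)")
  m
}

#' Truncated eigendecomposition
#'
#' Top-k eigenpairs of a symmetric matrix, ordered by decreasing absolute
#' eigenvalue. The operation contract is on the returned eigenpairs, not the
#' algorithm; for the subsample sizes used here (nr <= 2000) a dense
#' symmetric eigensolver is equivalent to Lanczos iteration and simpler.
#'
#' @param C symmetric matrix.
#' @param k number of eigenpairs to retain, k <= dim(C).
#' @return List with elements \code{values} (length k) and \code{vectors}
#'   (ncol(C) x k, orthonormal columns).
#' @export
truncatedEigendecomposition <- function(C, k) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8 * max(abs(C), 1))
    stop("C must be symmetric")
  if (k > nrow(C)) stop("k must not exceed dim(C)")
  e <- eigen(C, symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)[seq_len(k)]
  list(values = e$values[ord], vectors = e$vectors[, ord, drop = FALSE])
}

# Shared low-rank machinery: subsample the design, build the summed Matern
# kernel over (theta, 1/theta), truncate its spectrum, and form the N x k
# feature matrix Z = K(Theta, sub) U_k D_k^{-1/2}. The prior covariance of
# the latent function is then s2 * Z Z', the Nystrom approximation, exact
# when nr = N and k = N.
.lowRankBasis <- function(Theta, nr, k, seed) {
  Theta <- as.matrix(Theta)
  N <- nrow(Theta)
  nr <- min(nr, N)
  if (k > nr) stop("k must not exceed the subsample size nr")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  idx <- if (nr == N) seq_len(N) else sort(sample.int(N, nr))
  Xsub <- Theta[idx, , drop = FALSE]
  Tau <- 1 / Theta
  Tsub <- Tau[idx, , drop = FALSE]
  lenTheta <- defaultLengthScale(Xsub)
  lenTau <- defaultLengthScale(Tsub)
  C <- cpp_cov_matern32(Xsub, Xsub, lenTheta, 1) +
    cpp_cov_matern32(Tsub, Tsub, lenTau, 1)
  eig <- truncatedEigendecomposition(C, k)
  dk <- pmax(eig$values, 1e-12 * max(abs(eig$values)))
  Kcross <- cpp_cov_matern32(Theta, Xsub, lenTheta, 1) +
    cpp_cov_matern32(Tau, Tsub, lenTau, 1)
  Z <- Kcross %*% sweep(eig$vectors, 2, sqrt(dk), `/`)
  ZtZ <- crossprod(Z)
  ez <- eigen(ZtZ, symmetric = TRUE)
  list(idx = idx, Xsub = Xsub, Tsub = Tsub, lenTheta = lenTheta,
       lenTau = lenTau, Uk = eig$vectors, dk = dk, Z = Z,
       V = ez$vectors, Lambda = pmax(ez$values, 0), N = N, k = k, nr = nr,
       seed = seed)
}

# feature vector(s) z(theta) for query rows
.lowRankFeatures <- function(basis, Theta) {
  Theta <- rbind(Theta)
  Kc <- cpp_cov_matern32(Theta, basis$Xsub, basis$lenTheta, 1) +
    cpp_cov_matern32(1 / Theta, basis$Tsub, basis$lenTau, 1)
  Kc %*% sweep(basis$Uk, 2, sqrt(basis$dk), `/`)
}

# negative log marginal likelihood of y ~ N(beta, s2 Z Z' + sig2 I) in the
# rotated eigenbasis of Z'Z; O(k) per evaluation.
.lowRankNll <- function(p, Lambda, g2overL, yss, N) {
  s2 <- exp(p[1]); sig2 <- exp(p[2])
  denom <- s2 * Lambda + sig2
  quad <- (yss - sum(g2overL * s2 * Lambda / denom)) / sig2
  logdet <- sum(log(denom)) + (N - length(Lambda)) * log(sig2)
  0.5 * (quad + logdet + N * log(2 * pi))
}

.lowRankFitColumn <- function(basis, y, hyper = NULL) {
  beta <- mean(y)
  yc <- y - beta
  g <- drop(crossprod(basis$V, crossprod(basis$Z, yc)))
  yss <- sum(yc^2)
  vy <- max(var(y), 1e-12)
  pos <- basis$Lambda > 1e-12 * max(basis$Lambda, 1e-300)
  g2overL <- ifelse(pos, g^2 / pmax(basis$Lambda, 1e-300), 0)
  if (is.null(hyper)) {
    p0 <- log(c(vy, 1e-4 * vy))
    lb <- log(c(1e-8 * vy, 1e-12 * vy))
    ub <- log(c(1e6 * vy, 1e2 * vy))
    opt <- optim(p0, .lowRankNll, method = "L-BFGS-B", lower = lb,
                 upper = ub, Lambda = basis$Lambda, g2overL = g2overL,
                 yss = yss, N = basis$N)
    s2 <- exp(opt$par[1]); sig2 <- exp(opt$par[2]); nll <- opt$value
  } else {
    s2 <- hyper$s2; sig2 <- hyper$sigma2
    nll <- .lowRankNll(log(c(s2, sig2)), basis$Lambda, g2overL, yss,
                       basis$N)
  }
  # posterior weight vector in feature space: mean(theta) = beta + z(theta).w
  wbar <- drop(basis$V %*% (g / (basis$Lambda + sig2 / s2)))
  list(beta = beta, g = g, s2 = s2, sigma2 = sig2, nll = nll, wbar = wbar)
}

# features z(theta) and their Jacobian dz/dtheta (d x k) at a single query;
# analytic Matern 3/2 derivatives, using (dk/dr)/r = -(3/len^2) exp(-c r)
# which is finite at r = 0.
.lowRankFeatureGrad <- function(basis, theta) {
  theta <- as.numeric(theta)
  tau <- 1 / theta
  D1 <- sweep(basis$Xsub, 2, theta)    # x_i - theta
  D2 <- sweep(basis$Tsub, 2, tau)
  r1 <- sqrt(rowSums(D1^2))
  r2 <- sqrt(rowSums(D2^2))
  c1 <- sqrt(3) / basis$lenTheta
  c2 <- sqrt(3) / basis$lenTau
  e1 <- exp(-c1 * r1)
  e2 <- exp(-c2 * r2)
  kc <- (1 + c1 * r1) * e1 + (1 + c2 * r2) * e2
  UD <- sweep(basis$Uk, 2, sqrt(basis$dk), `/`)
  z <- drop(crossprod(UD, kc))
  # d kc / d theta_d = c1^2 e1 (x_d - theta_d) - c2^2 e2 (t_d - tau_d)/theta_d^2
  dKc <- t(D1 * (c1^2 * e1)) -
    t(D2 * (c2^2 * e2)) * matrix(1 / theta^2, length(theta), nrow(D1))
  list(z = z, dz = dKc %*% UD)
}

# mean/variance for one column given precomputed Vtz = V' z(theta*)
.lowRankColumnPredict <- function(basis, col, Vtz, wantVar = TRUE) {
  ratio <- 1 / (basis$Lambda + col$sigma2 / col$s2)
  mu <- col$beta + colSums(Vtz * (ratio * col$g))
  if (!wantVar) return(list(mean = mu))
  dvar <- col$s2 * col$sigma2 / (col$sigma2 + col$s2 * basis$Lambda)
  list(mean = mu, var = pmax(colSums(Vtz^2 * dvar), 0))
}

#' Fit a low-rank GP
#'
#' Fits a scalar target over the design with a low-rank Gaussian process:
#' the training inputs are randomly subsampled to \code{nr} rows, the summed
#' isotropic Matern 3/2 kernel over (theta, 1/theta) (each term with its own
#' Kammann-Wand default length scale) is eigendecomposed, and the rank-k
#' truncation defines a finite feature expansion whose output scale and
#' noise variance are estimated by maximum marginal likelihood. The additive
#' (theta, 1/theta) structure captures the steep response near the lower
#' stiffness bound.
#'
#' @param Theta N x 4 design matrix.
#' @param y scalar target column (a simulator output or a loss value).
#' @param nr subsample size (default 2000, capped at N).
#' @param k truncation rank (default: nr for output targets, capped by nr);
#'   conventional choices are 2000 for output targets and 1000 for loss
#'   targets.
#' @param seed integer seed controlling the subsample.
#' @param hyper optional list(s2, sigma2) of fixed hyperparameters (skips
#'   the marginal-likelihood optimisation).
#' @return A low-rank GP fit (list with the basis and column coefficients).
#' @export
fitLowRank <- function(Theta, y, nr = 2000L, k = NULL, seed = 1L,
                       hyper = NULL) {
  Theta <- as.matrix(Theta)
  if (length(y) != nrow(Theta)) stop("length(y) must equal nrow(Theta)")
  nr <- min(nr, nrow(Theta))
  if (is.null(k)) k <- nr
  if (k > nr) stop("k must not exceed nr")
  basis <- .lowRankBasis(Theta, nr, k, seed)
  col <- .lowRankFitColumn(basis, y, hyper)
  structure(list(basis = basis, col = col), class = "lowRankGPFit")
}

#' Predict from a low-rank GP fit
#'
#' @param fit a fit from \code{\link{fitLowRank}}.
#' @param thetaStar query point (length 4) or matrix of query rows.
#' @return List with elements \code{mean} and non-negative \code{var}
#'   (vectors over query rows).
#' @export
predictLowRank <- function(fit, thetaStar) {
  Z <- .lowRankFeatures(fit$basis, thetaStar)
  Vtz <- crossprod(fit$basis$V, t(Z))
  p <- .lowRankColumnPredict(fit$basis, fit$col, Vtz)
  list(mean = unname(p$mean), var = unname(p$var))
}
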