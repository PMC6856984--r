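#' ARD squared-exponential kernel
#'
#' k(x, x') = outputScale^2 * exp(-1/2 sum_d ((x_d - x'_d)/l_d)^2), the
#' automatic-relevance-determination kernel with one length scale per input
#' dimension.
#'
#' @param x,xp numeric vectors of equal length (or matrices with matching
#'   column count, in which case the full cross-covariance is returned).
#' @param hyperparams list with elements \code{outputScale} and
#'   \code{lengthScales}.
#' @return Scalar covariance (or cross-covariance matrix for matrix input).
#' @examples
#' h <- list(outputScale = 1, lengthScales = rep(1, 4))
#' ardSeKernel(c(1, 0, 0, 0), c(0, 0, 0, 0), h)  # exp(-0.5)
#' @export
ardSeKernel <- function(x, xp, hyperparams) {
  ls <- hyperparams$lengthScales
  s2 <- hyperparams$outputScale^2
  if (is.matrix(x) || is.matrix(xp)) {
    x <- rbind(x); xp <- rbind(xp)
    return(cpp_cov_ard_se(x, xp, ls, s2))
  }
  if (length(x) != length(xp)) stop("x and xp must have equal dimension")
  s2 * exp(-0.5 * sum(((x - xp) / ls)^2))
}

#' K nearest neighbours in the design
#'
#' Indices of the K design rows with the smallest Euclidean distances to the
#' query, in raw parameter space (all four dimensions share the same scale).
#' Ties are broken by lower row index.
#'
#' @param thetaStar query point.
#' @param Theta N x d design matrix.
#' @param K neighbourhood size, K <= N.
#' @return Integer vector of K row indices, ordered by distance.
#' @export
findNeighbors <- function(thetaStar, Theta, K) {
  Theta <- as.matrix(Theta)
  if (K > nrow(Theta)) stop("K must not exceed the number of design rows")
  d2 <- colSums((t(Theta) - as.numeric(thetaStar))^2)
  order(d2)[seq_len(K)]  # order() is stable: ties resolve to lower index
}

.defaultInitHyperparams <- function(X, y) {
  ls <- apply(X, 2, function(v) max(diff(range(v)), 1e-3))
  list(outputScale = max(sd(y), 1e-8), lengthScales = ls,
       noiseSd = 1e-2, meanConst = mean(y))
}

#' Fit local GP hyperparameters
#'
#' Maximises the log marginal likelihood of a constant-mean Gaussian process
#' with ARD squared-exponential kernel over the output scale, the four
#' length scales and the noise standard deviation, using bounded
#' quasi-Newton (L-BFGS-B) with analytic gradients. The constant mean is
#' profiled out analytically at every step. The noise standard deviation is
#' initialised at 1e-2 (the simulator is deterministic, so the noise mostly
#' regularises the factorisation) and floored at 1e-6.
#'
#' @param X K x d matrix of local training inputs.
#' @param y numeric vector of local training outputs.
#' @param init optional initial hyperparameter list (elements
#'   \code{outputScale}, \code{lengthScales}, \code{noiseSd}); defaults are
#'   derived from the data ranges.
#' @param fixNoise optional fixed noise sd; when given, the noise is not
#'   optimised.
#' @param maxit iteration cap for the optimiser.
#' @return List with elements outputScale, lengthScales, noiseSd, meanConst,
#'   nll (negative log marginal likelihood at the optimum, on the
#'   standardised scale) and convergence. All returned scale parameters are
#'   on the scale of \code{y}.
#' @details The target is standardised internally (centred, unit variance)
#'   before the marginal-likelihood optimisation: the noise initialisation
#'   of 1e-2 and its floor of 1e-6 are relative to the standardised output,
#'   and the returned output scale and noise sd are mapped back to the raw
#'   scale. This keeps the optimisation well conditioned for targets of very
#'   different magnitudes (strains are of order 0.1, volumes of order 100).
#' @export
fitHyperparameters <- function(X, y, init = NULL, fixNoise = NULL,
                               maxit = 60L) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 local points")
  d <- ncol(X)
  s <- sd(y)
  if (s == 0) {
    # degenerate constant outputs: any kernel interpolates the constant
    h <- .defaultInitHyperparams(X, y)
    h$outputScale <- 1e-8
    h$noiseSd <- if (is.null(fixNoise)) 1e-6 else fixNoise
    h$meanConst <- y[1]
    h$nll <- NA_real_
    h$convergence <- 0L
    return(h)
  }
  ys <- (y - mean(y)) / s
  ranges <- apply(X, 2, function(v) max(diff(range(v)), 1e-3))
  if (is.null(init)) {
    ls0 <- 0.5 * ranges
    sf0 <- 1
    sg0 <- 1e-2
  } else {
    ls0 <- init$lengthScales
    sf0 <- init$outputScale / s
    sg0 <- if (is.null(init$noiseSd)) 1e-2 else init$noiseSd / s
  }
  fixSigma <- if (is.null(fixNoise)) -1 else max(fixNoise / s, 0)
  lowerB <- c(rep(log(1e-3), d), log(1e-4))
  upperB <- c(rep(log(1e3), d), log(1e3))
  if (is.null(fixNoise)) {
    lowerB <- c(lowerB, log(1e-6))
    upperB <- c(upperB, log(10))
  }
  S <- cpp_dist2_cube(X)
  memo <- new.env(parent = emptyenv())
  evalAt <- function(p) {
    if (is.null(memo$p) || !identical(p, memo$p)) {
      memo$res <- cpp_nll_ard_se_cached(p, S, ys, fixSigma)
      memo$p <- p
    }
    memo$res
  }
  fn <- function(p) evalAt(p)$value
  gr <- function(p) evalAt(p)$gradient
  runFit <- function(ls, sf, sg) {
    par0 <- c(log(ls), log(max(sf, 1e-4)))
    if (is.null(fixNoise)) par0 <- c(par0, log(max(sg, 1e-6)))
    par0 <- pmin(pmax(par0, lowerB), upperB)
    opt <- optim(par0, fn, gr, method = "L-BFGS-B", lower = lowerB,
                 upper = upperB, control = list(maxit = maxit))
    # the optimiser must not end worse than the initial point
    if (opt$value > fn(par0) + 1e-8) {
      opt$par <- par0
      opt$value <- fn(par0)
    }
    opt
  }
  opt <- runFit(ls0, sf0, sg0)
  # a collapse of every length scale to its lower bound is the signature of
  # the degenerate pure-nugget optimum; restart from a shorter init
  if (all(exp(opt$par[seq_len(d)]) < 2e-3)) {
    opt2 <- runFit(0.125 * ranges, 1, 1e-2)
    if (opt2$value < opt$value) opt <- opt2
  }
  final <- evalAt(opt$par)
  list(outputScale = s * exp(opt$par[d + 1]),
       lengthScales = exp(opt$par[seq_len(d)]),
       noiseSd = if (is.null(fixNoise)) s * exp(opt$par[d + 2]) else fixNoise,
       meanConst = mean(y) + s * final$mean, nll = opt$value,
       convergence = opt$convergence)
}

# factorise a local GP at given hyperparameters
.localFactor <- function(X, y, hyp) {
  f <- cpp_gp_factor(X, y, hyp$lengthScales, hyp$outputScale, hyp$noiseSd)
  list(X = X, hyp = hyp, L = f$L, alpha = drop(f$alpha), meanConst = f$mean)
}

# predictive mean and its analytic gradient d mean / d theta at one query
# (exact for the current factorisation; the ARD-SE kernel differentiates to
# k(theta, x_i) (x_id - theta_d) / ls_d^2)
.localMeanGrad <- function(fac, theta) {
  kv <- drop(cpp_cov_ard_se(fac$X, matrix(theta, 1L), fac$hyp$lengthScales,
                            fac$hyp$outputScale^2))
  ak <- fac$alpha * kv
  grad <- drop(crossprod(sweep(fac$X, 2, theta), ak)) /
    fac$hyp$lengthScales^2
  list(mean = fac$meanConst + sum(ak), grad = grad)
}

.localPredict <- function(fac, Xstar, wantVar = TRUE) {
  Xstar <- rbind(Xstar)
  p <- cpp_gp_predict(Xstar, fac$X, fac$hyp$lengthScales,
                      fac$hyp$outputScale, fac$L, fac$alpha, fac$meanConst,
                      wantVar)
  if (wantVar) list(mean = drop(p$mean), var = drop(p$var))
  else list(mean = drop(p$mean))
}

#' Local GP prediction
#'
#' Predicts a scalar target at a query point using only its K nearest design
#' neighbours: subset the data, re-estimate the kernel hyperparameters on
#' the local set by maximum marginal likelihood, and return the Gaussian
#' process predictive mean and (latent) variance.
#'
#' @param thetaStar query point (length d).
#' @param Theta N x d design matrix.
#' @param y numeric target vector of length N.
#' @param K neighbourhood size (default 100).
#' @param init optional initial hyperparameters (see
#'   \code{\link{fitHyperparameters}}).
#' @param fixNoise optional fixed noise sd.
#' @return List with elements mean, var, hyperparams, neighbors.
#' @export
predictLocal <- function(thetaStar, Theta, y, K = 100L, init = NULL,
                         fixNoise = NULL) {
  Theta <- as.matrix(Theta)
  nb <- findNeighbors(thetaStar, Theta, min(K, nrow(Theta)))
  Xl <- Theta[nb, , drop = FALSE]
  yl <- y[nb]
  hyp <- fitHyperparameters(Xl, yl, init = init, fixNoise = fixNoise)
  fac <- .localFactor(Xl, yl, hyp)
  p <- .localPredict(fac, matrix(thetaStar, 1L))
  list(mean = p$mean, var = max(p$var, 0), hyperparams = hyp,
       neighbors = nb)
}
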