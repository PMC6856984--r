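#' Loss specification constructor
#'
#' @param kind "euclidean" or "mahalanobis".
#' @param sigma noise standard deviation for the Euclidean loss (default 1,
#'   making the loss half the sum of squared residuals).
#' @param Sigma output covariance matrix for the Mahalanobis loss; when NULL
#'   it is estimated from the training outputs at emulator-build time.
#' @param ridge diagonal inflation added to Sigma; NA selects the default
#'   1e-8 times the mean diagonal.
#' @return A \linkS4class{LossSpec}.
#' @export
lossSpec <- function(kind = c("euclidean", "mahalanobis"), sigma = 1,
                     Sigma = NULL, ridge = NA_real_) {
  kind <- match.arg(kind)
  new("LossSpec", kind = kind, sigma = as.numeric(sigma), Sigma = Sigma,
      ridge = as.numeric(ridge))
}

#' Euclidean loss
#'
#' Half the squared Euclidean distance between prediction and observation,
#' scaled by the noise variance: ||yhat - y0||^2 / (2 sigma^2). This is the
#' negative log-likelihood under iid Gaussian errors, with the constant term
#' dropped (it does not depend on theta).
#'
#' @param yHat,y0 numeric vectors of equal length.
#' @param sigma noise standard deviation.
#' @return Non-negative scalar.
#' @examples
#' euclideanLoss(c(3, 4), c(0, 0))  # 12.5
#' @export
euclideanLoss <- function(yHat, y0, sigma = 1) {
  if (length(yHat) != length(y0))
    stop("yHat and y0 must have equal length")
  sum((yHat - y0)^2) / (2 * sigma^2)
}

# Cholesky of Sigma with ridge escalation; returns the upper factor.
.cholRidge <- function(Sigma, ridge = NA_real_) {
  base <- mean(diag(Sigma))
  if (is.na(ridge)) ridge <- 1e-8 * base
  for (i in 0:6) {
    R <- tryCatch(chol(Sigma + diag(ridge * 10^i, nrow(Sigma))),
                  error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  stop("Sigma is not positive-definite even after ridge escalation")
}

#' Mahalanobis loss
#'
#' Half the squared Mahalanobis distance (yhat - y0)' Sigma^-1 (yhat - y0)/2,
#' the negative log-likelihood of a multivariate Gaussian with covariance
#' Sigma up to a constant. Solved through a Cholesky factorisation; the
#' inverse is never formed explicitly.
#'
#' @param yHat,y0 numeric vectors of equal length.
#' @param Sigma symmetric positive-definite covariance (after ridge).
#' @param ridge optional diagonal inflation (NA selects the default).
#' @return Non-negative scalar.
#' @examples
#' mahalanobisLoss(c(1, 2), c(0, 0), diag(c(1, 4)), ridge = 0)  # 1
#' @export
mahalanobisLoss <- function(yHat, y0, Sigma, ridge = 0) {
  if (length(yHat) != length(y0))
    stop("yHat and y0 must have equal length")
  R <- .cholRidge(Sigma, ridge)
  z <- backsolve(R, yHat - y0, transpose = TRUE)
  0.5 * sum(z^2)
}

#' Training-output covariance
#'
#' Unbiased sample covariance of the N x J output matrix, plus a small
#' diagonal ridge that guards against the large scale disparity between the
#' strain columns and the volume column.
#'
#' @param Y N x J output matrix with N >= 2.
#' @param ridge diagonal inflation (NA selects 1e-8 times the mean
#'   diagonal).
#' @return J x J covariance matrix.
#' @export
outputCovariance <- function(Y, ridge = NA_real_) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 2L) stop("need at least 2 rows to estimate a covariance")
  S <- cov(Y)
  if (is.na(ridge)) ridge <- 1e-8 * mean(diag(S))
  S + diag(ridge, ncol(Y))
}

# evaluate a LossSpec on a residual pair, with a prefactored Sigma chol
.evalLoss <- function(spec, yHat, y0, cholSigma = NULL) {
  if (spec@kind == "euclidean")
    return(euclideanLoss(yHat, y0, spec@sigma))
  if (is.null(cholSigma)) {
    if (is.null(spec@Sigma))
      stop("Mahalanobis loss requires Sigma")
    cholSigma <- .cholRidge(spec@Sigma, spec@ridge)
  }
  z <- backsolve(cholSigma, yHat - y0, transpose = TRUE)
  0.5 * sum(z^2)
}
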