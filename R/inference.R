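#' Optimiser configuration constructor
#'
#' @param lower,upper box bounds (default the design hyperbox 0.1..5 in 4D).
#' @param nStarts number of Sobol-scattered starting points (default 50).
#' @param maxit per-start iteration cap (default 100).
#' @param tol convergence tolerance (default 1e-8).
#' @param seed integer seed for stochastic components downstream (MVN
#'   sampling, low-rank subsampling).
#' @return An \linkS4class{OptimConfig}.
#' @export
optimConfig <- function(lower = rep(0.1, 4), upper = rep(5, 4),
                        nStarts = 50L, maxit = 100L, tol = 1e-8,
                        seed = 1L) {
  new("OptimConfig", lower = as.numeric(lower), upper = as.numeric(upper),
      nStarts = as.integer(nStarts), maxit = as.integer(maxit),
      tol = as.numeric(tol), seed = as.integer(seed))
}

.interpChoices <- c("local_gp", "lowrank_gp")

.defaultControl <- function(control, strategy) {
  defaults <- list(K = 100L, refit = "cached", fitMaxit = 40L,
                   warmMaxit = 25L, nr = 2000L, k = NULL, seed = 1L)
  for (nm in names(control)) defaults[[nm]] <- control[[nm]]
  if (is.null(defaults$k))
    defaults$k <- if (strategy == "output") 2000L else 1000L
  defaults
}

# Half the median nearest-neighbour spacing of the design, estimated from a
# subsample; used as the local-GP cache refresh radius.
.refreshRadius <- function(Theta) {
  n <- nrow(Theta)
  idx <- if (n > 256L) round(seq(1L, n, length.out = 256L)) else seq_len(n)
  sub <- Theta[idx, , drop = FALSE]
  nn <- vapply(seq_len(nrow(sub)), function(i) {
    d2 <- colSums((t(Theta) - sub[i, ])^2)
    sqrt(sort(d2, partial = 2)[2])
  }, 0)
  0.5 * median(nn)
}

# refresh the cached local fits for every target column at a query
.localRefresh <- function(bundle, theta) {
  cache <- bundle@cache
  Theta <- bundle@dataset@design
  ctl <- bundle@control
  nb <- findNeighbors(theta, Theta, min(ctl$K, nrow(Theta)))
  Xl <- Theta[nb, , drop = FALSE]
  cols <- cache$targets
  facs <- vector("list", ncol(cols))
  for (j in seq_len(ncol(cols))) {
    yl <- cols[nb, j]
    warm <- if (!is.null(cache$warm)) cache$warm[[j]] else NULL
    hyp <- fitHyperparameters(Xl, yl, init = warm,
                              maxit = if (is.null(warm)) ctl$fitMaxit
                                      else ctl$warmMaxit)
    facs[[j]] <- .localFactor(Xl, yl, hyp)
  }
  cache$facs <- facs
  cache$warm <- lapply(facs, `[[`, "hyp")
  cache$lastTheta <- theta
  cache$nRefits <- (if (is.null(cache$nRefits)) 0L else cache$nRefits) + 1L
  invisible(NULL)
}

.localMeans <- function(bundle, theta, wantVar = FALSE) {
  cache <- bundle@cache
  refit <- identical(bundle@control$refit, "always")
  if (refit || is.null(cache$lastTheta) ||
      sqrt(sum((theta - cache$lastTheta)^2)) > cache$refreshRadius)
    .localRefresh(bundle, theta)
  th <- matrix(theta, 1L)
  preds <- lapply(cache$facs, .localPredict, Xstar = th, wantVar = wantVar)
  if (wantVar)
    list(mean = vapply(preds, `[[`, 0, "mean"),
         var = vapply(preds, `[[`, 0, "var"))
  else
    list(mean = vapply(preds, `[[`, 0, "mean"))
}

.lowrankMeans <- function(bundle, theta, wantVar = FALSE) {
  basis <- bundle@cache$basis
  Z <- .lowRankFeatures(basis, theta)
  Vtz <- crossprod(basis$V, t(Z))
  m <- vapply(bundle@emulators, function(col)
    .lowRankColumnPredict(basis, col, Vtz, wantVar = FALSE)$mean, 0)
  if (!wantVar) return(list(mean = m))
  v <- vapply(bundle@emulators, function(col)
    .lowRankColumnPredict(basis, col, Vtz, wantVar = TRUE)$var, 0)
  list(mean = m, var = v)
}

# Emulated output means and their Jacobian (J x d) at one query; for the
# local interpolator the Jacobian is exact for the currently cached fits,
# for the low-rank interpolator it is exact everywhere.
.bundleMeansJac <- function(bundle, theta) {
  if (bundle@interpolator == "local_gp") {
    cache <- bundle@cache
    refit <- identical(bundle@control$refit, "always")
    if (refit || is.null(cache$lastTheta) ||
        sqrt(sum((theta - cache$lastTheta)^2)) > cache$refreshRadius)
      .localRefresh(bundle, theta)
    res <- lapply(cache$facs, .localMeanGrad, theta = theta)
    list(mean = vapply(res, `[[`, 0, "mean"),
         jac = t(vapply(res, `[[`, numeric(length(theta)), "grad")))
  } else {
    fg <- .lowRankFeatureGrad(bundle@cache$basis, theta)
    list(mean = vapply(bundle@emulators, function(col)
           col$beta + sum(fg$z * col$wbar), 0),
         jac = t(vapply(bundle@emulators, function(col)
           drop(fg$dz %*% col$wbar), numeric(length(theta)))))
  }
}

# surrogate loss and its gradient for either strategy
.bundleLossGrad <- function(bundle, theta, y0 = NULL) {
  if (bundle@strategy == "loss") {
    mj <- .bundleMeansJac(bundle, theta)
    return(list(value = mj$mean[1], gradient = drop(mj$jac[1, ])))
  }
  mj <- .bundleMeansJac(bundle, theta)
  r <- mj$mean - y0
  spec <- bundle@lossSpec
  if (spec@kind == "euclidean") {
    list(value = sum(r^2) / (2 * spec@sigma^2),
         gradient = drop(crossprod(mj$jac, r)) / spec@sigma^2)
  } else {
    R <- bundle@cache$cholSigma
    z <- backsolve(R, r, transpose = TRUE)
    Sr <- backsolve(R, z)
    list(value = 0.5 * sum(z^2), gradient = drop(crossprod(mj$jac, Sr)))
  }
}

# paired objective/gradient closures with a one-step memo (nlminb calls
# them separately at the same point)
.makeObjective <- function(bundle, y0 = NULL) {
  memo <- new.env(parent = emptyenv())
  calc <- function(th) {
    if (is.null(memo$th) || !identical(th, memo$th)) {
      memo$res <- .bundleLossGrad(bundle, th, y0)
      memo$th <- th
    }
    memo$res
  }
  list(fn = function(th) calc(th)$value,
       gr = function(th) calc(th)$gradient)
}

.newBundle <- function(strategy, interpolator, emulators, spec, dataset, y0,
                       control, targets) {
  cache <- new.env(parent = emptyenv())
  cache$targets <- targets
  b <- new("EmulatorBundle", strategy = strategy,
           interpolator = interpolator, emulators = emulators,
           lossSpec = spec, dataset = dataset, y0 = y0, control = control,
           cache = cache)
  if (interpolator == "local_gp")
    cache$refreshRadius <- if (identical(control$refit, "always")) 0
      else .refreshRadius(dataset@design)
  b
}

#' Build an output emulator bundle
#'
#' Output emulation: one independent scalar emulator per simulator output
#' column (25 in the standard strain+volume layout), all sharing the training design.
#' Local-GP bundles are fitted lazily per query; low-rank bundles prefit all
#' columns on a shared eigenbasis.
#'
#' @param dataset training \linkS4class{LVDataset}.
#' @param interpolator "local_gp" or "lowrank_gp".
#' @param spec a \linkS4class{LossSpec} attached for later surrogate-loss
#'   evaluation (Mahalanobis covariance defaults to the training-output
#'   covariance).
#' @param control list of interpolator settings: \code{K} (local
#'   neighbourhood, default 100), \code{refit} ("cached" refreshes the
#'   local fit only when the query moves more than half the median
#'   nearest-neighbour spacing; "always" refits at every query),
#'   \code{fitMaxit}, \code{nr}, \code{k}, \code{seed}.
#' @return An \linkS4class{EmulatorBundle}.
#' @export
buildOutputEmulator <- function(dataset, interpolator = c("local_gp",
                                                          "lowrank_gp"),
                                spec = lossSpec(), control = list()) {
  interpolator <- match.arg(interpolator)
  stopifnot(is(dataset, "LVDataset"))
  ctl <- .defaultControl(control, "output")
  Y <- dataset@outputs
  if (spec@kind == "mahalanobis" && is.null(spec@Sigma))
    spec@Sigma <- outputCovariance(Y, spec@ridge)
  if (interpolator == "local_gp") {
    emulators <- rep(list(NULL), ncol(Y))
    b <- .newBundle("output", interpolator, emulators, spec, dataset,
                    numeric(0), ctl, Y)
  } else {
    basis <- .lowRankBasis(dataset@design, ctl$nr, min(ctl$k, ctl$nr,
                                                       nrow(Y)), ctl$seed)
    emulators <- lapply(seq_len(ncol(Y)), function(j)
      .lowRankFitColumn(basis, Y[, j]))
    b <- .newBundle("output", interpolator, emulators, spec, dataset,
                    numeric(0), ctl, Y)
    b@cache$basis <- basis
  }
  if (spec@kind == "mahalanobis")
    b@cache$cholSigma <- .cholRidge(spec@Sigma, spec@ridge)
  b
}

#' Predict simulator outputs from a bundle
#'
#' @param bundle an output-strategy \linkS4class{EmulatorBundle}.
#' @param theta query parameter vector.
#' @param wantVar also return predictive variances.
#' @return List with \code{mean} (length-25 vector) and optionally
#'   \code{var}.
#' @export
predictOutputs <- function(bundle, theta, wantVar = FALSE) {
  if (bundle@strategy != "output")
    stop("predictOutputs requires an output-strategy bundle")
  if (bundle@interpolator == "local_gp") .localMeans(bundle, theta, wantVar)
  else .lowrankMeans(bundle, theta, wantVar)
}

#' Surrogate output-emulation loss
#'
#' The chosen loss evaluated between the emulated output vector and the
#' observation: l(theta) = d(mhat(theta), y0).
#'
#' @param theta query parameter vector.
#' @param bundle an output-strategy \linkS4class{EmulatorBundle}.
#' @param y0 observation vector (24 strains + volume).
#' @return Scalar surrogate loss.
#' @export
surrogateOutputLoss <- function(theta, bundle, y0) {
  if (bundle@strategy != "output")
    stop("surrogateOutputLoss requires an output-strategy bundle")
  yHat <- predictOutputs(bundle, theta)$mean
  .evalLoss(bundle@lossSpec, yHat, y0, bundle@cache$cholSigma)
}

# losses of every training row against y0, vectorised
.trainingLosses <- function(Y, y0, spec, cholSigma = NULL) {
  R <- sweep(Y, 2, y0)
  if (spec@kind == "euclidean")
    return(rowSums(R^2) / (2 * spec@sigma^2))
  if (is.null(cholSigma)) cholSigma <- .cholRidge(spec@Sigma, spec@ridge)
  W <- backsolve(cholSigma, t(R), transpose = TRUE)
  0.5 * colSums(W^2)
}

#' Build a loss emulator bundle
#'
#' Loss emulation: the chosen loss is evaluated between every training
#' output and the observation, and a single scalar emulator is fitted to
#' the resulting (theta, loss) pairs. This strategy can only be trained
#' after the observation arrives.
#'
#' @param dataset training \linkS4class{LVDataset}.
#' @param y0 observation vector.
#' @param spec a \linkS4class{LossSpec} (Mahalanobis covariance defaults to
#'   the training-output covariance).
#' @param interpolator "local_gp" or "lowrank_gp".
#' @param control interpolator settings, as in
#'   \code{\link{buildOutputEmulator}} (low-rank rank default 1000 for loss
#'   targets).
#' @return An \linkS4class{EmulatorBundle}.
#' @export
buildLossEmulator <- function(dataset, y0, spec = lossSpec(),
                              interpolator = c("local_gp", "lowrank_gp"),
                              control = list()) {
  interpolator <- match.arg(interpolator)
  stopifnot(is(dataset, "LVDataset"))
  Y <- dataset@outputs
  if (length(y0) != ncol(Y))
    stop("y0 must have length ", ncol(Y))
  ctl <- .defaultControl(control, "loss")
  if (spec@kind == "mahalanobis" && is.null(spec@Sigma))
    spec@Sigma <- outputCovariance(Y, spec@ridge)
  cholSigma <- if (spec@kind == "mahalanobis")
    .cholRidge(spec@Sigma, spec@ridge) else NULL
  losses <- .trainingLosses(Y, y0, spec, cholSigma)
  targets <- matrix(losses, ncol = 1L, dimnames = list(NULL, "loss"))
  if (interpolator == "local_gp") {
    b <- .newBundle("loss", interpolator, list(NULL), spec, dataset,
                    as.numeric(y0), ctl, targets)
  } else {
    basis <- .lowRankBasis(dataset@design, ctl$nr,
                           min(ctl$k, ctl$nr, nrow(Y)), ctl$seed)
    col <- .lowRankFitColumn(basis, losses)
    b <- .newBundle("loss", interpolator, list(col), spec, dataset,
                    as.numeric(y0), ctl, targets)
    b@cache$basis <- basis
  }
  if (!is.null(cholSigma)) b@cache$cholSigma <- cholSigma
  b@cache$trainingLosses <- losses
  b
}

#' Predictive mean of an emulated loss
#'
#' The quantity minimised under loss emulation: the conditional (GP
#' predictive) mean of the loss emulator at theta.
#'
#' @param theta query parameter vector.
#' @param bundle a loss-strategy \linkS4class{EmulatorBundle}.
#' @return Scalar predicted loss.
#' @export
emulatedLossMean <- function(theta, bundle) {
  if (bundle@strategy != "loss")
    stop("emulatedLossMean requires a loss-strategy bundle")
  if (bundle@interpolator == "local_gp")
    .localMeans(bundle, theta)$mean[1]
  else {
    basis <- bundle@cache$basis
    Z <- .lowRankFeatures(basis, theta)
    Vtz <- crossprod(basis$V, t(Z))
    .lowRankColumnPredict(basis, bundle@emulators[[1]], Vtz,
                          wantVar = FALSE)$mean
  }
}

#' Bounded multistart minimisation
#'
#' Scatters starting points over the box with a Sobol sequence, ranks them
#' by objective value, and runs a bounded quasi-Newton descent from each in
#' rank order, skipping starts that fall inside the basin of attraction
#' (the sphere around a previously found minimum with radius equal to that
#' run's start-to-minimum distance). The best bound-feasible minimum is
#' returned.
#'
#' @param objective function of a length-d parameter vector, finite on the
#'   box.
#' @param config an \linkS4class{OptimConfig}.
#' @param gradient optional gradient function of the objective; descents use
#'   numerical differences when absent.
#' @param extraStarts optional matrix of additional candidate starting
#'   points (rows), scored and ranked together with the Sobol scatter.
#' @return List with elements \code{par}, \code{value},
#'   \code{nStartsConverged} and a per-start \code{diagnostics} data frame.
#' @export
multistartMinimize <- function(objective, config = optimConfig(),
                               gradient = NULL, extraStarts = NULL) {
  d <- length(config@lower)
  spec <- designSpec(config@nStarts, dims = d, lower = config@lower,
                     upper = config@upper, skip = 1L)
  starts <- scaleToBounds(sobolUnitSequence(spec), config@lower,
                          config@upper)
  if (!is.null(extraStarts)) starts <- rbind(starts, as.matrix(extraStarts))
  vals <- apply(starts, 1, function(s)
    tryCatch(objective(s), error = function(e) NA_real_))
  ord <- order(vals, na.last = TRUE)
  basins <- list()
  best <- NULL
  diag_ <- data.frame(start = ord, startValue = vals[ord],
                      status = NA_character_, value = NA_real_)
  for (r in seq_along(ord)) {
    i <- ord[r]
    s <- starts[i, ]
    if (!is.finite(vals[i])) { diag_$status[r] <- "non-finite"; next }
    inBasin <- any(vapply(basins, function(bs)
      sqrt(sum((s - bs$center)^2)) < bs$radius, TRUE))
    if (inBasin) { diag_$status[r] <- "skipped"; next }
    # nlminb (PORT) rather than optim's L-BFGS-B: the objective may itself
    # run L-BFGS-B internally (local-GP hyperparameter refits), and R's
    # L-BFGS-B implementation is not reentrant.
    opt <- tryCatch(
      stats::nlminb(s, objective, gradient = gradient,
                    lower = config@lower, upper = config@upper,
                    control = list(iter.max = config@maxit,
                                   eval.max = 10L * config@maxit,
                                   rel.tol = config@tol)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) {
      diag_$status[r] <- "failed"
      next
    }
    par <- pmin(pmax(opt$par, config@lower), config@upper)
    if (any(abs(par - opt$par) > 1e-8)) { # infeasible beyond round-off
      diag_$status[r] <- "infeasible"
      next
    }
    basins[[length(basins) + 1L]] <-
      list(center = par, radius = sqrt(sum((s - par)^2)))
    diag_$status[r] <- if (opt$convergence == 0) "converged" else "maxit"
    diag_$value[r] <- opt$objective
    if (is.null(best) || opt$objective < best$value)
      best <- list(par = par, value = opt$objective)
  }
  if (is.null(best))
    stop("all optimisation starts failed; statuses: ",
         paste(unique(diag_$status), collapse = ", "))
  list(par = unname(best$par), value = best$value,
       nStartsConverged = sum(diag_$status == "converged", na.rm = TRUE),
       diagnostics = diag_)
}

#' Hessian-based uncertainty quantification
#'
#' Numerically estimates the Hessian of the surrogate loss at the optimum by
#' central differences; its inverse approximates (a lower bound on) the
#' parameter covariance. Samples are drawn from the multivariate normal
#' centred at the estimate with that covariance, truncated to the parameter
#' box by rejection, and pointwise 2.5/97.5 percent quantiles of the
#' stretch-stress curves over the samples give the confidence bands (widened
#' where necessary so the band always contains the point-estimate curve).
#'
#' @param objective the surrogate loss function.
#' @param thetaHat the minimiser (length 4).
#' @param nSamples number of MVN samples (default 1000).
#' @param seed integer seed for the sampling.
#' @param refs reference constitutive values for the curves.
#' @param grid stretch grid for the curves.
#' @param lower,upper parameter box bounds.
#' @param computeCurves logical; set FALSE to skip the curve bands.
#' @return List with elements hessian, covariance, samples, curves (list
#'   with fibre and sheet \linkS4class{StretchStressCurve}s),
#'   gradientNorm.
#' @export
hessianUncertainty <- function(objective, thetaHat, nSamples = 1000L,
                               seed = 1L, refs = referenceValues(),
                               grid = seq(1, 1.3, by = 0.01),
                               lower = rep(0.1, 4), upper = rep(5, 4),
                               computeCurves = TRUE) {
  d <- length(thetaHat)
  h <- 1e-4 * (upper - lower)
  f0 <- objective(thetaHat)
  ei <- function(i) { v <- numeric(d); v[i] <- 1; v }
  fp <- vapply(seq_len(d), function(i) objective(thetaHat + h[i] * ei(i)), 0)
  fm <- vapply(seq_len(d), function(i) objective(thetaHat - h[i] * ei(i)), 0)
  grad <- (fp - fm) / (2 * h)
  H <- matrix(0, d, d)
  diag(H) <- (fp - 2 * f0 + fm) / h^2
  for (i in seq_len(d - 1)) for (j in (i + 1):d) {
    hij <- (objective(thetaHat + h[i] * ei(i) + h[j] * ei(j)) -
            objective(thetaHat + h[i] * ei(i) - h[j] * ei(j)) -
            objective(thetaHat - h[i] * ei(i) + h[j] * ei(j)) +
            objective(thetaHat - h[i] * ei(i) - h[j] * ei(j))) /
      (4 * h[i] * h[j])
    H[i, j] <- H[j, i] <- hij
  }
  H <- 0.5 * (H + t(H))
  e <- eigen(H, symmetric = TRUE)
  maxev <- max(abs(e$values))
  if (maxev <= 0)
    stop("Hessian is numerically zero; consider profiling over ",
         "identifiable directions")
  floorev <- 1e-10 * maxev
  vals <- pmax(e$values, floorev)
  Hrep <- e$vectors %*% (vals * t(e$vectors))
  covariance <- e$vectors %*% (t(e$vectors) / vals)
  covariance <- 0.5 * (covariance + t(covariance))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  Lc <- chol(covariance)
  samples <- matrix(NA_real_, nSamples, d)
  got <- 0L
  tries <- 0L
  while (got < nSamples && tries < 400L) {
    m <- max(nSamples - got, 64L)
    cand <- matrix(rnorm(m * d), m, d) %*% Lc
    cand <- sweep(cand, 2, thetaHat, `+`)
    ok <- apply(cand, 1, function(r) all(r >= lower & r <= upper))
    keep <- which(ok)
    if (length(keep)) {
      take <- keep[seq_len(min(length(keep), nSamples - got))]
      samples[got + seq_along(take), ] <- cand[take, , drop = FALSE]
      got <- got + length(take)
    }
    tries <- tries + 1L
  }
  if (got < nSamples) {
    # acceptance too low: clamp the remaining draws to the box
    m <- nSamples - got
    cand <- matrix(rnorm(m * d), m, d) %*% Lc
    cand <- sweep(cand, 2, thetaHat, `+`)
    cand <- pmin(pmax(cand, matrix(lower, m, d, byrow = TRUE)),
                 matrix(upper, m, d, byrow = TRUE))
    samples[got + seq_len(m), ] <- cand
    warning("MVN truncation acceptance very low; clamped ", m, " draws")
  }
  colnames(samples) <- paste0("theta", seq_len(d))
  curves <- list()
  if (computeCurves) {
    curves <- lapply(c(fibre = "fibre", sheet = "sheet"), function(dir) {
      point <- stretchStressCurve(pmin(pmax(thetaHat, lower), upper),
                                  refs, dir, grid)
      S <- vapply(seq_len(nSamples), function(s) {
        p <- reduceParameters(samples[s, ], refs)
        uniaxialCauchyStress(p, grid, dir)
      }, numeric(length(grid)))
      lo <- apply(S, 1, quantile, probs = 0.025)
      hi <- apply(S, 1, quantile, probs = 0.975)
      new("StretchStressCurve", direction = dir, stretches = grid,
          stresses = point@stresses,
          lower = pmin(lo, point@stresses),
          upper = pmax(hi, point@stresses))
    })
  }
  list(hessian = Hrep, covariance = covariance, samples = samples,
       curves = curves, gradientNorm = sqrt(sum(grad^2)))
}

#' Estimate reduced constitutive parameters from an observation
#'
#' The end-to-end inverse problem: build the chosen emulator (output or loss
#' strategy, local or low-rank GP), minimise the surrogate loss over the
#' parameter box with the multistart optimiser, and (optionally) attach
#' Hessian-based uncertainty quantification with stretch-stress bands.
#'
#' @param y0 observation vector (24 circumferential strains + volume).
#' @param dataset training \linkS4class{LVDataset}.
#' @param strategy "output" (emulate each simulator output, then compare to
#'   y0) or "loss" (emulate the scalar loss surface directly).
#' @param interpolator "local_gp" or "lowrank_gp".
#' @param spec a \linkS4class{LossSpec}.
#' @param config an \linkS4class{OptimConfig}.
#' @param control interpolator settings (see
#'   \code{\link{buildOutputEmulator}}).
#' @param uq logical, compute Hessian UQ and curve bands (default TRUE).
#' @param nSamples MVN sample count for the UQ step.
#' @param refs reference constitutive values.
#' @param grid stretch grid for the curves.
#' @return An \linkS4class{InferenceResult}.
#' @export
estimateParameters <- function(y0, dataset,
                               strategy = c("output", "loss"),
                               interpolator = c("local_gp", "lowrank_gp"),
                               spec = lossSpec(), config = optimConfig(),
                               control = list(), uq = TRUE,
                               nSamples = 1000L, refs = referenceValues(),
                               grid = seq(1, 1.3, by = 0.01)) {
  t0 <- Sys.time()
  strategy <- match.arg(strategy)
  interpolator <- match.arg(interpolator)
  stopifnot(is(dataset, "LVDataset"))
  if (length(y0) != ncol(dataset@outputs))
    stop("y0 must have length ", ncol(dataset@outputs))
  control$seed <- if (is.null(control$seed)) config@seed else control$seed
  if (strategy == "output") {
    bundle <- buildOutputEmulator(dataset, interpolator, spec, control)
  } else {
    bundle <- buildLossEmulator(dataset, y0, spec, interpolator, control)
  }
  ob <- .makeObjective(bundle, y0)
  objective <- ob$fn
  # score the training design rows by their simulated loss against y0 and
  # add the best few as candidate starts: this mirrors a global search that
  # scores precomputed trial points before running local descents, and is
  # cheap because the training outputs are already available
  trainLoss <- if (strategy == "loss") bundle@cache$trainingLosses
    else .trainingLosses(dataset@outputs, y0, bundle@lossSpec,
                         bundle@cache$cholSigma)
  extra <- dataset@design[order(trainLoss)[seq_len(min(5L,
             length(trainLoss)))], , drop = FALSE]
  opt <- multistartMinimize(objective, config, gradient = ob$gr,
                            extraStarts = extra)
  hess <- matrix(numeric(0), 0, 0)
  covm <- matrix(numeric(0), 0, 0)
  samples <- matrix(numeric(0), 0, 4)
  curves <- list()
  diagn <- list(optim = opt$diagnostics, strategy = strategy,
                interpolator = interpolator, loss = spec@kind)
  if (uq) {
    # re-centre the local-GP cache on the optimum so that every
    # finite-difference point of the Hessian sees the same smooth fit
    # (a refresh boundary inside the difference stencil would corrupt the
    # curvature estimate)
    if (interpolator == "local_gp") {
      bundle@cache$lastTheta <- NULL
      invisible(objective(opt$par))
    }
    u <- hessianUncertainty(objective, opt$par, nSamples = nSamples,
                            seed = config@seed, refs = refs, grid = grid,
                            lower = config@lower, upper = config@upper)
    hess <- u$hessian
    covm <- u$covariance
    samples <- u$samples
    curves <- u$curves
    diagn$gradientNorm <- u$gradientNorm
  }
  diagn$elapsedSec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  new("InferenceResult", thetaHat = opt$par, lossMin = opt$value,
      nStartsConverged = as.integer(opt$nStartsConverged), hessian = hess,
      covariance = covm, samples = samples, curves = curves,
      diagnostics = diagn)
}
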