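#' The eight method combinations
#'
#' @return Data frame with columns strategy, interpolator, loss and a
#'   human-readable method label; 8 rows.
#' @export
methodGrid <- function() {
  g <- expand.grid(strategy = c("output", "loss"),
                   interpolator = c("local_gp", "lowrank_gp"),
                   loss = c("euclidean", "mahalanobis"),
                   stringsAsFactors = FALSE)
  g$method <- paste(g$interpolator, g$strategy, g$loss, sep = "+")
  g[order(g$interpolator, g$strategy, g$loss), c("method", "strategy",
                                                 "interpolator", "loss")]
}

#' Parameter-space mean squared error
#'
#' Mean over the four components of the squared estimation error,
#' (1/4) ||thetaHat - thetaTrue||^2. The mean (rather than sum) convention
#' is fixed and documented; method rankings are invariant to the choice.
#'
#' @param thetaHat,thetaTrue numeric vectors of length 4.
#' @return Non-negative scalar.
#' @export
parameterMSE <- function(thetaHat, thetaTrue) {
  if (length(thetaHat) != length(thetaTrue))
    stop("thetaHat and thetaTrue must have equal length")
  mean((thetaHat - thetaTrue)^2)
}

#' Tukey three-number summary
#'
#' Median and first/third quartiles under the linear-interpolation quantile
#' convention (R's default type 7), fixed and documented.
#'
#' @param values non-empty numeric vector (NAs dropped).
#' @return Named numeric vector c(median, q1, q3).
#' @export
tukeySummary <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty input")
  q <- quantile(values, probs = c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Run the method comparison
#'
#' For every requested method combination and every test point, runs the
#' full inverse estimation against the noiseless test output and records the
#' parameter-space MSE against the known test design row. Individual
#' failures are recorded as missing with a reason rather than aborting the
#' run; non-convergent fits are retained in the MSE distribution (they are
#' the outliers one sees in practice). Deterministic under a fixed seed.
#'
#' @param train,test \linkS4class{LVDataset}s; the test design rows are the
#'   true parameters.
#' @param methods data frame as from \code{\link{methodGrid}} (possibly a
#'   subset); duplicated rows are dropped with a warning.
#' @param config an \linkS4class{OptimConfig}.
#' @param control interpolator settings shared across methods.
#' @param seed integer master seed.
#' @return A \linkS4class{BenchmarkResult}.
#' @export
runMethodComparison <- function(train, test, methods = methodGrid(),
                                config = optimConfig(), control = list(),
                                seed = 1L) {
  stopifnot(is(train, "LVDataset"), is(test, "LVDataset"))
  if (anyDuplicated(methods$method)) {
    warning("duplicate methods dropped")
    methods <- methods[!duplicated(methods$method), ]
  }
  nTest <- nrow(test@design)
  rows <- vector("list", nrow(methods) * nTest)
  r <- 0L
  for (m in seq_len(nrow(methods))) {
    strat <- methods$strategy[m]
    interp <- methods$interpolator[m]
    spec <- lossSpec(methods$loss[m])
    # output-strategy bundles are observation-independent: build once
    bundle <- if (strat == "output")
      buildOutputEmulator(train, interp, spec,
                          c(control, list(seed = seed))) else NULL
    for (i in seq_len(nTest)) {
      r <- r + 1L
      cfg <- config
      cfg@seed <- as.integer((seed + 131L * m + i) %% .Machine$integer.max)
      res <- tryCatch({
        y0 <- test@outputs[i, ]
        b <- if (strat == "output") bundle
          else buildLossEmulator(train, y0, spec, interp,
                                 c(control, list(seed = cfg@seed)))
        ob <- .makeObjective(b, y0)
        trainLoss <- if (strat == "loss") b@cache$trainingLosses
          else .trainingLosses(train@outputs, y0, b@lossSpec,
                               b@cache$cholSigma)
        extra <- train@design[order(trainLoss)[1:5], , drop = FALSE]
        opt <- multistartMinimize(ob$fn, cfg, gradient = ob$gr,
                                  extraStarts = extra)
        list(mse = parameterMSE(opt$par, test@design[i, ]),
             converged = opt$nStartsConverged > 0, reason = "")
      }, error = function(e)
        list(mse = NA_real_, converged = FALSE, reason = conditionMessage(e)))
      rows[[r]] <- data.frame(method = methods$method[m], strategy = strat,
                              interpolator = interp, loss = methods$loss[m],
                              testId = i, mse = res$mse,
                              converged = res$converged,
                              reason = res$reason)
    }
  }
  mse <- do.call(rbind, rows)
  summary <- .benchmarkSummary(mse)
  new("BenchmarkResult", mse = mse, summary = summary,
      seed = as.integer(seed),
      config = list(optim = config, control = control))
}

# Table-4-shaped summary: one row per interpolator x strategy, one summary
# column per loss function.
.benchmarkSummary <- function(mse) {
  combos <- expand.grid(interpolator = c("lowrank_gp", "local_gp"),
                        strategy = c("output", "loss"),
                        stringsAsFactors = FALSE)
  combos <- combos[order(match(combos$interpolator,
                               c("lowrank_gp", "local_gp")),
                         match(combos$strategy, c("output", "loss"))), ]
  fmt <- function(v) {
    if (!length(v) || all(is.na(v))) return(NA_character_)
    s <- tukeySummary(v)
    sprintf("%.4f (%.4f, %.4f)", s["median"], s["q1"], s["q3"])
  }
  out <- data.frame(interpolator = combos$interpolator,
                    strategy = combos$strategy,
                    euclidean = NA_character_,
                    mahalanobis = NA_character_,
                    euclideanMedian = NA_real_,
                    mahalanobisMedian = NA_real_)
  for (i in seq_len(nrow(out))) {
    for (l in c("euclidean", "mahalanobis")) {
      v <- mse$mse[mse$interpolator == out$interpolator[i] &
                   mse$strategy == out$strategy[i] & mse$loss == l]
      out[[l]][i] <- fmt(v)
      if (length(v) && !all(is.na(v)))
        out[[paste0(l, "Median")]][i] <- unname(tukeySummary(v)["median"])
    }
  }
  keep <- !is.na(out$euclidean) | !is.na(out$mahalanobis)
  out[keep, , drop = FALSE]
}
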