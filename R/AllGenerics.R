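#' Accessors for lvemu classes
#'
#' @param object an lvemu S4 object.
#' @name lvemu-accessors
NULL

#' @describeIn lvemu-accessors the N x 4 design matrix of an
#'   \linkS4class{LVDataset}.
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))

#' @describeIn lvemu-accessors the N x 25 output matrix of an
#'   \linkS4class{LVDataset}.
#' @export
setGeneric("outputMatrix", function(object) standardGeneric("outputMatrix"))

#' @describeIn lvemu-accessors the estimated reduced parameter vector of an
#'   \linkS4class{InferenceResult}.
#' @export
setGeneric("thetaHat", function(object) standardGeneric("thetaHat"))

#' @describeIn lvemu-accessors the surrogate loss at the optimum.
#' @export
setGeneric("lossMin", function(object) standardGeneric("lossMin"))

#' @describeIn lvemu-accessors the Hessian-derived 4 x 4 covariance matrix.
#' @export
setGeneric("parameterCovariance",
           function(object) standardGeneric("parameterCovariance"))

#' @describeIn lvemu-accessors the truncated multivariate-normal samples
#'   around the estimate.
#' @export
setGeneric("mvnSamples", function(object) standardGeneric("mvnSamples"))

#' @describeIn lvemu-accessors the stretch-stress curves with 95 percent
#'   bands attached to an \linkS4class{InferenceResult}.
#' @export
setGeneric("curveBands", function(object) standardGeneric("curveBands"))

#' @describeIn lvemu-accessors long-format per-test-point MSE table of a
#'   \linkS4class{BenchmarkResult}.
#' @export
setGeneric("mseLong", function(object) standardGeneric("mseLong"))

#' @describeIn lvemu-accessors the median (Q1, Q3) summary table of a
#'   \linkS4class{BenchmarkResult}.
#' @export
setGeneric("mseSummary", function(object) standardGeneric("mseSummary"))

#' @rdname lvemu-accessors
#' @export
setMethod("designMatrix", "LVDataset", function(object) object@design)

#' @rdname lvemu-accessors
#' @export
setMethod("outputMatrix", "LVDataset", function(object) object@outputs)

#' @rdname lvemu-accessors
#' @export
setMethod("thetaHat", "InferenceResult", function(object) object@thetaHat)

#' @rdname lvemu-accessors
#' @export
setMethod("lossMin", "InferenceResult", function(object) object@lossMin)

#' @rdname lvemu-accessors
#' @export
setMethod("parameterCovariance", "InferenceResult",
          function(object) object@covariance)

#' @rdname lvemu-accessors
#' @export
setMethod("mvnSamples", "InferenceResult", function(object) object@samples)

#' @rdname lvemu-accessors
#' @export
setMethod("curveBands", "InferenceResult", function(object) object@curves)

#' @rdname lvemu-accessors
#' @export
setMethod("mseLong", "BenchmarkResult", function(object) object@mse)

#' @rdname lvemu-accessors
#' @export
setMethod("mseSummary", "BenchmarkResult", function(object) object@summary)

setMethod("show", "LVDataset", function(object) {
  cat("LVDataset:", nrow(object@design), "rows;",
      ncol(object@outputs), "outputs",
      "(", paste(head(colnames(object@outputs), 2), collapse = ", "),
      "... )\n")
  rng <- apply(object@design, 2, range)
  cat("  design range: [", paste(sprintf("%.3g", rng[1, ]), collapse = ", "),
      "] .. [", paste(sprintf("%.3g", rng[2, ]), collapse = ", "), "]\n")
})

setMethod("show", "EmulatorBundle", function(object) {
  cat("EmulatorBundle:", object@strategy, "emulation via",
      object@interpolator, "\n")
  cat("  ", length(object@emulators), "scalar emulator(s);",
      nrow(object@dataset@design), "training points;",
      object@lossSpec@kind, "loss\n")
})

setMethod("show", "InferenceResult", function(object) {
  cat("InferenceResult\n  thetaHat: (",
      paste(sprintf("%.4f", object@thetaHat), collapse = ", "),
      ")\n  surrogate loss:", format(object@lossMin, digits = 6), "\n")
  if (nrow(object@hessian))
    cat("  covariance diag: (",
        paste(sprintf("%.3g", diag(object@covariance)), collapse = ", "),
        ")\n")
  if (nrow(object@samples))
    cat("  ", nrow(object@samples), "MVN samples;",
        length(object@curves), "stretch-stress curve(s)\n")
})

setMethod("show", "BenchmarkResult", function(object) {
  cat("BenchmarkResult:", length(unique(object@mse$method)), "methods x",
      length(unique(object@mse$testId)), "test points\n")
  print(object@summary)
})

setMethod("show", "StretchStressCurve", function(object) {
  cat("StretchStressCurve (", object@direction, "): ",
      length(object@stretches), " points, stretch [",
      sprintf("%.3f", min(object@stretches)), ", ",
      sprintf("%.3f", max(object@stretches)), "], max stress ",
      sprintf("%.4g", max(object@stresses)), " kPa",
      if (length(object@lower)) " (with 95% band)", "\n", sep = "")
})
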