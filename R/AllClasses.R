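#' S4 classes for the left-ventricle emulation framework
#'
#' The package centres on a small set of S4 containers: experimental-design
#' and simulator configuration objects, the paired design/output dataset, the
#' fitted emulator bundle, the inference result with its uncertainty
#' quantification, and the benchmark result of the eight-method comparison.
#'
#' @name lvemu-classes
#' @keywords internal
NULL

#' Sobol design specification
#'
#' Describes a space-filling design over the reduced-parameter hyperbox:
#' number of points, dimension, per-dimension bounds, an optional burn-in
#' (number of initial Sobol points skipped) and optional digital-shift
#' scrambling controlled by a seed.
#'
#' @slot nPoints integer, number of design points.
#' @slot dims integer, dimension of the design (default 4).
#' @slot lower,upper numeric, per-dimension bounds (recycled from scalars).
#' @slot skip integer, number of initial Sobol points to skip.
#' @slot scramble logical, apply a random digital shift.
#' @slot seed integer, seed for the digital shift (ignored unless scrambled).
#' @exportClass DesignSpec
setClass("DesignSpec",
  slots = c(nPoints = "integer", dims = "integer", lower = "numeric",
            upper = "numeric", skip = "integer", scramble = "logical",
            seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@nPoints) != 1L || object@nPoints < 1L)
      msg <- c(msg, "nPoints must be a single integer >= 1")
    if (object@dims < 1L) msg <- c(msg, "dims must be >= 1")
    if (length(object@lower) != object@dims ||
        length(object@upper) != object@dims)
      msg <- c(msg, "lower/upper must have length dims")
    else if (any(object@lower >= object@upper))
      msg <- c(msg, "lower must be < upper componentwise")
    if (object@skip < 0L) msg <- c(msg, "skip must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Toy simulator configuration
#'
#' Configuration of the fast analytic stand-in for the finite-element
#' left-ventricle simulator: per-segment loading pressures (kPa), the
#' baseline cavity volume (mL), the stretch bracket used for root finding,
#' the root residual tolerance, the reference constitutive values and the
#' weak fibre-sheet shear coupling factor.
#'
#' @slot nSegments integer, number of wall segments (24 for the standard
#'   24-strain layout).
#' @slot segmentLoads numeric, per-segment end-diastolic loading pressures in
#'   kPa; must be positive.
#' @slot baselineVolume numeric, unloaded cavity volume in mL.
#' @slot stretchBracket numeric length 2, bracket for the per-segment stretch
#'   root finding.
#' @slot rootTol numeric, absolute residual tolerance (kPa) for recovered
#'   segment stretches.
#' @slot refs named numeric, the eight reference constitutive values.
#' @slot shearCoupling numeric (length 1 or nSegments), factor coupling
#'   segment extension to a fibre-sheet shear so that the fourth reduced
#'   parameter retains a weak but strictly monotone influence on every
#'   output.
#' @slot sheetMix numeric (length nSegments) in \[0, 1): per-segment weight
#'   of the sheet-direction uniaxial response mixed into the segment stress,
#'   emulating the transmural rotation of the material axes across the wall.
#' @exportClass SimulatorConfig
setClass("SimulatorConfig",
  slots = c(nSegments = "integer", segmentLoads = "numeric",
            baselineVolume = "numeric", stretchBracket = "numeric",
            rootTol = "numeric", refs = "numeric", shearCoupling = "numeric",
            sheetMix = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (object@nSegments < 1L) msg <- c(msg, "nSegments must be >= 1")
    if (length(object@segmentLoads) != object@nSegments)
      msg <- c(msg, "segmentLoads must have length nSegments")
    if (any(object@segmentLoads <= 0))
      msg <- c(msg, "segmentLoads must be positive")
    if (object@baselineVolume <= 0)
      msg <- c(msg, "baselineVolume must be positive")
    if (length(object@stretchBracket) != 2L ||
        object@stretchBracket[1] < 1 ||
        diff(object@stretchBracket) <= 0)
      msg <- c(msg, "stretchBracket must be (lo, hi) with 1 <= lo < hi")
    if (any(object@shearCoupling < 0))
      msg <- c(msg, "shearCoupling must be >= 0")
    if (length(object@sheetMix) != object@nSegments ||
        any(object@sheetMix < 0) || any(object@sheetMix >= 1))
      msg <- c(msg, "sheetMix must have length nSegments with values in [0, 1)")
    if (length(msg)) msg else TRUE
  })

#' Paired design/output dataset
#'
#' Holds an N x 4 design matrix of reduced Holzapfel-Ogden parameters and the
#' row-aligned N x 25 simulator output matrix (24 circumferential strains
#' followed by the end-diastolic volume), plus free-form metadata recording
#' provenance (simulator configuration, design specification, seed).
#'
#' @slot design numeric matrix, N x 4 with columns theta1..theta4.
#' @slot outputs numeric matrix, N x 25 with columns strain01..strain24,
#'   volume.
#' @slot metadata list of provenance information.
#' @exportClass LVDataset
setClass("LVDataset",
  slots = c(design = "matrix", outputs = "matrix", metadata = "list"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@design) != nrow(object@outputs))
      msg <- c(msg, "design and outputs must have the same number of rows")
    if (ncol(object@design) != 4L)
      msg <- c(msg, "design must have 4 columns")
    if (anyNA(object@design) || anyNA(object@outputs))
      msg <- c(msg, "missing values are not allowed")
    if (length(msg)) msg else TRUE
  })

#' Loss specification
#'
#' Chooses the observation-vs-prediction discrepancy: Euclidean (iid Gaussian
#' errors with standard deviation \code{sigma}) or Mahalanobis (correlated
#' errors with covariance \code{Sigma}). Additive constants of the negative
#' log-likelihood are dropped as they do not affect the minimiser.
#'
#' @slot kind character, "euclidean" or "mahalanobis".
#' @slot sigma numeric, noise standard deviation for the Euclidean loss.
#' @slot Sigma matrix or NULL; output covariance for the Mahalanobis loss
#'   (estimated from the training outputs when NULL).
#' @slot ridge numeric, diagonal inflation added to Sigma; if NA a default of
#'   1e-8 * mean diagonal is used.
#' @exportClass LossSpec
setClass("LossSpec",
  slots = c(kind = "character", sigma = "numeric", Sigma = "ANY",
            ridge = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (!object@kind %in% c("euclidean", "mahalanobis"))
      msg <- c(msg, "kind must be 'euclidean' or 'mahalanobis'")
    if (object@sigma <= 0) msg <- c(msg, "sigma must be positive")
    if (!is.null(object@Sigma)) {
      S <- object@Sigma
      if (!is.matrix(S) || nrow(S) != ncol(S))
        msg <- c(msg, "Sigma must be a square matrix")
      else if (max(abs(S - t(S))) > 1e-8 * max(abs(S), 1))
        msg <- c(msg, "Sigma must be symmetric")
    }
    if (length(msg)) msg else TRUE
  })

#' Multistart optimiser configuration
#'
#' Bounded multistart local optimisation over the parameter hyperbox:
#' Sobol-scattered starting points are ranked by objective value and a
#' bounded quasi-Newton descent is run from each, skipping starts that fall
#' inside the basin of attraction (sphere of radius equal to the start-to-
#' minimum distance) of a previously found minimum.
#'
#' @slot lower,upper numeric length 4, box bounds (default the design
#'   hyperbox 0.1..5).
#' @slot nStarts integer, number of Sobol starting points (default 50).
#' @slot maxit integer, per-start iteration cap (default 100).
#' @slot tol numeric, convergence tolerance (default 1e-8).
#' @slot seed integer, seed for any stochastic component.
#' @exportClass OptimConfig
setClass("OptimConfig",
  slots = c(lower = "numeric", upper = "numeric", nStarts = "integer",
            maxit = "integer", tol = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@lower) != length(object@upper))
      msg <- c(msg, "lower/upper must have equal length")
    if (any(object@lower >= object@upper))
      msg <- c(msg, "lower must be < upper")
    if (object@nStarts < 1L) msg <- c(msg, "nStarts must be >= 1")
    if (object@maxit < 1L) msg <- c(msg, "maxit must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Stretch-stress curve
#'
#' Cauchy stress (kPa) against stretch along the myocyte (fibre) or sheet
#' direction for uniaxial incompressible extension, with optional pointwise
#' 95\% confidence band.
#'
#' @slot direction character, "fibre" or "sheet".
#' @slot stretches numeric, strictly increasing grid of stretches >= 1.
#' @slot stresses numeric, Cauchy stresses at the grid points.
#' @slot lower,upper numeric, optional 95\% band (length 0 when absent).
#' @exportClass StretchStressCurve
setClass("StretchStressCurve",
  slots = c(direction = "character", stretches = "numeric",
            stresses = "numeric", lower = "numeric", upper = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (!object@direction %in% c("fibre", "sheet"))
      msg <- c(msg, "direction must be 'fibre' or 'sheet'")
    if (length(object@stretches) != length(object@stresses))
      msg <- c(msg, "stretches and stresses must have equal length")
    if (length(object@stretches) > 1 && any(diff(object@stretches) <= 0))
      msg <- c(msg, "stretches must be strictly increasing")
    if (length(object@stretches) && min(object@stretches) < 1)
      msg <- c(msg, "stretches must be >= 1")
    if (length(object@lower) &&
        (length(object@lower) != length(object@stretches) ||
         length(object@upper) != length(object@stretches)))
      msg <- c(msg, "band must match the stretch grid length")
    if (length(msg)) msg else TRUE
  })

#' Fitted emulator bundle
#'
#' A fitted surrogate of the simulator: either 25 independent scalar
#' emulators of the outputs (output emulation) or a single scalar emulator of
#' the loss surface for one observation (loss emulation), with either a
#' local K-nearest-neighbour Gaussian process or a low-rank Gaussian process
#' as the interpolator.
#'
#' @slot strategy character, "output" or "loss".
#' @slot interpolator character, "local_gp" or "lowrank_gp".
#' @slot emulators list of per-target fitted emulators (length 25 for the
#'   output strategy, 1 for the loss strategy).
#' @slot lossSpec a \linkS4class{LossSpec}.
#' @slot dataset the training \linkS4class{LVDataset}.
#' @slot y0 numeric, the observation the loss emulator was trained for
#'   (length 0 for the output strategy).
#' @slot control list of interpolator settings (K, nr, k, caching mode, ...).
#' @slot cache environment holding per-query cached local fits.
#' @exportClass EmulatorBundle
setClass("EmulatorBundle",
  slots = c(strategy = "character", interpolator = "character",
            emulators = "list", lossSpec = "LossSpec", dataset = "LVDataset",
            y0 = "numeric", control = "list", cache = "environment"),
  validity = function(object) {
    msg <- character(0)
    if (!object@strategy %in% c("output", "loss"))
      msg <- c(msg, "strategy must be 'output' or 'loss'")
    if (!object@interpolator %in% c("local_gp", "lowrank_gp"))
      msg <- c(msg, "interpolator must be 'local_gp' or 'lowrank_gp'")
    if (object@strategy == "output" &&
        length(object@emulators) != ncol(object@dataset@outputs))
      msg <- c(msg, "output strategy requires one emulator per output column")
    if (object@strategy == "loss" && length(object@emulators) != 1L)
      msg <- c(msg, "loss strategy requires exactly one emulator")
    if (length(msg)) msg else TRUE
  })

#' Parameter-inference result
#'
#' The estimate returned by \code{\link{estimateParameters}}: the minimising
#' reduced parameter vector, the surrogate loss at the optimum, optimiser
#' diagnostics, the central-difference Hessian at the optimum with its
#' inverse as an approximate covariance, truncated multivariate-normal
#' samples, and stretch-stress curves with 95\% bands.
#'
#' @slot thetaHat numeric length 4, the estimate.
#' @slot lossMin numeric, surrogate loss at the estimate.
#' @slot nStartsConverged integer, number of local descents that converged.
#' @slot hessian 4 x 4 matrix (may be empty when UQ is skipped).
#' @slot covariance 4 x 4 matrix, inverse Hessian after PSD repair.
#' @slot samples S x 4 matrix of truncated MVN samples.
#' @slot curves list of two \linkS4class{StretchStressCurve} objects (fibre,
#'   sheet) when UQ was requested.
#' @slot diagnostics list of optimiser and UQ diagnostics.
#' @exportClass InferenceResult
setClass("InferenceResult",
  slots = c(thetaHat = "numeric", lossMin = "numeric",
            nStartsConverged = "integer", hessian = "matrix",
            covariance = "matrix", samples = "matrix", curves = "list",
            diagnostics = "list"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@thetaHat) != 4L)
      msg <- c(msg, "thetaHat must have length 4")
    if (length(msg)) msg else TRUE
  })

#' Benchmark result
#'
#' Per-method, per-test-point parameter-space mean squared errors for the
#' eight strategy x interpolator x loss combinations, with the
#' median/quartile summary table.
#'
#' @slot mse data.frame with columns method, strategy, interpolator, loss,
#'   testId, mse, converged, reason.
#' @slot summary data.frame, one row per interpolator x strategy with
#'   Euclidean and Mahalanobis summary columns.
#' @slot seed integer.
#' @slot config list recording the run configuration.
#' @exportClass BenchmarkResult
setClass("BenchmarkResult",
  slots = c(mse = "data.frame", summary = "data.frame", seed = "integer",
            config = "list"))
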