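#' Toy simulator configuration constructor
#'
#' The stand-in simulator inflates each of 24 wall segments against its own
#' loading pressure through the real constitutive law and reports the Green
#' strain of the recovered stretch, plus a cavity volume that grows with the
#' mean stretch. Default loads form an increasing grid spanning 0.5 to 2.0
#' kPa with a small deterministic per-segment jitter (so that segments are
#' informative but not identical).
#'
#' @param nSegments number of wall segments (default 24).
#' @param segmentLoads per-segment loading pressures in kPa; defaults to the
#'   jittered increasing grid described above.
#' @param baselineVolume unloaded cavity volume in mL (default 60).
#' @param stretchBracket bracket for the stretch root finding
#'   (default c(1, 1.6)).
#' @param rootTol residual tolerance in kPa for recovered stretches
#'   (default 1e-10).
#' @param refs reference constitutive values.
#' @param shearCoupling fibre-sheet shear coupling factor(s), length 1 or
#'   nSegments (default a deterministic per-segment profile in
#'   \[0.2, 0.8\]); gives the fourth reduced parameter a weak but strictly
#'   monotone influence on every output, emulating its low sensitivity
#'   under circumferential-strain data.
#' @param sheetMix per-segment weight of the sheet-direction response mixed
#'   into the segment stress (default a deterministic profile in
#'   \[0, 0.5\]), emulating transmural rotation of the material axes; the
#'   variation across segments is what makes the anisotropic stiffness and
#'   exponent separable.
#' @return A \linkS4class{SimulatorConfig}.
#' @export
simulatorConfig <- function(nSegments = 24L, segmentLoads = NULL,
                            baselineVolume = 60, stretchBracket = c(1, 1.8),
                            rootTol = 1e-10, refs = referenceValues(),
                            shearCoupling = NULL, sheetMix = NULL) {
  nSegments <- as.integer(nSegments)
  j <- seq_len(nSegments)
  if (is.null(segmentLoads))
    segmentLoads <- seq(0.5, 2.0, length.out = nSegments) +
      0.015 * sin(2.7 * j)
  if (is.null(shearCoupling)) shearCoupling <- 0.2 + 0.3 * (1 + cos(0.9 * j))
  if (is.null(sheetMix)) sheetMix <- 0.25 * (1 + sin(1.7 * j))
  if (length(shearCoupling) == 1L)
    shearCoupling <- rep(shearCoupling, nSegments)
  new("SimulatorConfig", nSegments = nSegments,
      segmentLoads = as.numeric(segmentLoads),
      baselineVolume = as.numeric(baselineVolume),
      stretchBracket = as.numeric(stretchBracket),
      rootTol = as.numeric(rootTol), refs = refs,
      shearCoupling = as.numeric(shearCoupling),
      sheetMix = as.numeric(sheetMix))
}

# Segment stress: a per-segment mixture of the fibre- and sheet-direction
# uniaxial Cauchy stresses (weight w emulating the transmural rotation of
# the material axes) augmented with a weak fibre-sheet shear contribution
# (effective I8fs = gamma * (lam - 1)). Strictly increasing in lam for
# lam >= 1 and in every constitutive parameter, which makes the inflation
# model strictly monotone in theta. Vectorised over matrices.
.segmentStress <- function(lam, a, b, af, bf, as_, bs, afs, bfs, gamma, w) {
  I1 <- lam^2 + 2 / lam
  iso <- a * (lam^2 - 1 / lam) * exp(b * (I1 - 3))
  fib <- 2 * af * lam^2 * (lam^2 - 1) * exp(bf * (lam^2 - 1)^2)
  sht <- 2 * as_ * lam^2 * (lam^2 - 1) * exp(bs * (lam^2 - 1)^2)
  shr <- afs * gamma^2 * lam * (lam - 1) *
    exp(bfs * gamma^2 * (lam - 1)^2)
  iso + (1 - w) * fib + w * sht + shr
}

# Vectorised bisection solving .segmentStress(lam) = load for every
# (design row, segment) pair simultaneously. The stress is strictly
# increasing in lam on [1, hi], so bisection is safe; ~55 iterations take
# the interval below machine precision.
.solveStretches <- function(Theta, config) {
  n <- nrow(Theta)
  ns <- config@nSegments
  refs <- config@refs
  a   <- Theta[, 1] * refs[["a0"]]
  b   <- Theta[, 1] * refs[["b0"]]
  af  <- Theta[, 2] * refs[["af0"]]
  bf  <- Theta[, 3] * refs[["bf0"]]
  as_ <- Theta[, 2] * refs[["as0"]]
  bs  <- Theta[, 3] * refs[["bs0"]]
  afs <- Theta[, 4] * refs[["afs0"]]
  bfs <- Theta[, 4] * refs[["bfs0"]]
  P <- matrix(config@segmentLoads, n, ns, byrow = TRUE)
  G <- matrix(config@shearCoupling, n, ns, byrow = TRUE)
  W <- matrix(config@sheetMix, n, ns, byrow = TRUE)
  A <- matrix(a, n, ns); B <- matrix(b, n, ns)
  AF <- matrix(af, n, ns); BF <- matrix(bf, n, ns)
  AS <- matrix(as_, n, ns); BS <- matrix(bs, n, ns)
  AFS <- matrix(afs, n, ns); BFS <- matrix(bfs, n, ns)
  sg <- function(l) .segmentStress(l, A, B, AF, BF, AS, BS, AFS, BFS, G, W)
  hi0 <- config@stretchBracket[2]
  short <- sg(hi0 + 0 * P) < P
  if (any(short)) {
    w <- which(short, arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("segment %d (design row %d): load %.4g kPa not ",
                        "bracketed within stretch %g"),
                 w[2], w[1], P[w[1], w[2]], hi0))
  }
  lo <- matrix(max(config@stretchBracket[1], 1), n, ns)
  hi <- matrix(hi0, n, ns)
  for (it in seq_len(55L)) {
    mid <- 0.5 * (lo + hi)
    below <- sg(mid) < P
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  lam <- 0.5 * (lo + hi)
  resid <- abs(sg(lam) - P)
  if (max(resid) > max(config@rootTol, 1e-8))
    stop("stretch root finding did not reach the residual tolerance")
  lam
}

.outputNames <- function(ns) c(sprintf("strain%02d", seq_len(ns)), "volume")

# matrix-level forward map: N x 4 design -> N x (nSegments + 1) outputs
.simulateMatrix <- function(Theta, config) {
  lam <- .solveStretches(Theta, config)
  strains <- (lam^2 - 1) / 2
  volume <- config@baselineVolume * (1 + rowMeans(lam - 1))^3
  out <- cbind(strains, volume)
  colnames(out) <- .outputNames(config@nSegments)
  rownames(out) <- NULL
  out
}

#' Simulate one output vector
#'
#' Deterministic forward map from a reduced parameter vector to 24
#' circumferential strains plus the end-diastolic volume. For each segment
#' the stretch that balances the segment load is recovered by bracketed
#' root finding on the constitutive stress; the Green strain
#' (lambda^2 - 1)/2 is reported, and the volume is
#' V0 * (1 + mean(lambda - 1))^3. Stiffer tissue (larger theta) yields
#' strictly smaller strains and volume.
#'
#' @param theta numeric length 4 within the hyperbox.
#' @param config a \linkS4class{SimulatorConfig}.
#' @return Named numeric vector of length nSegments + 1 (strain01..strain24,
#'   volume).
#' @examples
#' simulateOutput(c(1, 1, 1, 1))
#' @export
simulateOutput <- function(theta, config = simulatorConfig()) {
  .checkTheta(theta)
  drop(.simulateMatrix(matrix(theta, 1L), config))
}

#' Construct a paired dataset
#'
#' @param design N x 4 design matrix within the hyperbox.
#' @param outputs N x J output matrix aligned row-wise.
#' @param metadata optional provenance list.
#' @return An \linkS4class{LVDataset}.
#' @export
lvDataset <- function(design, outputs, metadata = list()) {
  design <- as.matrix(design)
  outputs <- as.matrix(outputs)
  colnames(design) <- paste0("theta", seq_len(ncol(design)))
  if (is.null(colnames(outputs)))
    colnames(outputs) <- .outputNames(ncol(outputs) - 1L)
  new("LVDataset", design = design, outputs = outputs, metadata = metadata)
}

#' Generate train/test benchmark datasets
#'
#' Builds the Sobol train/test designs (the test design continues the same
#' sequence) and runs the toy simulator row-wise over both. Fully
#' deterministic given the specification; test outputs carry no observation
#' noise, matching how benchmark test sets are produced straight from the
#' simulator.
#'
#' @param nTrain,nTest numbers of training and test points.
#' @param config a \linkS4class{SimulatorConfig}.
#' @param spec a \linkS4class{DesignSpec} controlling the Sobol sequence.
#' @return List with elements \code{train} and \code{test}, each an
#'   \linkS4class{LVDataset}.
#' @examples
#' ds <- generateDataset(32, 4)
#' ds$train
#' @export
generateDataset <- function(nTrain, nTest, config = simulatorConfig(),
                            spec = designSpec(1L)) {
  d <- makeTrainTestDesign(nTrain, nTest, spec)
  meta <- list(config = config, spec = spec)
  list(train = lvDataset(d$train, .simulateMatrix(d$train, config), meta),
       test = lvDataset(d$test, .simulateMatrix(d$test, config), meta))
}

#' Add observation noise to an output vector
#'
#' Adds independent Gaussian noise on the strain and volume scales,
#' reproducibly for a given seed. The global random-number state is left
#' untouched.
#'
#' @param y output vector (strains then volume).
#' @param strainSd standard deviation for the strain entries (default 0.01,
#'   a plausible strain measurement error from cine MRI).
#' @param volumeSd standard deviation for the volume entry in mL (default 1).
#' @param seed integer seed.
#' @return Noisy output vector of the same length and names.
#' @export
addObservationNoise <- function(y, strainSd = 0.01, volumeSd = 1,
                                seed = 1L) {
  if (strainSd < 0 || volumeSd < 0) stop("noise sds must be >= 0")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  J <- length(y)
  noise <- c(rnorm(J - 1L, 0, strainSd), rnorm(1L, 0, volumeSd))
  y + noise
}

#' Read / write datasets as CSV
#'
#' The on-disk format is one row per design point with columns
#' theta1..theta4, strain01..strain24, volume. \code{readDataset} validates
#' the header and every cell, reporting the first offending line.
#'
#' @param path CSV file path.
#' @return \code{readDataset} returns an \linkS4class{LVDataset};
#'   \code{writeDataset} returns \code{path} invisibly.
#' @export
readDataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  need <- c(paste0("theta", 1:4), .outputNames(24L))
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("malformed header: missing column(s) ",
         paste(missing, collapse = ", "))
  df <- df[, need]
  for (cn in need) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop(sprintf("non-numeric cell in column %s at data line %d", cn,
                   if (is.na(bad)) 1L else bad))
    }
    if (anyNA(v))
      stop(sprintf("missing value in column %s at data line %d", cn,
                   which(is.na(v))[1]))
  }
  lvDataset(as.matrix(df[, 1:4]), as.matrix(df[, -(1:4)]),
            metadata = list(source = path))
}

#' @rdname readDataset
#' @param dataset an \linkS4class{LVDataset}.
#' @export
writeDataset <- function(dataset, path) {
  stopifnot(is(dataset, "LVDataset"))
  df <- data.frame(dataset@design, dataset@outputs, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
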