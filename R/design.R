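#' Design specification constructor
#'
#' @param nPoints number of design points.
#' @param dims design dimension (default 4, the reduced-parameter space).
#' @param lower,upper per-dimension bounds; scalars are recycled
#'   (defaults 0.1 and 5, the reduced-parameter hyperbox).
#' @param skip number of initial Sobol points to skip (burn-in, default 0).
#' @param scramble apply a seeded random digital shift (default off, for
#'   cross-run and cross-language reproducibility of the plain sequence).
#' @param seed integer seed used only when \code{scramble = TRUE}.
#' @return A \linkS4class{DesignSpec}.
#' @examples
#' designSpec(128)
#' @export
designSpec <- function(nPoints, dims = 4L, lower = 0.1, upper = 5,
                       skip = 0L, scramble = FALSE, seed = 1L) {
  dims <- as.integer(dims)
  if (length(lower) == 1L) lower <- rep(lower, dims)
  if (length(upper) == 1L) upper <- rep(upper, dims)
  new("DesignSpec", nPoints = as.integer(nPoints), dims = dims,
      lower = as.numeric(lower), upper = as.numeric(upper),
      skip = as.integer(skip), scramble = isTRUE(scramble),
      seed = as.integer(seed))
}

# Direction-number data (Joe & Kuo style) for Sobol dimensions 2..8; the
# first dimension is the van der Corput sequence in base 2.
.SOBOL_POLY <- list(
  list(s = 1L, a = 0L, m = c(1L)),
  list(s = 2L, a = 1L, m = c(1L, 3L)),
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L)),
  list(s = 4L, a = 4L, m = c(1L, 3L, 5L, 13L)),
  list(s = 5L, a = 2L, m = c(1L, 1L, 5L, 5L, 17L)))

.SOBOL_NBITS <- 31L
.SOBOL_MAXDIM <- length(.SOBOL_POLY) + 1L

# direction numbers for one dimension, scaled to integers in [0, 2^31)
.sobolDirections <- function(d) {
  nb <- .SOBOL_NBITS
  m <- integer(nb)
  if (d == 1L) {
    m[] <- 1L
  } else {
    p <- .SOBOL_POLY[[d - 1L]]
    s <- p$s
    m[seq_len(s)] <- p$m
    if (nb > s) for (i in (s + 1L):nb) {
      val <- bitwXor(m[i - s], bitwShiftL(m[i - s], s))
      if (s > 1L) for (j in seq_len(s - 1L)) {
        if (bitwAnd(bitwShiftR(p$a, s - 1L - j), 1L) == 1L)
          val <- bitwXor(val, bitwShiftL(m[i - j], j))
      }
      m[i] <- val
    }
  }
  as.integer(m * 2^(nb - seq_len(nb)))
}

#' Sobol sequence on the unit hypercube
#'
#' Generates the first \code{nPoints} points (after any skip) of the Sobol
#' low-discrepancy sequence in \code{dims} dimensions, in Gray-code order
#' (the ordering used by standard quasi-Monte-Carlo implementations; any
#' prefix of length 2^m covers the same point set as the natural order).
#' Optional scrambling applies a seeded random digital shift (XOR of a fixed
#' random bit pattern per dimension), which preserves the digital-net
#' structure.
#'
#' @param spec a \linkS4class{DesignSpec}.
#' @return An nPoints x dims matrix with entries in \[0, 1).
#' @examples
#' sobolUnitSequence(designSpec(8, lower = 0, upper = 1))
#' @export
sobolUnitSequence <- function(spec) {
  stopifnot(is(spec, "DesignSpec"))
  n <- spec@nPoints
  dims <- spec@dims
  if (dims > .SOBOL_MAXDIM)
    stop("Sobol generator supports at most ", .SOBOL_MAXDIM, " dimensions")
  if (spec@skip + n >= 2^.SOBOL_NBITS)
    stop("requested index range exceeds the generator period")
  V <- vapply(seq_len(dims), .sobolDirections, integer(.SOBOL_NBITS))
  idx <- spec@skip + seq_len(n) - 1
  gray <- bitwXor(as.integer(idx), as.integer(idx %/% 2))
  X <- matrix(0L, n, dims)
  for (k in seq_len(.SOBOL_NBITS)) {
    hit <- bitwAnd(bitwShiftR(gray, k - 1L), 1L) == 1L
    if (any(hit))
      X[hit, ] <- bitwXor(X[hit, , drop = FALSE],
                          matrix(V[k, ], sum(hit), dims, byrow = TRUE))
  }
  if (spec@scramble) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(spec@seed)
    shift <- as.integer(floor(runif(dims) * 2^.SOBOL_NBITS))
    X <- bitwXor(X, matrix(shift, n, dims, byrow = TRUE))
  }
  X / 2^.SOBOL_NBITS
}

#' Scale unit-cube points to box bounds
#'
#' Affine map x -> lower + x * (upper - lower), componentwise.
#'
#' @param unitPoints matrix with entries in \[0, 1\].
#' @param lower,upper per-dimension bounds (scalars recycled).
#' @return Matrix of the same shape with columns named theta1, theta2, ...
#' @export
scaleToBounds <- function(unitPoints, lower = 0.1, upper = 5) {
  unitPoints <- as.matrix(unitPoints)
  d <- ncol(unitPoints)
  if (length(lower) == 1L) lower <- rep(lower, d)
  if (length(upper) == 1L) upper <- rep(upper, d)
  if (min(unitPoints) < 0 || max(unitPoints) > 1)
    stop("unit points must lie in [0, 1]")
  out <- sweep(sweep(unitPoints, 2, upper - lower, `*`), 2, lower, `+`)
  colnames(out) <- paste0("theta", seq_len(d))
  out
}

#' Train/test Sobol design
#'
#' Generates a training design of \code{nTrain} points and an independent
#' test design formed by continuing the same Sobol sequence for a further
#' \code{nTest} points (indices nTrain .. nTrain + nTest - 1 after any
#' skip), mirroring the way the benchmark datasets extend the training
#' sequence. No point is duplicated.
#'
#' @param nTrain,nTest numbers of training and test points (each >= 1).
#' @param spec a \linkS4class{DesignSpec}; its \code{nPoints} is ignored.
#' @return List with elements \code{train} and \code{test}, scaled design
#'   matrices with columns theta1..theta4.
#' @examples
#' d <- makeTrainTestDesign(64, 8)
#' dim(d$train); dim(d$test)
#' @export
makeTrainTestDesign <- function(nTrain, nTest, spec = designSpec(1L)) {
  stopifnot(nTrain >= 1, nTest >= 1)
  full <- spec
  full@nPoints <- as.integer(nTrain + nTest)
  U <- sobolUnitSequence(full)
  X <- scaleToBounds(U, spec@lower, spec@upper)
  list(train = X[seq_len(nTrain), , drop = FALSE],
       test = X[nTrain + seq_len(nTest), , drop = FALSE])
}
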