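#' Reference constitutive values
#'
#' The eight published reference values of the Holzapfel-Ogden law for human
#' myocardium that anchor the reduced four-parameter description. a-type
#' values are stresses in kPa, b-type values are dimensionless exponents.
#'
#' @param a0,b0 isotropic matrix stiffness and exponent.
#' @param af0,bf0 fibre (myocyte) stiffness and exponent.
#' @param as0,bs0 sheet stiffness and exponent.
#' @param afs0,bfs0 fibre-sheet coupling stiffness and exponent.
#' @return Named numeric vector with elements a0, b0, af0, as0, bf0, bs0,
#'   afs0, bfs0.
#' @examples
#' referenceValues()
#' @export
referenceValues <- function(a0 = 0.22, b0 = 1.62, af0 = 2.43, as0 = 0.56,
                            bf0 = 1.83, bs0 = 0.77, afs0 = 0.39,
                            bfs0 = 1.70) {
  refs <- c(a0 = a0, b0 = b0, af0 = af0, as0 = as0, bf0 = bf0, bs0 = bs0,
            afs0 = afs0, bfs0 = bfs0)
  if (any(!is.finite(refs)) || any(refs <= 0))
    stop("all reference values must be strictly positive")
  refs
}

.checkTheta <- function(theta) {
  if (length(theta) != .THETA_DIM)
    stop("theta must have length ", .THETA_DIM, ", got ", length(theta))
  if (any(!is.finite(theta)))
    stop("theta must be finite")
  bad <- which(theta < .THETA_LOWER | theta > .THETA_UPPER)
  if (length(bad))
    stop(sprintf("theta%d = %g is outside [%g, %g]", bad[1], theta[bad[1]],
                 .THETA_LOWER, .THETA_UPPER))
  invisible(theta)
}

#' Reduced Holzapfel-Ogden parameterization
#'
#' Maps the four reduced parameters theta onto the eight constitutive
#' constants by scaling published reference values: theta1 scales the
#' isotropic pair (a, b), theta2 the anisotropic stiffnesses (af, as),
#' theta3 the anisotropic exponents (bf, bs) and theta4 the fibre-sheet
#' coupling pair (afs, bfs). The grouping restores identifiability that the
#' full eight-parameter law lacks under in vivo strain data.
#'
#' @param theta numeric length 4, each component in \[0.1, 5\].
#' @param refs named reference values as from \code{\link{referenceValues}}.
#' @return Named numeric vector with elements a, b, af, bf, as, bs, afs, bfs
#'   (a-type in kPa).
#' @examples
#' reduceParameters(c(1, 1, 1, 1))    # returns the reference values
#' @export
reduceParameters <- function(theta, refs = referenceValues()) {
  .checkTheta(theta)
  if (any(refs <= 0)) stop("reference values must be positive")
  c(a   = unname(theta[1] * refs[["a0"]]),
    b   = unname(theta[1] * refs[["b0"]]),
    af  = unname(theta[2] * refs[["af0"]]),
    bf  = unname(theta[3] * refs[["bf0"]]),
    as  = unname(theta[2] * refs[["as0"]]),
    bs  = unname(theta[3] * refs[["bs0"]]),
    afs = unname(theta[4] * refs[["afs0"]]),
    bfs = unname(theta[4] * refs[["bfs0"]]))
}

#' Deformation state
#'
#' Bundles a deformation gradient with the material fibre and sheet
#' directions. The right Cauchy-Green tensor C = F'F and the Jacobian
#' J = det(F) are derived on construction.
#'
#' @param F 3 x 3 deformation gradient with positive determinant.
#' @param f0,s0 unit 3-vectors, fibre and sheet directions; must be
#'   orthonormal for the uniaxial protocols used here.
#' @param Kpen incompressibility penalty constant (default 1e6).
#' @return List with elements F, f0, s0, C, J, Kpen.
#' @export
deformationState <- function(F, f0 = c(1, 0, 0), s0 = c(0, 1, 0),
                             Kpen = 1e6) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(3L, 3L))) stop("F must be 3 x 3")
  J <- det(F)
  if (!is.finite(J) || J <= 0) stop("F must have positive determinant")
  if (abs(sum(f0^2) - 1) > 1e-8 || abs(sum(s0^2) - 1) > 1e-8)
    stop("f0 and s0 must be unit vectors")
  if (abs(sum(f0 * s0)) > 1e-8)
    stop("f0 and s0 must be orthogonal for the uniaxial protocols")
  list(F = F, f0 = as.numeric(f0), s0 = as.numeric(s0),
       C = crossprod(F), J = J, Kpen = Kpen)
}

#' Deformation invariants
#'
#' Computes I1 = tr(C), I4f = f0.(C f0), I4s = s0.(C s0) and
#' I8fs = f0.(C s0) from a deformation state.
#'
#' @param state a deformation state from \code{\link{deformationState}}.
#' @return List with elements I1, I4f, I4s, I8fs.
#' @export
computeInvariants <- function(state) {
  C <- state$C
  list(I1   = sum(diag(C)),
       I4f  = as.numeric(crossprod(state$f0, C %*% state$f0)),
       I4s  = as.numeric(crossprod(state$s0, C %*% state$s0)),
       I8fs = as.numeric(crossprod(state$f0, C %*% state$s0)))
}

#' Holzapfel-Ogden strain energy
#'
#' Evaluates the orthotropic strain-energy density: an isotropic exponential
#' in I1 - 3, tension-only exponential terms in (I4f - 1)^2 and (I4s - 1)^2,
#' a fibre-sheet coupling exponential in I8fs^2, and a quadratic volumetric
#' penalty (Kpen/2)(J - 1)^2. The anisotropic I4 terms contribute only when
#' the corresponding invariant exceeds 1 (fibres do not support compression),
#' the standard convention for this law.
#'
#' @param params named constitutive constants, as from
#'   \code{\link{reduceParameters}}.
#' @param state a deformation state from \code{\link{deformationState}}.
#' @return Strain energy in kPa.
#' @export
strainEnergy <- function(params, state) {
  inv <- computeInvariants(state)
  a <- params[["a"]]; b <- params[["b"]]
  psi <- a / (2 * b) * (exp(b * (inv$I1 - 3)) - 1)
  if (inv$I4f > 1) {
    af <- params[["af"]]; bf <- params[["bf"]]
    psi <- psi + af / (2 * bf) * (exp(bf * (inv$I4f - 1)^2) - 1)
  }
  if (inv$I4s > 1) {
    as_ <- params[["as"]]; bs <- params[["bs"]]
    psi <- psi + as_ / (2 * bs) * (exp(bs * (inv$I4s - 1)^2) - 1)
  }
  afs <- params[["afs"]]; bfs <- params[["bfs"]]
  psi <- psi + afs / (2 * bfs) * (exp(bfs * inv$I8fs^2) - 1)
  psi + 0.5 * state$Kpen * (state$J - 1)^2
}

# Analytic Cauchy stress for incompressible uniaxial extension along the
# fibre (or sheet) axis: F = diag(lam, lam^-1/2, lam^-1/2) in the material
# frame, hydrostatic pressure eliminated by the zero-lateral-stress
# condition. Under fibre loading I4s = 1/lam < 1 (and vice versa), so the
# transverse anisotropic term is inactive and sigma = lam * dPsi/dlam with
# Psi restricted to the isochoric kinematics. Vectorised over lam.
.uniaxialStress <- function(lam, a, b, aAx, bAx) {
  I1 <- lam^2 + 2 / lam
  iso <- a * (lam^2 - 1 / lam) * exp(b * (I1 - 3))
  axl <- 2 * aAx * lam^2 * (lam^2 - 1) * exp(bAx * (lam^2 - 1)^2)
  iso + ifelse(lam > 1, axl, 0)
}

#' Uniaxial Cauchy stress
#'
#' Cauchy stress along the loading axis for incompressible uniaxial
#' extension along the fibre or sheet direction, with the transverse
#' directions stress free. Equals lambda * dPsi/dlambda for the isochoric
#' strain energy under the same kinematics (the volumetric penalty vanishes
#' identically because J = 1 is enforced kinematically).
#'
#' @param params named constitutive constants, as from
#'   \code{\link{reduceParameters}}.
#' @param stretch numeric vector of stretches, each >= 1.
#' @param direction "fibre" (myocyte) or "sheet".
#' @return Cauchy stress in kPa, same length as \code{stretch}.
#' @export
uniaxialCauchyStress <- function(params, stretch,
                                 direction = c("fibre", "sheet")) {
  direction <- match.arg(direction)
  if (any(stretch < 1))
    stop("stretch must be >= 1 (compression protocols are not supported)")
  if (direction == "fibre")
    .uniaxialStress(stretch, params[["a"]], params[["b"]],
                    params[["af"]], params[["bf"]])
  else
    .uniaxialStress(stretch, params[["a"]], params[["b"]],
                    params[["as"]], params[["bs"]])
}

#' Stretch-stress curve
#'
#' Applies the reduced parameterization and evaluates the uniaxial Cauchy
#' stress over a grid of stretches, returning a
#' \linkS4class{StretchStressCurve}.
#'
#' @param theta numeric length 4, reduced parameters in \[0.1, 5\].
#' @param refs reference values, as from \code{\link{referenceValues}}.
#' @param direction "fibre" or "sheet".
#' @param grid strictly increasing stretch grid with minimum >= 1.
#' @return A \linkS4class{StretchStressCurve}.
#' @examples
#' stretchStressCurve(c(1, 1, 1, 1), direction = "fibre",
#'                    grid = seq(1, 1.3, by = 0.05))
#' @export
stretchStressCurve <- function(theta, refs = referenceValues(),
                               direction = c("fibre", "sheet"),
                               grid = seq(1, 1.3, by = 0.01)) {
  direction <- match.arg(direction)
  if (length(grid) > 1 && any(diff(grid) <= 0))
    stop("grid must be strictly increasing")
  if (min(grid) < 1) stop("grid must start at stretch >= 1")
  params <- reduceParameters(theta, refs)
  new("StretchStressCurve", direction = direction, stretches = grid,
      stresses = uniaxialCauchyStress(params, grid, direction),
      lower = numeric(0), upper = numeric(0))
}

#' Export a stretch-stress curve to CSV
#'
#' Writes columns direction, stretch, stress and (when present) lo95, hi95.
#'
#' @param curve a \linkS4class{StretchStressCurve}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeCurve <- function(curve, path) {
  df <- data.frame(direction = curve@direction, stretch = curve@stretches,
                   stress = curve@stresses)
  if (length(curve@lower)) {
    df$lo95 <- curve@lower
    df$hi95 <- curve@upper
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
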