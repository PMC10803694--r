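#' @include AllClasses.R AllGenerics.R volumes.R
NULL

# Fixed shape constants of the model family (not per-subject parameters).
# The healthy deformation profile w(x) peaks at normalised radius 0.9 (width
# 0.42 in r^2 units) and is emphasised on the inferior (basal) half through a
# 15 mm logistic ramp flooring at 0.5 superiorly -- the peripheral-basal
# pattern of compliant breathing.  Severity attenuates that profile on the
# peripheral shell only (transition width 0.18 in r^2 units), capped so a
# fully stiffened lung retains a small residual compliance.
.W_PEAK_R2 <- 0.81
.W_WIDTH_R2 <- 0.42
.SHELL_WIDTH_R2 <- 0.18
.BASAL_RAMP_MM <- 15
.BASAL_FLOOR <- 0.5
.ATTEN_MAX <- 0.85

#' Construct a DeformationModel
#'
#' Parametric breathing deformation with closed-form displacement (see
#' \linkS4class{DeformationModel}).  Defaults describe a compliant thorax:
#' anisotropic inspiratory expansion (stronger cranio-caudally, mimicking
#' diaphragm excursion) plus a radial contraction concentrated in the
#' peripheral shell of the lung region.
#'
#' @param affineScale per-axis inspiratory scale factors.
#' @param center deformation centre, world mm.
#' @param lungRadii semi-axes (mm) of the deformation (thorax) ellipsoid.
#' @param amplitude peak radial contraction fraction; maps with
#'   amplitude <= 0.3 stay invertible at the default radii.
#' @param peripheralAttenuation severity factor beta in [0, 1]; 1 = healthy,
#'   0 = fully stiffened periphery.
#' @param shellFraction normalised radius beyond which attenuation applies.
#' @param seed integer recorded for provenance.
#' @return A \linkS4class{DeformationModel}.
#' @examples
#' m <- DeformationModel(amplitude = 0.15)
#' trueDisplacement(m, c(20, 0, 0))
#' @export
DeformationModel <- function(affineScale = c(1.10, 1.10, 1.22),
                             center = c(0, 0, 0),
                             lungRadii = c(42, 38, 48),
                             amplitude = 0.15,
                             peripheralAttenuation = 1,
                             shellFraction = 0.7,
                             seed = 1L) {
  if (length(affineScale) == 1L) affineScale <- rep(affineScale, 3L)
  new("DeformationModel", affineScale = as.numeric(affineScale),
      center = as.numeric(center), lungRadii = as.numeric(lungRadii),
      amplitude = as.numeric(amplitude),
      peripheralAttenuation = as.numeric(peripheralAttenuation),
      shellFraction = as.numeric(shellFraction), seed = as.integer(seed))
}

# Squared normalised ellipsoid radius of world points about the model centre.
.normRadius2 <- function(model, points) {
  dx <- sweep(rbind(points), 2, model@center)
  rowSums(sweep(dx, 2, model@lungRadii, `/`)^2)
}

# Smooth peripheral-basal deformation profile w(x) and the severity
# attenuation m(x) (radial shell only, so attenuation scales the deformation
# pattern without reshaping it).
.radialProfile <- function(model, points, r2) {
  z <- rbind(points)[, 3] - model@center[3]
  basal <- .BASAL_FLOOR + (1 - .BASAL_FLOOR) / (1 + exp(z / .BASAL_RAMP_MM))
  exp(-((r2 - .W_PEAK_R2) / .W_WIDTH_R2)^2) * basal
}

.attenuation <- function(model, r2) {
  beta <- model@peripheralAttenuation
  if (beta == 1) return(rep(1, length(r2)))
  shell <- 1 / (1 + exp(-(r2 - model@shellFraction^2) / .SHELL_WIDTH_R2))
  1 - (1 - beta) * .ATTEN_MAX * shell
}

#' Closed-form ground-truth displacement
#'
#' Evaluates \eqn{u(x) = (A - I)(x - c) - \alpha\, m(x)\, w(r^2)\,(x - c)}
#' exactly (machine precision) at arbitrary world points on the expiration
#' grid; \eqn{x + u(x)} is the corresponding inspiration-space point.
#'
#' @param model a \linkS4class{DeformationModel}.
#' @param points n x 3 world mm (a single point may be given as a vector).
#' @return n x 3 matrix of mm displacements.
#' @export
setMethod("trueDisplacement", "DeformationModel", function(model, points) {
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  cc <- model@center; R <- model@lungRadii; s <- model@affineScale
  dx1 <- pts[, 1] - cc[1]; dx2 <- pts[, 2] - cc[2]; dx3 <- pts[, 3] - cc[3]
  r2 <- (dx1 / R[1])^2 + (dx2 / R[2])^2 + (dx3 / R[3])^2
  basal <- .BASAL_FLOOR + (1 - .BASAL_FLOOR) / (1 + exp(dx3 / .BASAL_RAMP_MM))
  w <- exp(-((r2 - .W_PEAK_R2) / .W_WIDTH_R2)^2) * basal
  beta <- model@peripheralAttenuation
  m <- if (beta == 1) 1 else
    1 - (1 - beta) * .ATTEN_MAX /
      (1 + exp(-(r2 - model@shellFraction^2) / .SHELL_WIDTH_R2))
  f <- model@amplitude * m * w
  cbind((s[1] - 1 - f) * dx1, (s[2] - 1 - f) * dx2, (s[3] - 1 - f) * dx3)
})

# Forward map T(x) = x + u(x).
.forwardMap <- function(model, points) {
  rbind(points) + trueDisplacement(model, points)
}

# Numerical inverse of the forward map by fixed-point iteration
# x_{k+1} = y - u(x_k); the displacement is a contraction for admissible
# amplitudes, so convergence is geometric; stop below 1e-4 mm.  The
# contraction factor approaches 1 near the invertibility bound, hence the
# generous iteration cap (the tolerance exit keeps mild models cheap).
.inverseMap <- function(model, points, iters = 200L, tol = 1e-4) {
  y <- rbind(points)
  x <- y
  step <- Inf
  for (i in seq_len(iters)) {
    xn <- y - trueDisplacement(model, x)
    step <- max(abs(xn - x))
    x <- xn
    if (step < tol) break
  }
  if (step >= tol) {
    # plain iteration can cycle where the radial profile is steepest (near
    # the invertibility bound); a damped residual iteration always
    # converges there because the forward Jacobian stays positive
    res <- x + trueDisplacement(model, x) - y
    bad <- which(sqrt(rowSums(res^2)) > tol)
    if (length(bad)) {
      xb <- x[bad, , drop = FALSE]
      yb <- y[bad, , drop = FALSE]
      for (i in seq_len(400L)) {
        r <- xb + trueDisplacement(model, xb) - yb
        if (max(abs(r)) < tol) break
        xb <- xb - 0.5 * r
      }
      x[bad, ] <- xb
    }
  }
  x
}

# Evaluate the model displacement on every voxel of a grid -> DisplacementField.
.modelField <- function(model, geom, roi = NULL) {
  pts <- worldGrid(geom)
  u <- trueDisplacement(model, pts)
  d <- gridDim(geom)
  if (!is.null(roi)) u <- u * as.numeric(roi@data)
  new("DisplacementField",
      vectors = array(u, c(d, 3L)),
      spacing = voxelSpacing(geom), origin = gridOrigin(geom), roi = roi)
}
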