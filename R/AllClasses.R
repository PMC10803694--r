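#' @import methods
NULL

#' ImageVolume: an axis-aligned 3D scalar grid
#'
#' The basic container for a respiratory-phase volume: a 3D array of
#' intensities plus the voxel spacing (mm per axis) and the world origin (mm)
#' of the first voxel.  World coordinates follow
#' \code{world = origin + (index - 1) * spacing} with 1-based voxel indices.
#'
#' @slot data 3D numeric array of voxel values.
#' @slot spacing numeric(3), voxel spacing in mm, all positive.
#' @slot origin numeric(3), world position (mm) of voxel (1,1,1).
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("ImageVolume", function(object) {
  if (length(dim(object@data)) != 3L)
    return("data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values (mm)")
  if (any(!is.finite(object@data)))
    return("voxel values must all be finite")
  TRUE
})

#' BinaryMask: a \{0,1\} volume on an image grid
#'
#' Same geometry as \linkS4class{ImageVolume}; voxel values restricted to 0/1.
#' @export
setClass("BinaryMask", contains = "ImageVolume")

setValidity("BinaryMask", function(object) {
  v <- object@data
  if (!all(v == 0 | v == 1)) return("mask values must be 0 or 1")
  TRUE
})

#' DeformationModel: parametric ground-truth breathing deformation
#'
#' Closed-form displacement on the expiration (fixed) grid mapping each
#' expiration-space point to its inspiration-space correspondent:
#' \deqn{u(x) = (A - I)(x - c) - \alpha\, m(x)\, w(r^2)\, (x - c)}
#' where \eqn{A = diag(affineScale)} is the global inspiratory expansion,
#' \eqn{r} is the normalised ellipsoid radius of \eqn{x} about \code{center}
#' with semi-axes \code{lungRadii}, \eqn{w} a smooth radial profile peaking in
#' the peripheral shell, and \eqn{m(x)} the severity attenuation: 1 inside the
#' core and blending to \code{peripheralAttenuation} (\eqn{\beta}) beyond
#' \code{shellFraction}, more strongly on the inferior (low-z, basal) half.
#' \eqn{\beta = 1} reproduces a compliant (healthy) lung; \eqn{\beta \to 0} a
#' peripherally/basally stiffened, fibrotic-like lung.
#'
#' @slot affineScale numeric(3) per-axis inspiratory scale factors.
#' @slot center numeric(3) deformation centre, world mm.
#' @slot lungRadii numeric(3) semi-axes (mm) of the deformation region.
#' @slot amplitude peak radial contraction fraction in [0, 1); the induced map
#'   is invertible for amplitude <= 0.3 with the default radii.
#' @slot peripheralAttenuation severity factor \eqn{\beta} in [0, 1].
#' @slot shellFraction normalised radius beyond which attenuation applies.
#' @slot seed integer seed recorded for provenance.
#' @export
setClass("DeformationModel",
  representation(affineScale = "numeric", center = "numeric",
                 lungRadii = "numeric", amplitude = "numeric",
                 peripheralAttenuation = "numeric", shellFraction = "numeric",
                 seed = "integer"))

setValidity("DeformationModel", function(object) {
  if (length(object@affineScale) != 3L || any(object@affineScale <= 0))
    return("affineScale must be 3 positive scale factors")
  if (length(object@center) != 3L || any(!is.finite(object@center)))
    return("center must be a finite world point (mm)")
  if (length(object@lungRadii) != 3L || any(object@lungRadii <= 0))
    return("lungRadii must be 3 positive semi-axes (mm)")
  if (object@amplitude < 0 || object@amplitude >= 1)
    return("amplitude must be in [0, 1)")
  if (object@peripheralAttenuation < 0 || object@peripheralAttenuation > 1)
    return("peripheralAttenuation (beta) must be in [0, 1]")
  if (object@shellFraction <= 0 || object@shellFraction >= 1)
    return("shellFraction must be in (0, 1)")
  TRUE
})

#' LandmarkSet: labelled world-coordinate landmarks
#'
#' @slot points n x 3 matrix of world coordinates (mm).
#' @slot category character, "A" or "B" per point.
#' @slot side character, "left"/"right" per point.
#' @slot phase one of "insp", "exp", "registered".
#' @export
setClass("LandmarkSet",
  representation(points = "matrix", category = "character",
                 side = "character", phase = "character"))

setValidity("LandmarkSet", function(object) {
  n <- nrow(object@points)
  if (ncol(object@points) != 3L) return("points must be n x 3 (mm)")
  if (any(!is.finite(object@points))) return("landmark coordinates must be finite")
  if (length(object@category) != n || length(object@side) != n)
    return("category and side must label every point")
  if (!object@phase %in% c("insp", "exp", "registered"))
    return("phase must be insp, exp or registered")
  TRUE
})

#' DisplacementField: dense per-voxel displacement on the fixed grid
#'
#' Vectors are world-mm displacements on the fixed (expiration) grid and point
#' toward moving (inspiration) space: the correspondence of fixed-grid point
#' \eqn{x} is \eqn{x + u(x)} (pull-back warping convention).  The field is
#' zero outside the region of interest.
#'
#' @slot vectors 4D array dim c(nx, ny, nz, 3) of mm displacements.
#' @slot spacing,origin fixed-grid geometry.
#' @slot roi \linkS4class{BinaryMask} of the region where the field is defined,
#'   or NULL for the whole grid.
#' @export
setClass("DisplacementField",
  representation(vectors = "array", spacing = "numeric", origin = "numeric",
                 roi = "ANY"))

setValidity("DisplacementField", function(object) {
  d <- dim(object@vectors)
  if (length(d) != 4L || d[4] != 3L)
    return("vectors must be a 4D array with 3 components")
  if (any(!is.finite(object@vectors))) return("field must be finite everywhere")
  if (!is.null(object@roi)) {
    if (!is(object@roi, "BinaryMask")) return("roi must be a BinaryMask or NULL")
    if (!all(dim(object@roi@data) == d[1:3]))
      return("roi grid must match the field grid")
  }
  TRUE
})

#' AffineTransform: world-to-world affine map
#'
#' Maps fixed-space world points to moving-space world points,
#' \eqn{y = L x + t} (the same pull-back direction as
#' \linkS4class{DisplacementField}).
#'
#' @slot linear 3x3 matrix, invertible.
#' @slot translation numeric(3), mm.
#' @export
setClass("AffineTransform",
  representation(linear = "matrix", translation = "numeric"))

setValidity("AffineTransform", function(object) {
  if (!all(dim(object@linear) == c(3, 3))) return("linear part must be 3x3")
  if (abs(det(object@linear)) <= 1e-8) return("linear part must be invertible")
  if (length(object@translation) != 3L) return("translation must be length 3")
  TRUE
})

#' RegistrationResult: displacement field plus convergence diagnostics
#'
#' @slot displacement \linkS4class{DisplacementField}.
#' @slot backend one of "builtin", "external", "oracle".
#' @slot metrics list with per-level similarity traces and the final local
#'   normalised cross-correlation.
#' @slot converged logical; FALSE flags non-improving similarity (reported,
#'   never silently accepted).
#' @export
setClass("RegistrationResult",
  representation(displacement = "DisplacementField", backend = "character",
                 metrics = "list", converged = "logical"))

#' JacobianMap: scalar deformation map with a processing-stage tag
#'
#' Tracks the staged transformations of the Jacobian determinant:
#' \code{JAC} (raw determinant, > 0), \code{JAC-N} (divided by the
#' inspiratory/expiratory lung-volume ratio), \code{JAC-NL} (natural log;
#' positive = stretch, negative = shrinkage, 0 = no change) and
#' \code{JAC-NLC} (mapped into the common space).  Stage transitions are only
#' permitted in that order.
#'
#' @slot values 3D array of map values.
#' @slot stage one of "JAC", "JAC-N", "JAC-NL", "JAC-NLC".
#' @slot mask \linkS4class{BinaryMask} of valid voxels.
#' @slot spacing,origin grid geometry.
#' @slot provenance list: subject id, normalisation ratio, clipped-voxel
#'   count, common-space info.
#' @export
setClass("JacobianMap",
  representation(values = "array", stage = "character", mask = "BinaryMask",
                 spacing = "numeric", origin = "numeric", provenance = "list"))

setValidity("JacobianMap", function(object) {
  if (!object@stage %in% c("JAC", "JAC-N", "JAC-NL", "JAC-NLC"))
    return("stage must be one of JAC, JAC-N, JAC-NL, JAC-NLC")
  if (!all(dim(object@values) == dim(object@mask@data)))
    return("values and mask grids must agree")
  inmask <- object@values[object@mask@data == 1]
  if (any(!is.finite(inmask))) return("values must be finite inside the mask")
  if (object@stage %in% c("JAC", "JAC-N") && any(inmask <= 0))
    return("JAC / JAC-N values must be positive inside the mask")
  TRUE
})

#' GroupAverageMap: voxelwise group mean of common-space log-Jacobian maps
#'
#' @slot values 3D array, voxelwise mean over contributing subjects.
#' @slot group group label (e.g. "control", "IPF-like").
#' @slot n number of subjects averaged.
#' @slot coverage \linkS4class{BinaryMask}: voxels with at least the required
#'   number of contributing subjects.
#' @slot spacing,origin common-space grid geometry.
#' @export
setClass("GroupAverageMap",
  representation(values = "array", group = "character", n = "integer",
                 coverage = "BinaryMask", spacing = "numeric",
                 origin = "numeric"))

#' SyntheticSubject: one simulated participant
#'
#' Paired-phase phantom volumes, analytic lung masks, true-correspondence
#' landmarks, the generating \linkS4class{DeformationModel} and the clinical
#' record row.
#'
#' @slot subjectId character id.
#' @slot group "control" or "IPF-like".
#' @slot model \linkS4class{DeformationModel}.
#' @slot inspiration,expiration \linkS4class{ImageVolume} or NULL (mask-only
#'   subjects used with the oracle registration backend).
#' @slot lungMaskInsp,lungMaskExp analytic \linkS4class{BinaryMask}s.
#' @slot landmarksInsp,landmarksExp \linkS4class{LandmarkSet}s related exactly
#'   by the model's true displacement.
#' @slot record one-row data.frame of clinical covariates.
#' @export
setClass("SyntheticSubject",
  representation(subjectId = "character", group = "character",
                 model = "DeformationModel",
                 inspiration = "ANY", expiration = "ANY",
                 lungMaskInsp = "BinaryMask", lungMaskExp = "BinaryMask",
                 landmarksInsp = "LandmarkSet", landmarksExp = "LandmarkSet",
                 record = "data.frame"))

#' DiceBreakdown: overlap counts and the Dice coefficient
#'
#' Dice = 2 TP / (2 TP + FN + FP) exactly, where TP/FN/FP are voxel counts of
#' subject-vs-template overlap.  When both masks are empty the coefficient is
#' undefined and reported as NA.
#'
#' @slot tp,fn,fp integer voxel counts.
#' @slot dice numeric in [0, 1], or NA when undefined.
#' @export
setClass("DiceBreakdown",
  representation(tp = "integer", fn = "integer", fp = "integer",
                 dice = "numeric"))

setValidity("DiceBreakdown", function(object) {
  if (object@tp < 0 || object@fn < 0 || object@fp < 0)
    return("counts must be nonnegative")
  tot <- 2 * object@tp + object@fn + object@fp
  if (tot == 0) {
    if (!is.na(object@dice)) return("dice must be NA when both masks are empty")
  } else if (abs(object@dice - 2 * object@tp / tot) > 1e-12)
    return("dice must equal 2*TP/(2*TP+FN+FP)")
  TRUE
})
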