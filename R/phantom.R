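#' @include deformation-model.R
NULL

# Phantom geometry, relative to the model's deformation ellipsoid (semi-axes
# R): a body ellipsoid of semi-axes 1.12 R, and two lung ellipsoids of
# semi-axes (0.45, 0.80, 0.90) R centred at +/- 0.5 Rx laterally.  Intensity
# levels give the bimodal lung/body contrast the segmentation relies on.
.BODY_FACTOR <- 1.12
.LUNG_AXES_FACTOR <- c(0.45, 0.80, 0.90)
.LUNG_OFFSET_X <- 0.5
.I_BODY <- 100
.I_LUNG <- 35
.I_BACKGROUND <- 0
.TEXTURE_AMP <- 0.22
.EDGE_WQ <- 0.018 # logistic width of tissue interfaces, in squared-radius units

# Smooth band-limited multiplicative textures (closed form so the
# inspiration image can be synthesised exactly through the inverse map).
# Wavelengths 17-37 mm resolve comfortably at the default 2 mm spacing; the
# body (soft-tissue) texture is milder and uses its own wavelengths so the
# chest wall carries tangential image structure too.
.texture <- function(pts, phase = 0) {
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  1 + .TEXTURE_AMP * (
    0.45 * sin(2 * pi * x / 23 + 0.7 + phase) +
    0.35 * sin(2 * pi * y / 19 + 1.3 + 0.5 * phase) +
    0.35 * sin(2 * pi * z / 29 + 2.1) +
    0.25 * sin(2 * pi * (x + y) / 17 + 0.3) +
    0.20 * sin(2 * pi * (y - z) / 21 + 1.9 + phase))
}

.textureBody <- function(pts, phase = 0) {
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  1 + 0.10 * (
    0.5 * sin(2 * pi * x / 31 + 1.1 + phase) +
    0.4 * sin(2 * pi * y / 26 + 0.4) +
    0.4 * sin(2 * pi * z / 37 + 2.6 + 0.5 * phase) +
    0.3 * sin(2 * pi * (x - z) / 22 + 1.5))
}

# Squared normalised radius inside each structure.
.lungEq <- function(model, pts) {
  R <- model@lungRadii
  ax <- .LUNG_AXES_FACTOR * R
  cl <- model@center + c(-.LUNG_OFFSET_X * R[1], 0, 0)
  cr <- model@center + c(.LUNG_OFFSET_X * R[1], 0, 0)
  ql <- rowSums(sweep(sweep(rbind(pts), 2, cl), 2, ax, `/`)^2)
  qr <- rowSums(sweep(sweep(rbind(pts), 2, cr), 2, ax, `/`)^2)
  pmin(ql, qr)
}

.bodyEq <- function(model, pts) {
  R <- .BODY_FACTOR * model@lungRadii
  rowSums(sweep(sweep(rbind(pts), 2, model@center), 2, R, `/`)^2)
}

# Analytic expiration-space intensity at arbitrary world points.  Tissue
# interfaces are anti-aliased with a smooth partial-volume ramp so the
# intensity function is differentiable (the binary masks stay sharp).
.expirationIntensity <- function(model, pts, texturePhase = 0) {
  pts <- rbind(pts)
  wBody <- stats::plogis((1 - .bodyEq(model, pts)) / .EDGE_WQ)
  wLung <- stats::plogis((1 - .lungEq(model, pts)) / .EDGE_WQ)
  lungI <- .I_LUNG * .texture(pts, texturePhase)
  bodyI <- .I_BODY * .textureBody(pts, texturePhase)
  wBody * (wLung * lungI + (1 - wLung) * bodyI) +
    (1 - wBody) * .I_BACKGROUND
}

#' Generate a paired inspiration/expiration phantom subject
#'
#' Builds a two-lung thorax phantom in expiration space and synthesises the
#' inspiration volume by pulling the analytic expiration intensity back
#' through the numerically inverted forward map, so the model's closed-form
#' displacement is the exact ground truth of the inspiration(moving) to
#' expiration(fixed) registration.  Lung masks are generated analytically from
#' the ellipsoid equations in each phase; landmarks are placed on the chest
#' wall with exact phase correspondence.
#'
#' @param model a \linkS4class{DeformationModel}.
#' @param gridShape grid dimensions (default 64^3).
#' @param spacing voxel spacing mm (scalar or length 3, default 2 mm).
#' @param withImages if FALSE, only masks/landmarks are generated (fast path
#'   for oracle-registration studies).
#' @param imageNoiseSd additive Gaussian intensity noise (acquisition noise),
#'   seeded from the model seed.
#' @param texturePhase phase offset of the parenchymal texture (a second
#'   acquisition of the same subject uses a different offset).
#' @param noiseSeed seed for the acquisition noise (defaults to the model
#'   seed; a repeat acquisition passes a different one).
#' @param subjectId,group labels stored on the subject.
#' @return A \linkS4class{SyntheticSubject}.
#' @examples
#' sub <- makePhantom(DeformationModel(amplitude = 0), gridShape = c(24, 24, 24),
#'                    spacing = 4)
#' all.equal(imageData(sub@inspiration), imageData(sub@expiration))
#' @export
makePhantom <- function(model, gridShape = c(64, 64, 64), spacing = 2,
                        withImages = TRUE, imageNoiseSd = 0,
                        texturePhase = 0, noiseSeed = NULL,
                        subjectId = "sub-001", group = "control") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  gridShape <- as.integer(gridShape)
  origin <- model@center - (gridShape - 1) / 2 * spacing
  geom <- ImageVolume(array(0, gridShape), spacing, origin)

  # reject non-invertible parameter combinations by evaluating the forward
  # Jacobian sign on the grid (cheap finite-difference probe)
  probe <- worldGrid(geom)[seq(1, prod(gridShape), length.out = 2048), , drop = FALSE]
  if (min(.numericJacobian(model, probe)) <= 0)
    stop("deformation model is not invertible on this grid ",
         "(amplitude/attenuation out of bounds)")

  pts <- worldGrid(geom)
  maskExp <- .lungEq(model, pts) <= 1
  if (!any(maskExp)) stop("grid too small: lung ellipsoids fall outside")
  if (withImages) {
    xinv <- .inverseMap(model, pts)
    maskInsp <- .lungEq(model, xinv) <= 1
  } else {
    # masks only: invert just inside a conservative bound on the
    # inspiratory lung (the forward map scales radii by < 1.25, so points
    # beyond normalised radius 1.26 cannot map back into the lung)
    cand <- .normRadius2(model, pts) <= 1.6
    maskInsp <- logical(nrow(pts))
    maskInsp[cand] <- .lungEq(model,
      .inverseMap(model, pts[cand, , drop = FALSE])) <= 1
  }

  lmExp <- .chestWallLandmarks(model)
  lmInsp <- LandmarkSet(.forwardMap(model, lmExp@points),
                        lmExp@category, lmExp@side, "insp")

  insp <- expi <- NULL
  if (withImages) {
    vExp <- .expirationIntensity(model, pts, texturePhase)
    vInsp <- .expirationIntensity(model, xinv, texturePhase)
    if (imageNoiseSd > 0) {
      rs <- .Random.seed_save()
      set.seed(if (is.null(noiseSeed)) model@seed else as.integer(noiseSeed))
      vExp <- vExp + stats::rnorm(length(vExp), sd = imageNoiseSd)
      vInsp <- vInsp + stats::rnorm(length(vInsp), sd = imageNoiseSd)
      .Random.seed_restore(rs)
    }
    expi <- ImageVolume(array(vExp, gridShape), spacing, origin)
    insp <- ImageVolume(array(vInsp, gridShape), spacing, origin)
  }

  new("SyntheticSubject", subjectId = subjectId, group = group, model = model,
      inspiration = insp, expiration = expi,
      lungMaskInsp = BinaryMask(array(as.numeric(maskInsp), gridShape),
                                spacing, origin),
      lungMaskExp = BinaryMask(array(as.numeric(maskExp), gridShape),
                               spacing, origin),
      landmarksInsp = lmInsp, landmarksExp = lmExp,
      record = data.frame(subject_id = subjectId, group = group,
                          stringsAsFactors = FALSE))
}

# Finite-difference Jacobian determinant of the forward map at points
# (invertibility probe; step in mm).
.numericJacobian <- function(model, points, step = 1e-3) {
  pts <- rbind(points)
  n <- nrow(pts)
  J <- vector("list", 3)
  for (a in 1:3) {
    e <- matrix(0, n, 3); e[, a] <- step
    J[[a]] <- (.forwardMap(model, pts + e) - .forwardMap(model, pts - e)) /
      (2 * step)
  }
  J[[1]][, 1] * (J[[2]][, 2] * J[[3]][, 3] - J[[2]][, 3] * J[[3]][, 2]) -
  J[[2]][, 1] * (J[[1]][, 2] * J[[3]][, 3] - J[[1]][, 3] * J[[3]][, 2]) +
  J[[3]][, 1] * (J[[1]][, 2] * J[[2]][, 3] - J[[1]][, 3] * J[[2]][, 2])
}

# RNG bookkeeping: phantom noise is seeded locally without disturbing the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
    envir = globalenv()) else NULL
}
.Random.seed_restore <- function(rs) {
  if (is.null(rs)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", rs, envir = globalenv())
}

# Bilateral chest-wall landmarks at an axial level on the superior chest
# (the convention emulates paired bony/chest-wall reference points): two
# categories A (antero-lateral) and B (lateral), left and right.
.chestWallLandmarks <- function(model, levelFraction = 0.45) {
  R <- .BODY_FACTOR * model@lungRadii
  z0 <- model@center[3] + levelFraction * model@lungRadii[3]
  srel <- (z0 - model@center[3]) / R[3]
  if (abs(srel) >= 1)
    stop("landmark level lies outside the body mask extent")
  f <- sqrt(1 - srel^2)
  fx <- R[1] * f; fy <- R[2] * f
  angA <- 40 * pi / 180   # antero-lateral
  angB <- 80 * pi / 180   # lateral
  pts <- rbind(
    model@center + c(-fx * sin(angA), fy * cos(angA), z0 - model@center[3]),
    model@center + c(fx * sin(angA), fy * cos(angA), z0 - model@center[3]),
    model@center + c(-fx * sin(angB), fy * cos(angB), z0 - model@center[3]),
    model@center + c(fx * sin(angB), fy * cos(angB), z0 - model@center[3]))
  LandmarkSet(pts, category = c("A", "A", "B", "B"),
              side = c("left", "right", "left", "right"), phase = "exp")
}

#' Place chest-wall landmarks on a phantom subject
#'
#' Two bilateral categories (A antero-lateral, B lateral) at a fixed axial
#' level in expiration space; inspiration-space positions follow exactly from
#' the model's true displacement.
#'
#' @param subject a \linkS4class{SyntheticSubject}.
#' @param levelFraction axial level as a fraction of the superior lung radius.
#' @return list with elements \code{exp} and \code{insp}
#'   (\linkS4class{LandmarkSet}s).
#' @export
placeLandmarks <- function(subject, levelFraction = 0.45) {
  lmExp <- .chestWallLandmarks(subject@model, levelFraction)
  zIdx <- worldToIndex(subject@lungMaskExp, lmExp@points)[, 3]
  if (any(zIdx < 1 | zIdx > gridDim(subject@lungMaskExp)[3]))
    stop("landmark level lies outside the mask extent")
  list(exp = lmExp,
       insp = LandmarkSet(.forwardMap(subject@model, lmExp@points),
                          lmExp@category, lmExp@side, "insp"))
}
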