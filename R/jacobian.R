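#' @include registration.R
NULL

#' Jacobian determinant map of a displacement field (stage JAC)
#'
#' Per voxel, \eqn{\det(I + \nabla u)} with spacing-scaled central
#' differences (one-sided at the grid border).  Values greater than 1 mark
#' local stretch from expiration to inspiration, values below 1 local
#' shrinkage.  Values are clipped below at \code{epsilon} and the number of
#' clipped voxels is recorded in the provenance (reported, never fatal).
#'
#' @param displacement a \linkS4class{DisplacementField}.
#' @param mask optional \linkS4class{BinaryMask} of valid voxels; defaults to
#'   the field's ROI, else the full grid.
#' @param epsilon positive lower clip before the later log transform.
#' @param subjectId recorded in provenance.
#' @return A \linkS4class{JacobianMap} at stage "JAC".
#' @export
jacobianMap <- function(displacement, mask = NULL, epsilon = 1e-6,
                        subjectId = NA_character_) {
  sp <- voxelSpacing(displacement)
  d <- gridDim(displacement)
  J11 <- .gradientAxis(displacement@vectors[, , , 1], 1, sp[1]) + 1
  J12 <- .gradientAxis(displacement@vectors[, , , 1], 2, sp[2])
  J13 <- .gradientAxis(displacement@vectors[, , , 1], 3, sp[3])
  J21 <- .gradientAxis(displacement@vectors[, , , 2], 1, sp[1])
  J22 <- .gradientAxis(displacement@vectors[, , , 2], 2, sp[2]) + 1
  J23 <- .gradientAxis(displacement@vectors[, , , 2], 3, sp[3])
  J31 <- .gradientAxis(displacement@vectors[, , , 3], 1, sp[1])
  J32 <- .gradientAxis(displacement@vectors[, , , 3], 2, sp[2])
  J33 <- .gradientAxis(displacement@vectors[, , , 3], 3, sp[3]) + 1
  det <- J11 * (J22 * J33 - J23 * J32) -
         J12 * (J21 * J33 - J23 * J31) +
         J13 * (J21 * J32 - J22 * J31)
  nclip <- sum(det < epsilon)
  det[det < epsilon] <- epsilon
  if (is.null(mask)) {
    mask <- if (!is.null(displacement@roi)) displacement@roi
            else BinaryMask(array(1, d), sp, gridOrigin(displacement))
  }
  new("JacobianMap", values = det, stage = "JAC", mask = mask,
      spacing = sp, origin = gridOrigin(displacement),
      provenance = list(subject = subjectId, clippedVoxels = nclip,
                        epsilon = epsilon))
}

#' Normalise a Jacobian map by the lung-volume ratio (stage JAC-N)
#'
#' Divides by \eqn{V_{insp} / V_{exp}} so the lung mean becomes ~1 and the
#' later log transform is centred at "no change".
#'
#' @param jac a stage-"JAC" \linkS4class{JacobianMap}.
#' @param vInsp,vExp positive lung volumes (any common unit).
#' @return A stage "JAC-N" \linkS4class{JacobianMap}; the ratio is recorded
#'   in provenance.
#' @export
normalizeJac <- function(jac, vInsp, vExp) {
  if (mapStage(jac) != "JAC") stop("normalizeJac needs a stage-JAC map")
  if (vInsp <= 0 || vExp <= 0) stop("lung volumes must be positive")
  ratio <- vInsp / vExp
  prov <- jac@provenance
  prov$volumeRatio <- ratio
  new("JacobianMap", values = jac@values / ratio, stage = "JAC-N",
      mask = jac@mask, spacing = jac@spacing, origin = jac@origin,
      provenance = prov)
}

#' Natural log of a normalised Jacobian map (stage JAC-NL)
#'
#' Positive values imply voxel stretch, negative shrinkage, 0 no change.
#'
#' @param jacn a stage-"JAC-N" \linkS4class{JacobianMap}.
#' @return A stage "JAC-NL" \linkS4class{JacobianMap}.
#' @export
logJac <- function(jacn) {
  if (mapStage(jacn) != "JAC-N") stop("logJac needs a stage-JAC-N map")
  new("JacobianMap", values = log(jacn@values), stage = "JAC-NL",
      mask = jacn@mask, spacing = jacn@spacing, origin = jacn@origin,
      provenance = jacn@provenance)
}

#' Resample a log-Jacobian map into the common space (stage JAC-NLC)
#'
#' Values are transported by pull-back through the subject's affine (common
#' space to subject space) with trilinear interpolation.  Values are not
#' rescaled by the affine determinant by default (the affine only transports
#' the map between anatomies); set \code{rescaleByDet = TRUE} for the
#' sensitivity variant.  The valid mask is the resampled subject mask
#' intersected with the common-space lung mask.
#'
#' @param jacnl a stage-"JAC-NL" \linkS4class{JacobianMap}.
#' @param affine \linkS4class{AffineTransform} from
#'   \code{registerAffine(commonMask, subjectMask)} (common to subject).
#' @param commonMask \linkS4class{BinaryMask} defining the common grid and
#'   lung region.
#' @param rescaleByDet divide values by log det? (off by default; the flag is
#'   recorded in provenance).
#' @return A stage "JAC-NLC" \linkS4class{JacobianMap} on the common grid.
#' @export
toCommonSpace <- function(jacnl, affine, commonMask, rescaleByDet = FALSE) {
  if (mapStage(jacnl) != "JAC-NL") stop("toCommonSpace needs a stage-JAC-NL map")
  d <- gridDim(commonMask)
  pts <- applyAffine(affine, worldGrid(commonMask))
  idx <- worldToIndex(jacnl@mask, pts)
  vals <- .interpTrilinear(jacnl@values, idx, background = 0)
  inSubj <- .interpTrilinear(jacnl@mask@data, idx, background = 0) >= 0.5
  valid <- inSubj & (imageData(commonMask) == 1)
  if (rescaleByDet) vals <- vals - log(abs(det(affine@linear)))
  vals[!valid] <- 0
  prov <- jacnl@provenance
  prov$commonSpace <- list(rescaleByDet = rescaleByDet,
                           affineDet = det(affine@linear))
  new("JacobianMap", values = array(vals, d), stage = "JAC-NLC",
      mask = BinaryMask(array(as.numeric(valid), d),
                        voxelSpacing(commonMask), gridOrigin(commonMask)),
      spacing = voxelSpacing(commonMask), origin = gridOrigin(commonMask),
      provenance = prov)
}

#' Voxelwise group average of common-space maps
#'
#' Mean over the subjects contributing at each voxel; the coverage mask keeps
#' voxels with at least \code{minCoverage} contributors.
#'
#' @param maps nonempty list of stage-"JAC-NLC" \linkS4class{JacobianMap}s on
#'   a shared common grid.
#' @param group group label (e.g. "control").
#' @param minCoverage minimum number of contributing subjects per voxel.
#' @return A \linkS4class{GroupAverageMap}.
#' @export
groupAverage <- function(maps, group = "group", minCoverage = 1L) {
  if (!length(maps)) stop("empty list of maps")
  d <- gridDim(maps[[1]]@mask)
  sumv <- array(0, d); cnt <- array(0, d)
  for (m in maps) {
    if (mapStage(m) != "JAC-NLC") stop("groupAverage needs stage-JAC-NLC maps")
    if (!all(gridDim(m@mask) == d)) stop("maps must share the common grid")
    w <- m@mask@data
    sumv <- sumv + m@values * w
    cnt <- cnt + w
  }
  avg <- ifelse(cnt > 0, sumv / pmax(cnt, 1), 0)
  cov <- (cnt >= minCoverage) * 1
  new("GroupAverageMap", values = avg, group = group, n = length(maps),
      coverage = BinaryMask(array(cov, d), voxelSpacing(maps[[1]]@mask),
                            gridOrigin(maps[[1]]@mask)),
      spacing = voxelSpacing(maps[[1]]@mask),
      origin = gridOrigin(maps[[1]]@mask))
}

#' Project a group-average map along an axis
#'
#' Mean along the chosen axis over covered voxels, yielding the coronal,
#' sagittal or axial view; lines with no coverage are NA (missing, not zero).
#'
#' @param avg a \linkS4class{GroupAverageMap}.
#' @param axis "x", "y" or "z".
#' @return 2D matrix of means (NA where uncovered).
#' @export
axisProjection <- function(avg, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  a <- match(axis, c("x", "y", "z"))
  w <- avg@coverage@data
  v <- avg@values * w
  sums <- apply(v, setdiff(1:3, a), sum)
  cnts <- apply(w, setdiff(1:3, a), sum)
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  out
}

#' Plot an axis projection as a diverging colour map
#'
#' @param proj matrix from \code{\link{axisProjection}}.
#' @param main plot title.
#' @export
plotProjection <- function(proj, main = "log-Jacobian projection") {
  lim <- max(abs(proj), na.rm = TRUE)
  pal <- grDevices::colorRampPalette(c("#b2182b", "#f7f7f7", "#2166ac"))(64)
  graphics::image(proj, zlim = c(-lim, lim), col = pal, main = main,
                  useRaster = TRUE, axes = FALSE)
}

#' Jac-mean: the per-subject scalar deformation endpoint
#'
#' Absolute value of the mean JAC-NLC over the analysis mask (the
#' common-space lung mask intersected with the map's valid mask).  The
#' signed-mean-then-absolute-value form is the default; \code{meanOfAbs}
#' computes the mean of absolute values instead (sensitivity variant).
#'
#' @param jacnlc a stage-"JAC-NLC" \linkS4class{JacobianMap}.
#' @param mask optional \linkS4class{BinaryMask} restricting the average.
#' @param meanOfAbs use mean(|values|) instead of |mean(values)|.
#' @return nonnegative scalar.
#' @export
jacMean <- function(jacnlc, mask = NULL, meanOfAbs = FALSE) {
  if (mapStage(jacnlc) != "JAC-NLC") stop("jacMean needs a stage-JAC-NLC map")
  w <- jacnlc@mask@data == 1
  if (!is.null(mask)) w <- w & (imageData(mask) == 1)
  if (!any(w)) stop("empty averaging mask")
  v <- jacnlc@values[w]
  if (meanOfAbs) mean(abs(v)) else abs(mean(v))
}

#' Marked-deformation segmentation of a log-Jacobian map
#'
#' Default interpretation: voxels with JAC-NLC \eqn{\le -cutoff} (marked
#' shrinkage, which is negative on the log scale).  The literal
#' "below +cutoff" reading is selectable via \code{rule = "literal"} for
#' sensitivity analysis; the cutoff and rule are recorded as attributes.
#'
#' @param jacnlc a stage-"JAC-NLC" \linkS4class{JacobianMap} (or a
#'   \linkS4class{GroupAverageMap}).
#' @param cutoff positive cutoff on the log scale (default 0.15).
#' @param rule "shrinkage" (<= -cutoff) or "literal" (< +cutoff).
#' @return A \linkS4class{BinaryMask} restricted to the valid/coverage mask.
#' @export
markedDeformationMask <- function(jacnlc, cutoff = 0.15,
                                  rule = c("shrinkage", "literal")) {
  rule <- match.arg(rule)
  if (is(jacnlc, "GroupAverageMap")) {
    vals <- jacnlc@values; valid <- jacnlc@coverage@data == 1
    sp <- jacnlc@spacing; o <- jacnlc@origin
  } else {
    if (mapStage(jacnlc) != "JAC-NLC")
      stop("markedDeformationMask needs a stage-JAC-NLC map")
    vals <- jacnlc@values; valid <- jacnlc@mask@data == 1
    sp <- jacnlc@spacing; o <- jacnlc@origin
  }
  sel <- if (rule == "shrinkage") vals <= -cutoff else vals < cutoff
  m <- BinaryMask(array(as.numeric(sel & valid), dim(vals)), sp, o)
  attr(m, "cutoff") <- cutoff
  attr(m, "rule") <- rule
  m
}

#' Healthy deformation template
#'
#' The marked-deformation segmentation of the control-group average map
#' (HAJ); represents the healthy breathing pattern the per-subject masks are
#' compared against.
#'
#' @param haj \linkS4class{GroupAverageMap} of the control group.
#' @param cutoff,rule passed to \code{\link{markedDeformationMask}}.
#' @return A \linkS4class{BinaryMask} with provenance attributes (cutoff,
#'   rule, group size).
#' @export
healthyTemplate <- function(haj, cutoff = 0.15,
                            rule = c("shrinkage", "literal")) {
  rule <- match.arg(rule)
  tpl <- markedDeformationMask(haj, cutoff = cutoff, rule = rule)
  if (sum(imageData(tpl)) == 0)
    stop("healthy deformation template is empty: cutoff ", cutoff,
         " too strict for this group average")
  attr(tpl, "n") <- haj@n
  tpl
}

#' Dice similarity of a subject's marked-deformation mask to the template
#'
#' TP = subject AND template, FN = template not subject, FP = subject not
#' template; Dice = 2 TP / (2 TP + FN + FP).  Both-empty input is undefined
#' and returned with \code{dice = NA}.
#'
#' @param subjectMask,template \linkS4class{BinaryMask}s on the common grid.
#' @return A \linkS4class{DiceBreakdown}.
#' @export
diceToTemplate <- function(subjectMask, template) {
  if (!all(gridDim(subjectMask) == gridDim(template)))
    stop("masks must share the common grid")
  s <- imageData(subjectMask) == 1
  t <- imageData(template) == 1
  tp <- sum(s & t); fn <- sum(t & !s); fp <- sum(s & !t)
  dice <- if (2 * tp + fn + fp == 0) NA_real_ else 2 * tp / (2 * tp + fn + fp)
  new("DiceBreakdown", tp = as.integer(tp), fn = as.integer(fn),
      fp = as.integer(fp), dice = dice)
}
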