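#' @include volumes.R utils-grid.R
NULL

#' Resample a volume to isotropic spacing
#'
#' The output grid covers the same physical extent; the new shape along each
#' axis is \code{ceiling(extent / target) + 1} voxel centres (documented
#' rounding rule), where extent is the distance spanned by the voxel centres,
#' so a 64^3 grid at 2 mm resamples to 127^3 at 1 mm.  Images are
#' interpolated trilinearly; masks use nearest-neighbour and stay binary.
#'
#' @param image an \linkS4class{ImageVolume} or \linkS4class{BinaryMask}.
#' @param targetSpacing target isotropic spacing in mm.
#' @return resampled object of the same class.
#' @export
resampleIsotropic <- function(image, targetSpacing = 1) {
  stopifnot(targetSpacing > 0)
  d <- gridDim(image)
  if (any(d < 2)) stop("degenerate (single-slice) input cannot be resampled")
  sp <- voxelSpacing(image)
  if (all(abs(sp - targetSpacing) < 1e-12)) return(image)
  extent <- (d - 1) * sp
  nd <- pmax(2L, as.integer(ceiling(extent / targetSpacing)) + 1L)
  # centre the new grid on the old physical extent
  newExtent <- (nd - 1) * targetSpacing
  newOrigin <- gridOrigin(image) + (extent - newExtent) / 2
  idx <- arrayInd(seq_len(prod(nd)), nd)
  world <- sweep((idx - 1) * targetSpacing, 2, newOrigin, `+`)
  srcIdx <- worldToIndex(image, world)
  isMask <- is(image, "BinaryMask")
  if (isMask) {
    si <- pmin(pmax(round(srcIdx), 1), matrix(d, nrow(srcIdx), 3, byrow = TRUE))
    vals <- imageData(image)[si]
    BinaryMask(array(vals, nd), rep(targetSpacing, 3), newOrigin)
  } else {
    vals <- .interpTrilinear(imageData(image), srcIdx,
                             background = min(imageData(image)))
    ImageVolume(array(vals, nd), rep(targetSpacing, 3), newOrigin)
  }
}

#' Threshold-based lung segmentation
#'
#' Global Otsu threshold, then 6-connected components of the candidate class.
#' The darker class is examined first (lungs are hypointense relative to the
#' body); its components touching the grid border (air background) are
#' discarded and the two largest interior components are kept.  If the dark
#' class has no interior component (e.g. an image already masked to the
#' lungs), the bright class is used instead, which makes the operation
#' idempotent under masking.  Interior holes are filled.
#'
#' @param image an \linkS4class{ImageVolume} with bimodal lung/body contrast.
#' @return A \linkS4class{BinaryMask} on the image grid.
#' @export
segmentLungs <- function(image) {
  v <- imageData(image)
  t <- .otsuThreshold(v)
  pick <- function(cand) {
    comp <- .interiorComponents(cand)
    if (!length(comp$interior)) return(NULL)
    keep <- comp$interior[order(comp$sizes[comp$interior],
                                decreasing = TRUE)][seq_len(min(2L,
                                length(comp$interior)))]
    array(comp$label %in% keep, dim(cand))
  }
  m <- pick(v < t)
  if (is.null(m)) m <- pick(v >= t)
  if (is.null(m))
    stop("lung segmentation failed: no interior connected component found")
  m <- .fillHoles(m)
  BinaryMask(array(as.numeric(m), dim(v)), voxelSpacing(image),
             gridOrigin(image))
}

#' Morphological dilation by a Euclidean ball
#'
#' Dilates the mask with a digital Euclidean ball of the given voxel radius
#' (radius 0 is the identity).  On a 1 mm isotropic grid a radius of 10
#' voxels extends the lung mask by 10 mm to include the peri-lung region.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param radiusVoxels nonnegative integer radius in voxels.
#' @return the dilated \linkS4class{BinaryMask}.
#' @export
dilateMask <- function(mask, radiusVoxels) {
  stopifnot(radiusVoxels >= 0, radiusVoxels == round(radiusVoxels))
  if (radiusVoxels == 0) return(mask)
  m <- .dilateBall(imageData(mask) == 1, radiusVoxels)
  BinaryMask(array(as.numeric(m), gridDim(mask)), voxelSpacing(mask),
             gridOrigin(mask))
}

#' Lung volume of a mask in millilitres
#'
#' Voxel count times voxel volume; 1000 mm^3 = 1 ml.
#'
#' @param mask a nonempty \linkS4class{BinaryMask}.
#' @return volume in ml.
#' @export
lungVolume <- function(mask) {
  n <- sum(imageData(mask) == 1)
  if (n == 0) stop("empty mask has no volume")
  n * prod(voxelSpacing(mask)) / 1000
}
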