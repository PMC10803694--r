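#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an ImageVolume
#'
#' @param data 3D numeric array.
#' @param spacing voxel spacing in mm (scalar or length 3).
#' @param origin world coordinates (mm) of voxel (1,1,1).
#' @return An \linkS4class{ImageVolume}.
#' @examples
#' img <- ImageVolume(array(0, c(8, 8, 8)), spacing = 2)
#' gridDim(img)
#' @export
ImageVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a BinaryMask
#'
#' @param data 3D array coercible to 0/1 (logical allowed).
#' @inheritParams ImageVolume
#' @return A \linkS4class{BinaryMask}.
#' @export
BinaryMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(data) <- "double"
  new("BinaryMask", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' @describeIn ImageVolume voxel array
#' @param x an object
#' @export
setMethod("imageData", "ImageVolume", function(x) x@data)
#' @describeIn ImageVolume voxel spacing (mm)
#' @export
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)
#' @describeIn ImageVolume world origin (mm)
#' @export
setMethod("gridOrigin", "ImageVolume", function(x) x@origin)
#' @describeIn ImageVolume grid dimensions
#' @export
setMethod("gridDim", "ImageVolume", function(x) dim(x@data))

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(class(object), sprintf("%d x %d x %d", d[1], d[2], d[3]),
      sprintf("| spacing %s mm", paste(signif(object@spacing, 4), collapse = " x ")),
      sprintf("| origin (%s) mm\n", paste(signif(object@origin, 4), collapse = ", ")))
  v <- object@data
  cat(sprintf("  values in [%g, %g]\n", min(v), max(v)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@data)
  cat("BinaryMask", sprintf("%d x %d x %d", d[1], d[2], d[3]),
      sprintf("| spacing %s mm", paste(signif(object@spacing, 4), collapse = " x ")),
      sprintf("| %d foreground voxels\n", sum(object@data == 1)))
})

setMethod("show", "DisplacementField", function(object) {
  d <- dim(object@vectors)
  mag <- sqrt(rowSums(matrix(object@vectors, ncol = 3)^2))
  cat("DisplacementField", sprintf("%d x %d x %d", d[1], d[2], d[3]),
      sprintf("| spacing %s mm", paste(signif(object@spacing, 4), collapse = " x ")),
      sprintf("| max |u| %.2f mm\n", max(mag)))
})

setMethod("show", "JacobianMap", function(object) {
  v <- object@values[object@mask@data == 1]
  cat("JacobianMap stage", object@stage,
      sprintf("| %d valid voxels | mean %.4f [%.3f, %.3f]\n",
              length(v), mean(v), min(v), max(v)))
})

setMethod("show", "DeformationModel", function(object) {
  cat("DeformationModel: scale (",
      paste(signif(object@affineScale, 4), collapse = ", "),
      "), amplitude ", object@amplitude,
      ", beta ", object@peripheralAttenuation,
      ", shell > ", object@shellFraction, "\n", sep = "")
})

setMethod("show", "SyntheticSubject", function(object) {
  cat("SyntheticSubject", object@subjectId, sprintf("(%s)", object@group),
      if (is.null(object@expiration)) "[masks only]" else "[with images]", "\n")
})

setMethod("show", "DiceBreakdown", function(object) {
  cat(sprintf("Dice %.4f (TP %d, FN %d, FP %d)\n",
              object@dice, object@tp, object@fn, object@fp))
})

#' @describeIn JacobianMap processing stage tag
#' @param x an object
#' @export
setMethod("mapStage", "JacobianMap", function(x) x@stage)
#' @describeIn JacobianMap value array
#' @export
setMethod("mapValues", "JacobianMap", function(x) x@values)
#' @describeIn JacobianMap mask of valid voxels
#' @export
setMethod("validMask", "JacobianMap", function(x) x@mask)
#' @describeIn JacobianMap provenance list
#' @export
setMethod("provenance", "JacobianMap", function(x) x@provenance)

#' @describeIn DisplacementField 4D vector array (mm)
#' @param x an object
#' @export
setMethod("fieldVectors", "DisplacementField", function(x) x@vectors)
#' @export
setMethod("voxelSpacing", "DisplacementField", function(x) x@spacing)
#' @export
setMethod("gridOrigin", "DisplacementField", function(x) x@origin)
#' @export
setMethod("gridDim", "DisplacementField", function(x) dim(x@vectors)[1:3])

#' @describeIn LandmarkSet n x 3 world coordinates (mm)
#' @param x an object
#' @export
setMethod("landmarkPoints", "LandmarkSet", function(x) x@points)

setMethod("show", "LandmarkSet", function(object) {
  cat("LandmarkSet:", nrow(object@points), "points, phase", object@phase,
      "| categories", paste(sort(unique(object@category)), collapse = "/"), "\n")
})

#' World coordinates of every voxel centre
#'
#' @param x an \linkS4class{ImageVolume}, \linkS4class{BinaryMask} or
#'   \linkS4class{DisplacementField}.
#' @return n x 3 matrix of world mm, voxel order = array order.
#' @export
worldGrid <- function(x) {
  d <- gridDim(x)
  sp <- voxelSpacing(x)
  o <- gridOrigin(x)
  idx <- arrayInd(seq_len(prod(d)), d)
  sweep(sweep(idx - 1, 2, sp, `*`), 2, o, `+`)
}

#' Convert world coordinates to continuous 1-based voxel indices
#' @param x a gridded object.
#' @param points n x 3 world mm.
#' @return n x 3 continuous voxel coordinates.
#' @export
worldToIndex <- function(x, points) {
  points <- rbind(points)
  sweep(sweep(points, 2, gridOrigin(x)), 2, voxelSpacing(x), `/`) + 1
}

#' Convert continuous voxel indices to world coordinates
#' @inheritParams worldToIndex
#' @param index n x 3 continuous 1-based voxel coordinates.
#' @export
indexToWorld <- function(x, index) {
  index <- rbind(index)
  sweep(sweep(index - 1, 2, voxelSpacing(x), `*`), 2, gridOrigin(x), `+`)
}

#' Construct a LandmarkSet
#' @param points n x 3 world mm.
#' @param category character vector ("A"/"B") per point.
#' @param side character vector ("left"/"right") per point.
#' @param phase "insp", "exp" or "registered".
#' @export
LandmarkSet <- function(points, category, side, phase) {
  points <- rbind(points)
  dimnames(points) <- NULL
  new("LandmarkSet", points = points, category = as.character(category),
      side = as.character(side), phase = phase)
}

#' Construct an AffineTransform
#' @param linear 3x3 matrix.
#' @param translation numeric(3) mm.
#' @export
AffineTransform <- function(linear = diag(3), translation = c(0, 0, 0)) {
  new("AffineTransform", linear = linear, translation = as.numeric(translation))
}

#' Apply an AffineTransform to points
#' @param affine an \linkS4class{AffineTransform}.
#' @param points n x 3 world mm.
#' @return n x 3 transformed points.
#' @export
applyAffine <- function(affine, points) {
  points <- rbind(points)
  sweep(points %*% t(affine@linear), 2, affine@translation, `+`)
}

setMethod("show", "AffineTransform", function(object) {
  cat("AffineTransform | det", signif(det(object@linear), 5),
      "| t (", paste(signif(object@translation, 4), collapse = ", "), ") mm\n")
})
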