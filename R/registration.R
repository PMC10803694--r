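#' @include volumes.R utils-grid.R preprocess.R
NULL

#' Registration configuration for the builtin backend
#'
#' Multiresolution demons-style deformable registration with Gaussian field
#' regularisation.  All parameters are deterministic; there is no hidden
#' randomness.
#'
#' @param levels number of resolution levels (coarsest is
#'   \code{2^(levels-1)}-fold downsampled).
#' @param iterations iterations per level, coarse to fine.
#' @param sigmaUpdate Gaussian sigma (voxels) smoothing each update field
#'   (fluid-like regularisation).
#' @param sigmaTotal Gaussian sigma (voxels) smoothing the accumulated field
#'   (elastic-like regularisation).
#' @param maxStepVoxels cap on a single update step, in voxels.
#' @return list of class \code{regConfig}.
#' @export
registrationConfig <- function(levels = 3L, iterations = c(100L, 60L, 30L),
                               sigmaUpdate = 1.0, sigmaTotal = 1.25,
                               maxStepVoxels = 1.25) {
  stopifnot(length(iterations) == levels)
  structure(list(levels = as.integer(levels),
                 iterations = as.integer(iterations),
                 sigmaUpdate = sigmaUpdate, sigmaTotal = sigmaTotal,
                 maxStepVoxels = maxStepVoxels), class = "regConfig")
}

# Local normalised cross-correlation inside a mask (reported similarity).
.lncc <- function(a, b, mask, transfer) {
  w <- as.numeric(mask)
  mu_a <- .smoothFFT(a * w, transfer); n <- .smoothFFT(w, transfer)
  mu_b <- .smoothFFT(b * w, transfer)
  n[n < 1e-8] <- 1e-8
  mu_a <- mu_a / n; mu_b <- mu_b / n
  va <- .smoothFFT(a * a * w, transfer) / n - mu_a^2
  vb <- .smoothFFT(b * b * w, transfer) / n - mu_b^2
  cab <- .smoothFFT(a * b * w, transfer) / n - mu_a * mu_b
  den <- sqrt(pmax(va, 0) * pmax(vb, 0))
  ok <- w > 0 & den > 1e-6
  if (!any(ok)) return(NA_real_)
  mean(cab[ok] / den[ok])
}

# One resolution level of demons iterations.  Images are range-normalised to
# [0,1] upstream; force = diff * grad / (|grad|^2 + diff^2 / K) with
# K = mean squared spacing (the classical normalised demons step).
.demonsLevel <- function(fixed, moving, roi, u, spacing, iters, cfg) {
  d <- dim(fixed)
  K <- mean(spacing^2)
  tfU <- .gaussianTransfer(d, rep(cfg$sigmaUpdate, 3))
  tfT <- .gaussianTransfer(d, rep(cfg$sigmaTotal, 3))
  gx <- .gradientAxis(fixed, 1, spacing[1])
  gy <- .gradientAxis(fixed, 2, spacing[2])
  gz <- .gradientAxis(fixed, 3, spacing[3])
  g2 <- gx^2 + gy^2 + gz^2
  idx0 <- arrayInd(seq_len(prod(d)), d)
  w <- as.numeric(roi)
  mse <- rep(NA_real_, iters)
  maxStep <- cfg$maxStepVoxels * spacing
  for (it in seq_len(iters)) {
    pts <- idx0 + sweep(matrix(u, ncol = 3), 2, spacing, `/`)
    wm <- .interpTrilinear(moving, pts, background = 0)
    diffv <- (wm - as.numeric(fixed)) * w
    mse[it] <- sum(diffv^2) / max(1, sum(w))
    den <- g2 + diffv^2 / K
    scal <- ifelse(den > 1e-12, -diffv / den, 0)
    ux <- array(scal * as.numeric(gx), d)
    uy <- array(scal * as.numeric(gy), d)
    uz <- array(scal * as.numeric(gz), d)
    ux <- .smoothFFT(ux, tfU); uy <- .smoothFFT(uy, tfU); uz <- .smoothFFT(uz, tfU)
    ux <- pmin(pmax(ux, -maxStep[1]), maxStep[1])
    uy <- pmin(pmax(uy, -maxStep[2]), maxStep[2])
    uz <- pmin(pmax(uz, -maxStep[3]), maxStep[3])
    u[, , , 1] <- .smoothFFT(u[, , , 1] + ux, tfT)
    u[, , , 2] <- .smoothFFT(u[, , , 2] + uy, tfT)
    u[, , , 3] <- .smoothFFT(u[, , , 3] + uz, tfT)
  }
  list(u = u, mse = mse,
       lncc = .lncc(as.numeric(fixed),
                    .interpTrilinear(moving, idx0 +
                      sweep(matrix(u, ncol = 3), 2, spacing, `/`),
                      background = 0), w, .gaussianTransfer(d, rep(2, 3))))
}

#' Deformable registration of inspiration (moving) to expiration (fixed)
#'
#' Estimates the dense displacement field on the fixed grid, restricted to
#' the dilated-lung region of interest.  Backends: \code{"builtin"} -- the
#' multiresolution demons-style algorithm configured by
#' \code{\link{registrationConfig}}; \code{"oracle"} -- passes a supplied
#' ground-truth field through unchanged (for exact downstream testing);
#' \code{"external"} -- calls a user function
#' \code{function(fixed, moving, roi)} returning a
#' \linkS4class{DisplacementField} on the fixed grid (adapter contract for
#' external tools).
#'
#' @param fixed,moving \linkS4class{ImageVolume}s sharing spacing.
#' @param roi \linkS4class{BinaryMask} on the fixed grid (nonempty).
#' @param config a \code{\link{registrationConfig}}.
#' @param backend "builtin", "oracle" or "external".
#' @param oracleField \linkS4class{DisplacementField} for the oracle backend.
#' @param externalFn function for the external backend.
#' @return A \linkS4class{RegistrationResult}; non-improving similarity is
#'   flagged in \code{converged}, never silent.
#' @export
registerElastic <- function(fixed, moving, roi, config = registrationConfig(),
                            backend = c("builtin", "oracle", "external"),
                            oracleField = NULL, externalFn = NULL) {
  backend <- match.arg(backend)
  if (backend == "oracle") {
    if (is.null(oracleField)) stop("oracle backend needs oracleField")
    return(new("RegistrationResult", displacement = oracleField,
               backend = "oracle", metrics = list(), converged = TRUE))
  }
  if (backend == "external") {
    if (is.null(externalFn)) stop("external backend needs externalFn")
    fld <- externalFn(fixed, moving, roi)
    stopifnot(is(fld, "DisplacementField"))
    return(new("RegistrationResult", displacement = fld,
               backend = "external", metrics = list(), converged = TRUE))
  }
  if (any(abs(voxelSpacing(fixed) - voxelSpacing(moving)) > 1e-9))
    stop("fixed and moving must share voxel spacing")
  if (sum(imageData(roi)) == 0) stop("ROI is empty")

  # range-normalise both images together
  rng <- range(c(imageData(fixed), imageData(moving)))
  nf <- (imageData(fixed) - rng[1]) / max(diff(rng), 1e-12)
  nm <- (imageData(moving) - rng[1]) / max(diff(rng), 1e-12)

  # image/roi pyramids, coarse to fine
  nlev <- config$levels
  pf <- list(nf); pm <- list(nm); pr <- list(imageData(roi))
  psp <- list(voxelSpacing(fixed))
  for (l in seq_len(nlev - 1)) {
    pf[[l + 1]] <- .downsample2(pf[[l]])
    pm[[l + 1]] <- .downsample2(pm[[l]])
    pr[[l + 1]] <- (.downsample2(pr[[l]]) > 0.25) * 1
    psp[[l + 1]] <- psp[[l]] * 2
  }
  ord <- rev(seq_len(nlev))
  u <- array(0, c(dim(pf[[ord[1]]]), 3L))
  traces <- list()
  lnccs <- numeric(0)
  converged <- TRUE
  for (li in seq_along(ord)) {
    l <- ord[li]
    if (li > 1) u <- .upsampleField(u, dim(pf[[l]]))
    res <- .demonsLevel(pf[[l]], pm[[l]], pr[[l]], u, psp[[l]],
                        config$iterations[li], config)
    u <- res$u
    traces[[li]] <- res$mse
    lnccs <- c(lnccs, res$lncc)
    if (length(res$mse) > 1 &&
        res$mse[length(res$mse)] > res$mse[1]) converged <- FALSE
  }
  # zero outside the ROI (field defined only there)
  u <- u * as.numeric(imageData(roi))
  fld <- new("DisplacementField", vectors = u, spacing = voxelSpacing(fixed),
             origin = gridOrigin(fixed), roi = roi)
  new("RegistrationResult", displacement = fld, backend = "builtin",
      metrics = list(mse = traces, lnccByLevel = lnccs,
                     finalLNCC = lnccs[length(lnccs)]),
      converged = converged)
}

# Trilinear upsampling of a coarse field to a finer grid (values are mm so
# they carry over unchanged).
.upsampleField <- function(u, newDim) {
  dc <- dim(u)[1:3]
  out <- array(0, c(newDim, 3L))
  idx <- arrayInd(seq_len(prod(newDim)), newDim)
  # coarse voxel l covers fine voxels 2l-1, 2l  -> fine i maps to (i+1)/2
  src <- (idx + 1) / 2
  for (c3 in 1:3)
    out[, , , c3] <- array(.interpTrilinear(u[, , , c3], src), newDim)
  out
}

#' Mask-driven affine registration (moment matching)
#'
#' Computes the affine mapping fixed-space points to moving-space points from
#' the masks' first and second moments: centroids align exactly and the
#' symmetric square roots of the world-coordinate covariance matrices match
#' the mask ellipsoids.  Deterministic and closed-form.
#'
#' @param fixed,moving nonempty \linkS4class{BinaryMask}s.
#' @return An \linkS4class{AffineTransform} (fixed to moving).
#' @export
registerAffine <- function(fixed, moving) {
  mom <- function(mask) {
    w <- imageData(mask) == 1
    if (!any(w)) stop("empty mask cannot be registered")
    pts <- worldGrid(mask)[as.vector(w), , drop = FALSE]
    mu <- colMeans(pts)
    cc <- sweep(pts, 2, mu)
    list(mu = mu, C = crossprod(cc) / nrow(cc))
  }
  sqrtm <- function(C) {
    e <- eigen(C, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 1e-12))) %*% t(e$vectors)
  }
  mf <- mom(fixed); mm <- mom(moving)
  L <- sqrtm(mm$C) %*% solve(sqrtm(mf$C))
  AffineTransform(linear = L, translation = mm$mu - as.vector(L %*% mf$mu))
}

#' Map points through a displacement field
#'
#' Trilinearly interpolates the field at each (fixed-space) point and returns
#' the displaced points (their moving-space correspondences).  Category and
#' side labels are preserved; points outside the fixed-grid extent are
#' rejected with a diagnostic.
#'
#' @param points a \linkS4class{LandmarkSet} in fixed space.
#' @param displacement a \linkS4class{DisplacementField}.
#' @return a \linkS4class{LandmarkSet} with phase "registered".
#' @export
transformPoints <- function(points, displacement) {
  idx <- worldToIndex(displacement, points@points)
  d <- gridDim(displacement)
  bad <- idx[, 1] < 1 | idx[, 1] > d[1] | idx[, 2] < 1 | idx[, 2] > d[2] |
         idx[, 3] < 1 | idx[, 3] > d[3]
  if (any(bad))
    stop(sum(bad), " point(s) outside the fixed-grid extent")
  u <- sapply(1:3, function(c3)
    .interpTrilinear(displacement@vectors[, , , c3], idx))
  LandmarkSet(points@points + rbind(u), points@category, points@side,
              "registered")
}

#' Warp a moving image through a displacement field
#'
#' Pull-back resampling: the output at fixed-grid point \eqn{x} samples the
#' moving image at \eqn{x + u(x)} with trilinear interpolation.
#'
#' @param moving an \linkS4class{ImageVolume} or \linkS4class{BinaryMask}.
#' @param displacement a \linkS4class{DisplacementField} on the fixed grid.
#' @param background value for out-of-extent samples.
#' @return warped volume on the fixed grid (masks are re-binarised at 0.5).
#' @export
warpImage <- function(moving, displacement, background = 0) {
  d <- gridDim(displacement)
  pts <- worldGrid(displacement) + matrix(displacement@vectors, ncol = 3)
  idx <- worldToIndex(moving, pts)
  vals <- .interpTrilinear(imageData(moving), idx, background = background)
  if (is(moving, "BinaryMask"))
    BinaryMask(array(as.numeric(vals >= 0.5), d), displacement@spacing,
               displacement@origin)
  else
    ImageVolume(array(vals, d), displacement@spacing, displacement@origin)
}
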