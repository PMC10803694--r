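# Shared fixtures, memoised so expensive phantoms are built once per run.

.fixtures <- new.env(parent = emptyenv())

memoFixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# default healthy phantom, full resolution, with images
defaultSubject <- function() memoFixture("defaultSubject", function()
  makePhantom(DeformationModel()))

# same model, masks only
defaultMaskSubject <- function() memoFixture("defaultMaskSubject", function()
  makePhantom(DeformationModel(), withImages = FALSE))

defaultField <- function() memoFixture("defaultField", function() {
  s <- defaultMaskSubject()
  roi <- dilateMask(s@lungMaskExp, 5)
  lungdeform:::.modelField(s@model, s@lungMaskExp, roi)
})

# small subject for registration smoke tests
smallSubject <- function() memoFixture("smallSubject", function()
  makePhantom(DeformationModel(), gridShape = c(32, 32, 32), spacing = 4))

# independent finite-difference Jacobian oracle on the closed-form
# displacement (central differences, 1e-3 mm step), written directly against
# trueDisplacement so it shares no code with jacobianMap
fdJacobianOracle <- function(model, points, step = 1e-3) {
  pts <- rbind(points)
  n <- nrow(pts)
  cols <- vector("list", 3)
  for (a in 1:3) {
    e <- matrix(0, n, 3); e[, a] <- step
    fp <- (pts + e) + trueDisplacement(model, pts + e)
    fm <- (pts - e) + trueDisplacement(model, pts - e)
    cols[[a]] <- (fp - fm) / (2 * step)
  }
  cols[[1]][, 1] * (cols[[2]][, 2] * cols[[3]][, 3] -
                      cols[[2]][, 3] * cols[[3]][, 2]) -
  cols[[2]][, 1] * (cols[[1]][, 2] * cols[[3]][, 3] -
                      cols[[1]][, 3] * cols[[3]][, 2]) +
  cols[[3]][, 1] * (cols[[1]][, 2] * cols[[2]][, 3] -
                      cols[[1]][, 3] * cols[[2]][, 2])
}

# brute-force voxel-counting Dice/IoU oracle
bruteOverlap <- function(a, b) {
  stopifnot(length(a) == length(b))
  tp <- 0L; fn <- 0L; fp <- 0L; un <- 0L
  for (i in seq_along(a)) {
    if (a[i] == 1 && b[i] == 1) tp <- tp + 1L
    if (a[i] == 0 && b[i] == 1) fn <- fn + 1L
    if (a[i] == 1 && b[i] == 0) fp <- fp + 1L
    if (a[i] == 1 || b[i] == 1) un <- un + 1L
  }
  list(tp = tp, fn = fn, fp = fp,
       dice = if (2 * tp + fn + fp == 0) NA_real_ else
         2 * tp / (2 * tp + fn + fp),
       iou = if (un == 0) NA_real_ else tp / un)
}

# uniform-scaling linear displacement field on a given mask geometry
linearField <- function(geom, A, center = c(0, 0, 0)) {
  pts <- worldGrid(geom)
  u <- sweep(pts, 2, center) %*% t(A - diag(3))
  new("DisplacementField", vectors = array(u, c(gridDim(geom), 3L)),
      spacing = voxelSpacing(geom), origin = gridOrigin(geom), roi = NULL)
}

fullMask <- function(dims = c(32, 32, 32), spacing = 2) {
  BinaryMask(array(1, dims), spacing, -(dims - 1) / 2 * spacing)
}

# cheap oracle-registration study cohort (shared by several files)
smallOracleRun <- function() memoFixture("smallOracleRun", function() {
  co <- makeCohort(6, 6, seed = 42, gridShape = c(32, 32, 32), spacing = 4,
                   withImages = FALSE)
  list(cohort = co,
       result = runPipeline(co, pipelineConfig(backend = "oracle",
                                               spacing = NULL)))
})
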