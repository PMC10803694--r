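test_that("oracle and external backends honour the adapter contract", {
  s <- smallSubject()
  roi <- dilateMask(s@lungMaskExp, 3)
  fld <- lungdeform:::.modelField(s@model, s@lungMaskExp, roi)
  res <- registerElastic(s@expiration, s@inspiration, roi,
                         backend = "oracle", oracleField = fld)
  expect_identical(res@displacement@vectors, fld@vectors)
  ext <- registerElastic(s@expiration, s@inspiration, roi,
                         backend = "external",
                         externalFn = function(f, m, r) fld)
  expect_identical(ext@displacement@vectors, fld@vectors)
  expect_error(registerElastic(s@expiration, s@inspiration, roi,
                               backend = "oracle"), "oracleField")
  bad <- ImageVolume(imageData(s@inspiration), voxelSpacing(s@inspiration) * 2)
  expect_error(registerElastic(s@expiration, bad, roi), "spacing")
  empty <- BinaryMask(array(0, gridDim(s@expiration)),
                      voxelSpacing(s@expiration), gridOrigin(s@expiration))
  expect_error(registerElastic(s@expiration, s@inspiration, empty), "empty")
})

test_that("self-registration returns a null field, deterministically", {
  s <- smallSubject()
  roi <- dilateMask(s@lungMaskExp, 3)
  cfg <- registrationConfig(iterations = c(20L, 10L, 5L))
  r1 <- registerElastic(s@expiration, s@expiration, roi, config = cfg)
  expect_lt(max(abs(r1@displacement@vectors)) / 4, 1e-3)  # voxels at 4 mm
  # identical inputs and config give bit-identical fields
  r2 <- registerElastic(s@expiration, s@inspiration, roi, config = cfg)
  r3 <- registerElastic(s@expiration, s@inspiration, roi, config = cfg)
  expect_identical(r2@displacement@vectors, r3@displacement@vectors)
})

test_that("mask-driven affine registration is exact on moments", {
  s <- defaultMaskSubject()
  a0 <- registerAffine(s@lungMaskExp, s@lungMaskExp)
  expect_lt(max(abs(a0@linear - diag(3))), 1e-3)
  expect_lt(max(abs(a0@translation)), 0.1)
  shifted <- BinaryMask(imageData(s@lungMaskExp), voxelSpacing(s@lungMaskExp),
                        gridOrigin(s@lungMaskExp) + c(5, 0, 0))
  at <- registerAffine(s@lungMaskExp, shifted)
  expect_equal(at@translation, c(5, 0, 0), tolerance = 0.5)
  # different lung radii: post-registration mask IoU > 0.85
  s2 <- makePhantom(DeformationModel(lungRadii = c(38, 42, 52), seed = 3L),
                    withImages = FALSE)
  aff <- registerAffine(s@lungMaskExp, s2@lungMaskExp)
  pts <- applyAffine(aff, worldGrid(s@lungMaskExp))
  v <- lungdeform:::.interpTrilinear(imageData(s2@lungMaskExp),
                                     worldToIndex(s2@lungMaskExp, pts))
  moved <- BinaryMask(array(as.numeric(v >= 0.5), gridDim(s@lungMaskExp)),
                      voxelSpacing(s@lungMaskExp), gridOrigin(s@lungMaskExp))
  expect_gt(iouOverlap(moved, s@lungMaskExp), 0.85)
  expect_error(registerAffine(s@lungMaskExp,
    BinaryMask(array(0, c(8, 8, 8)))), "empty")
})

test_that("point transport follows the field exactly", {
  s <- defaultMaskSubject()
  d <- gridDim(s@lungMaskExp)
  zero <- new("DisplacementField", vectors = array(0, c(d, 3L)),
              spacing = voxelSpacing(s@lungMaskExp),
              origin = gridOrigin(s@lungMaskExp), roi = NULL)
  lm <- s@landmarksExp
  expect_equal(landmarkPoints(transformPoints(lm, zero)),
               landmarkPoints(lm), tolerance = 1e-12)
  cst <- zero; cst@vectors[, , , 1] <- 3
  expect_equal(landmarkPoints(transformPoints(lm, cst)),
               sweep(landmarkPoints(lm), 2, c(3, 0, 0), `+`),
               tolerance = 1e-12)
  # the true field maps expiration landmarks onto the inspiration ones
  reg <- transformPoints(lm, defaultField())
  expect_lt(max(sqrt(rowSums((landmarkPoints(reg) -
    landmarkPoints(s@landmarksInsp))^2))), 0.1)
  expect_identical(reg@category, lm@category)
  far <- LandmarkSet(rbind(c(1e4, 0, 0)), "A", "left", "exp")
  expect_error(transformPoints(far, zero), "outside")
})

test_that("warping is a pull-back resampling with sane degenerate cases", {
  s <- smallSubject()
  d <- gridDim(s@expiration)
  zero <- new("DisplacementField", vectors = array(0, c(d, 3L)),
              spacing = voxelSpacing(s@expiration),
              origin = gridOrigin(s@expiration), roi = NULL)
  expect_equal(imageData(warpImage(s@inspiration, zero)),
               imageData(s@inspiration), tolerance = 1e-12)
  cst <- ImageVolume(array(7, d), voxelSpacing(s@expiration),
                     gridOrigin(s@expiration))
  rnd <- zero; set.seed(5); rnd@vectors[] <- stats::rnorm(length(rnd@vectors))
  expect_true(all(abs(imageData(warpImage(cst, rnd, background = 7)) - 7)
                  < 1e-12))
})

test_that("forward and backward registrations are inverse-consistent", {
  s <- smallSubject()
  rAB <- registerElastic(s@expiration, s@inspiration,
                         dilateMask(s@lungMaskExp, 3), backend = "builtin")
  rBA <- registerElastic(s@inspiration, s@expiration,
                         dilateMask(s@lungMaskInsp, 3), backend = "builtin")
  w <- which(imageData(s@lungMaskExp) == 1)
  p0 <- worldGrid(s@lungMaskExp)[w, , drop = FALSE]
  uab <- sapply(1:3, function(c3) lungdeform:::.interpTrilinear(
    rAB@displacement@vectors[, , , c3], worldToIndex(rAB@displacement, p0)))
  p1 <- p0 + uab
  uba <- sapply(1:3, function(c3) lungdeform:::.interpTrilinear(
    rBA@displacement@vectors[, , , c3], worldToIndex(rBA@displacement, p1)))
  expect_lt(mean(sqrt(rowSums((uab + uba)^2))) / 4, 1)  # voxels at 4 mm
})
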