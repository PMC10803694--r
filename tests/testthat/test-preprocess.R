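test_that("isotropic resampling preserves grids, constants and volumes", {
  img <- ImageVolume(array(stats::runif(8^3), c(8, 8, 8)), 2, c(0, 0, 0))
  expect_identical(resampleIsotropic(img, 2), img)
  cst <- ImageVolume(array(5, c(10, 10, 10)), 2)
  r <- resampleIsotropic(cst, 1.3)
  expect_true(all(abs(imageData(r) - 5) < 1e-12))
  expect_equal(voxelSpacing(r), rep(1.3, 3))
  # 2 mm -> 1 mm on the default phantom follows the documented rounding rule
  s <- defaultMaskSubject()
  m1 <- resampleIsotropic(s@lungMaskExp, 1)
  expect_equal(gridDim(m1), c(127L, 127L, 127L))
  expect_lt(abs(lungVolume(m1) - lungVolume(s@lungMaskExp)) /
              lungVolume(s@lungMaskExp), 0.01)
  # spacing-convergence: halving the spacing changes the volume < 1%
  m05 <- resampleIsotropic(s@lungMaskExp, 4)
  expect_lt(abs(lungVolume(m05) - lungVolume(s@lungMaskExp)) /
              lungVolume(s@lungMaskExp), 0.01)
  expect_error(resampleIsotropic(
    ImageVolume(array(0, c(8, 8, 1)), 1), 0.5), "degenerate")
})

test_that("lung segmentation recovers the analytic masks", {
  s <- defaultSubject()
  seg <- segmentLungs(s@expiration)
  expect_gt(diceToTemplate(seg, s@lungMaskExp)@dice, 0.97)
  # 10% acquisition noise still segments well
  sn <- makePhantom(DeformationModel(), imageNoiseSd = 10)
  segn <- segmentLungs(sn@expiration)
  expect_gt(diceToTemplate(segn, sn@lungMaskExp)@dice, 0.95)
  # degenerate constant image is rejected
  expect_error(segmentLungs(ImageVolume(array(1, c(8, 8, 8)))), "constant")
  # idempotence under masking: segmenting the masked image returns the mask
  masked <- ImageVolume(imageData(s@expiration) * imageData(seg),
                        voxelSpacing(seg), gridOrigin(seg))
  expect_identical(imageData(segmentLungs(masked)), imageData(seg))
})

test_that("ball dilation is exact, monotone and distance-correct", {
  m <- fullMask(c(9, 9, 9), 1)
  m@data[] <- 0; m@data[5, 5, 5] <- 1
  expect_identical(dilateMask(m, 0), m)
  d1 <- dilateMask(m, 1)
  expect_equal(sum(imageData(d1)), 7)  # 6-neighbourhood + centre
  # monotone in radius
  set.seed(4)
  rnd <- BinaryMask(array(as.numeric(stats::runif(16^3) > 0.97), c(16, 16, 16)), 1)
  d2 <- dilateMask(rnd, 2); d3 <- dilateMask(rnd, 3)
  expect_true(all(imageData(d2) >= imageData(rnd)))
  expect_true(all(imageData(d3) >= imageData(d2)))
  # distance-transform oracle on a small ellipsoid
  dims <- c(20, 20, 20)
  g <- BinaryMask(array(0, dims), 2, -c(19, 19, 19))
  pts <- worldGrid(g)
  inside <- rowSums((pts / 10)^2) <= 1
  g@data[] <- as.numeric(inside)
  r <- 3L
  dil <- dilateMask(g, r)
  src <- pts[inside, , drop = FALSE]
  mind <- apply(pts, 1, function(p)
    sqrt(min(colSums((t(src) - p)^2))))
  expect_identical(as.vector(imageData(dil) == 1),
                   mind <= r * 2 + 1e-9)  # radius in voxels at 2 mm
})

test_that("lung volume is voxel count times voxel volume in ml", {
  m <- BinaryMask(array(0, c(20, 20, 20)), 1)
  m@data[1:10, 1:10, 1:10] <- 1
  expect_equal(lungVolume(m), 1.0)
  expect_error(lungVolume(BinaryMask(array(0, c(4, 4, 4)))), "empty")
  # analytic ellipsoid (60, 40, 80) mm within 2% at 2 mm spacing
  dims <- c(76, 56, 96)
  g <- ImageVolume(array(0, dims), 2, -(dims - 1))
  q <- rowSums(sweep(worldGrid(g), 2, c(60, 40, 80), `/`)^2)
  mk <- BinaryMask(array(as.numeric(q <= 1), dims), 2, -(dims - 1))
  expect_lt(abs(lungVolume(mk) - 4 / 3 * pi * 60 * 40 * 80 / 1000) /
              (4 / 3 * pi * 60 * 40 * 80 / 1000), 0.02)
})
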