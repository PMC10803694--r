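test_that("Jacobian map reproduces analytic determinants", {
  m <- fullMask()
  zero <- new("DisplacementField", vectors = array(0, c(32, 32, 32, 3)),
              spacing = voxelSpacing(m), origin = gridOrigin(m), roi = NULL)
  expect_true(all(abs(mapValues(jacobianMap(zero)) - 1) < 1e-12))
  # uniform scaling s = 0.8 -> det 0.512 at interior voxels
  fld <- linearField(m, diag(rep(0.8, 3)))
  j <- mapValues(jacobianMap(fld))[2:31, 2:31, 2:31]
  expect_lt(max(abs(j - 0.512)), 1e-6)
  # 20 random well-conditioned linear maps -> det(A)
  set.seed(7)
  for (i in 1:20) {
    A <- diag(3) + matrix(stats::rnorm(9, sd = 0.1), 3, 3)
    ji <- mapValues(jacobianMap(linearField(m, A)))[2:31, 2:31, 2:31]
    expect_lt(max(abs(ji - det(A))), 1e-6)
  }
})

test_that("Jacobian of the breathing phantom matches the analytic oracle", {
  # at the 1 mm working resolution the central-difference map agrees with
  # the small-step finite-difference oracle on the closed form to < 1%
  # (checked on a random subsample of lung voxels to keep the run light)
  mdl <- DeformationModel()
  dims <- c(127L, 127L, 127L)
  g <- ImageVolume(array(0, dims), 1, -c(63, 63, 63))
  pts <- worldGrid(g)
  lungw <- which(lungdeform:::.lungEq(mdl, pts) <= 1)
  mask <- BinaryMask(array(0, dims), 1, -c(63, 63, 63))
  mask@data[lungw] <- 1
  jac <- jacobianMap(lungdeform:::.modelField(mdl, mask, NULL), mask = mask)
  set.seed(2)
  sel <- sample(lungw, 20000)
  fd <- fdJacobianOracle(mdl, pts[sel, , drop = FALSE])
  expect_lt(max(abs(mapValues(jac)[sel] - fd) / fd), 0.01)
  expect_equal(provenance(jac)$clippedVoxels, 0)
})

test_that("volume-ratio normalisation and log transform behave as stages", {
  s <- defaultMaskSubject()
  jac <- jacobianMap(defaultField(), mask = s@lungMaskExp)
  expect_identical(mapValues(normalizeJac(jac, 2, 2)), mapValues(jac))
  vI <- lungVolume(s@lungMaskInsp); vE <- lungVolume(s@lungMaskExp)
  jn <- normalizeJac(jac, vI, vE)
  expect_equal(mapStage(jn), "JAC-N")
  w <- imageData(s@lungMaskExp) == 1
  expect_lt(abs(mean(mapValues(jn)[w]) - 1), 0.03)
  jl <- logJac(jn)
  expect_equal(mapStage(jl), "JAC-NL")
  expect_lt(max(abs(exp(mapValues(jl)[w]) - mapValues(jn)[w])), 1e-12)
  # stage transitions only in the documented order
  expect_error(normalizeJac(jn, vI, vE), "stage-JAC")
  expect_error(logJac(jac), "stage-JAC-N")
  expect_error(normalizeJac(jac, -1, 2), "positive")
  # uniform-scaling phantom: the ratio cancels, JAC-NL is 0
  ms <- DeformationModel(affineScale = rep(1.1, 3), amplitude = 0)
  ss <- makePhantom(ms, withImages = FALSE)
  js <- jacobianMap(lungdeform:::.modelField(ms, ss@lungMaskExp, NULL),
                    mask = ss@lungMaskExp)
  jnl <- logJac(normalizeJac(js, lungVolume(ss@lungMaskInsp),
                             lungVolume(ss@lungMaskExp)))
  expect_lt(max(abs(mapValues(jnl)[imageData(ss@lungMaskExp) == 1])), 0.02)
})

test_that("common-space transport is an affine pull-back of the values", {
  s <- defaultMaskSubject()
  jac <- jacobianMap(defaultField(), mask = s@lungMaskExp)
  jl <- logJac(normalizeJac(jac, lungVolume(s@lungMaskInsp),
                            lungVolume(s@lungMaskExp)))
  idt <- AffineTransform()
  same <- toCommonSpace(jl, idt, s@lungMaskExp)
  w <- imageData(validMask(same)) == 1
  expect_lt(max(abs(mapValues(same)[w] - mapValues(jl)[w])), 1e-9)
  expect_equal(mapStage(same), "JAC-NLC")
  # constant map stays constant under any affine
  cj <- jl; cj@values[] <- -0.2
  aff <- AffineTransform(diag(c(1.1, 0.95, 1.02)), c(3, -2, 1))
  cc <- toCommonSpace(cj, aff, s@lungMaskExp)
  wc <- imageData(validMask(cc)) == 1
  expect_true(all(abs(mapValues(cc)[wc] + 0.2) < 1e-9))
  # linear-in-world values are transported exactly (trilinear is exact on
  # linear functions): independent oracle by direct evaluation
  lin <- jl
  pts <- worldGrid(s@lungMaskExp)
  lin@values[] <- 0.01 * pts[, 1] - 0.005 * pts[, 3]
  lt <- toCommonSpace(lin, aff, s@lungMaskExp)
  wl <- imageData(validMask(lt)) == 1
  moved <- applyAffine(aff, pts)
  expect_lt(max(abs(mapValues(lt)[wl] -
                      (0.01 * moved[, 1] - 0.005 * moved[, 3])[wl])), 1e-9)
})

test_that("group averages, projections and Jac-mean are elementwise means", {
  s <- defaultMaskSubject()
  jac <- jacobianMap(defaultField(), mask = s@lungMaskExp)
  jl <- toCommonSpace(logJac(normalizeJac(jac, lungVolume(s@lungMaskInsp),
                                          lungVolume(s@lungMaskExp))),
                      AffineTransform(), s@lungMaskExp)
  g1 <- groupAverage(list(jl), group = "one")
  expect_equal(g1@values, jl@values, tolerance = 1e-12)
  a <- jl; a@values[] <- -0.1
  b <- jl; b@values[] <- -0.3
  g2 <- groupAverage(list(a, b), minCoverage = 2L)
  wc <- imageData(g2@coverage) == 1
  expect_true(all(abs(g2@values[wc] + 0.2) < 1e-12))
  expect_error(groupAverage(list()), "empty")
  # projections equal brute-force per-line means over covered voxels
  for (ax in c("x", "y", "z")) {
    pr <- axisProjection(g1, ax)
    ai <- match(ax, c("x", "y", "z"))
    num <- apply(jl@values * jl@mask@data, setdiff(1:3, ai), sum)
    den <- apply(jl@mask@data, setdiff(1:3, ai), sum)
    ref <- ifelse(den > 0, num / den, NA_real_)
    expect_equal(pr, ref, tolerance = 1e-12)
  }
  # Jac-mean is the absolute mean over the analysis mask
  cj <- jl; cj@values[] <- -0.2
  expect_equal(jacMean(cj), 0.2)
  zj <- jl; zj@values[] <- 0
  expect_equal(jacMean(zj), 0)
  expect_gte(jacMean(jl, meanOfAbs = TRUE), jacMean(jl))
  expect_error(jacMean(jl, mask = BinaryMask(array(0, gridDim(jl@mask)),
    voxelSpacing(jl@mask), gridOrigin(jl@mask))), "empty")
})

test_that("marked-deformation segmentation and the healthy template", {
  s <- defaultMaskSubject()
  jac <- jacobianMap(defaultField(), mask = s@lungMaskExp)
  jl <- toCommonSpace(logJac(normalizeJac(jac, lungVolume(s@lungMaskInsp),
                                          lungVolume(s@lungMaskExp))),
                      AffineTransform(), s@lungMaskExp)
  zj <- jl; zj@values[] <- 0
  expect_equal(sum(imageData(markedDeformationMask(zj))), 0)
  cj <- jl; cj@values[] <- -0.2
  expect_equal(imageData(markedDeformationMask(cj, 0.15)),
               imageData(validMask(cj)))
  # threshold monotonicity: raising the cutoff never grows the mask
  m10 <- imageData(markedDeformationMask(jl, 0.10))
  m15 <- imageData(markedDeformationMask(jl, 0.15))
  m20 <- imageData(markedDeformationMask(jl, 0.20))
  expect_true(all(m15 <= m10) && all(m20 <= m15))
  # literal rule selects the other side
  lit <- markedDeformationMask(cj, 0.15, rule = "literal")
  expect_equal(sum(imageData(lit)), sum(imageData(validMask(cj))))
  # template: empty average errors, constant shrinkage fills the coverage
  haj0 <- groupAverage(list(zj), group = "control")
  expect_error(healthyTemplate(haj0), "empty")
  hajc <- groupAverage(list(cj), group = "control")
  tpl <- healthyTemplate(hajc)
  expect_equal(imageData(tpl), imageData(hajc@coverage))
  # synthetic control template concentrates in the peripheral shell
  run <- smallOracleRun()
  tm <- run$result$template
  csId <- run$result$manifest$commonSubject
  cs <- run$cohort$subjects[[match(csId,
    vapply(run$cohort$subjects, function(x) x@subjectId, character(1)))]]
  wv <- which(imageData(tm) == 1)
  r <- sqrt(lungdeform:::.normRadius2(cs@model, worldGrid(tm)[wv, ,
                                                             drop = FALSE]))
  expect_gt(mean(r > cs@model@shellFraction), 0.7)
})

test_that("Dice agrees with exhaustive counting and its identities", {
  tpl <- BinaryMask(array(1, c(4, 4, 4)))
  expect_equal(diceToTemplate(tpl, tpl)@dice, 1)
  expect_equal(diceToTemplate(tpl, tpl)@fn, 0L)
  # direct formula: TP=2, FN=1, FP=1 -> 4/6
  a <- BinaryMask(array(0, c(4, 4, 4))); a@data[1:3] <- 1
  b <- BinaryMask(array(0, c(4, 4, 4))); b@data[2:4] <- 1
  db <- diceToTemplate(a, b)
  expect_equal(c(db@tp, db@fn, db@fp), c(2L, 1L, 1L))
  expect_equal(db@dice, 2 / 3)
  # both empty: undefined, reported missing
  e <- BinaryMask(array(0, c(4, 4, 4)))
  expect_true(is.na(diceToTemplate(e, e)@dice))
  # 100 random 8^3 pairs: exact match with the brute-force oracle,
  # Dice symmetry, and the Dice-IoU identity
  set.seed(99)
  for (i in 1:100) {
    x <- BinaryMask(array(as.numeric(stats::runif(512) > 0.6), c(8, 8, 8)))
    y <- BinaryMask(array(as.numeric(stats::runif(512) > 0.6), c(8, 8, 8)))
    got <- diceToTemplate(x, y)
    ref <- bruteOverlap(as.vector(imageData(x)), as.vector(imageData(y)))
    expect_identical(c(got@tp, got@fn, got@fp), c(ref$tp, ref$fn, ref$fp))
    expect_equal(got@dice, ref$dice)
    expect_equal(got@dice, diceToTemplate(y, x)@dice)
    iou <- iouOverlap(x, y)
    if (!is.na(got@dice))
      expect_equal(iou, got@dice / (2 - got@dice), tolerance = 1e-12)
  }
})
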