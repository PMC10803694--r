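test_that("IoU handles trivial, exact and degenerate cases", {
  a <- BinaryMask(array(1, c(4, 4, 4)))
  expect_equal(iouOverlap(a, a), 1)
  b <- BinaryMask(array(0, c(4, 4, 4)))
  expect_equal(iouOverlap(a, b), 0)
  # |A| = |B| = 100, |A intersect B| = 60 -> 60/140
  x <- BinaryMask(array(0, c(10, 10, 10))); x@data[1:100] <- 1
  y <- BinaryMask(array(0, c(10, 10, 10))); y@data[41:140] <- 1
  expect_equal(iouOverlap(x, y), 60 / 140)
  expect_true(is.na(iouOverlap(b, b)))
  expect_error(iouOverlap(a, BinaryMask(array(1, c(5, 5, 5)))), "grid")
})

test_that("landmark distances are per-category Euclidean means", {
  p <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
  ref <- LandmarkSet(p, c("A", "A", "B", "B"),
                     c("left", "right", "left", "right"), "insp")
  reg0 <- LandmarkSet(p, c("A", "A", "B", "B"),
                      c("left", "right", "left", "right"), "registered")
  expect_equal(unname(landmarkDistances(reg0, ref)), c(0, 0))
  off <- LandmarkSet(sweep(p, 2, c(3, 4, 0), `+`), c("A", "A", "B", "B"),
                     c("left", "right", "left", "right"), "registered")
  expect_equal(landmarkDistances(off, ref),
               c(da_mm = 5, db_mm = 5))
  wrong <- LandmarkSet(p, c("A", "A", "A", "B"),
                       c("left", "right", "left", "right"), "registered")
  expect_error(landmarkDistances(wrong, ref), "labels")
  # oracle-registered phantom landmarks land within 0.1 mm
  s <- defaultMaskSubject()
  reg <- transformPoints(s@landmarksExp, defaultField())
  dd <- landmarkDistances(reg, s@landmarksInsp)
  expect_lt(max(dd), 0.1)
})

test_that("ICC(2,1) matches the ANOVA mean-squares oracle", {
  # identical columns with between-subject variance
  x <- cbind(1:6, 1:6)
  r <- iccTwoWay(x)
  expect_equal(r$icc, 1)
  expect_equal(r$classification, "almost perfect")
  # independent columns: ICC near 0 (null simulation fixture)
  set.seed(11)
  xn <- matrix(stats::rnorm(400), 200, 2)
  expect_lt(abs(iccTwoWay(xn)$icc), 0.15)
  # 6 x 2 fixture against stats::aov mean squares
  set.seed(1)
  xf <- matrix(stats::rnorm(12), 6, 2) + stats::rnorm(6)
  got <- iccTwoWay(xf)
  df <- data.frame(y = as.vector(xf), subj = factor(rep(1:6, 2)),
                   rater = factor(rep(1:2, each = 6)))
  ms <- stats::anova(stats::aov(y ~ subj + rater, df))$`Mean Sq`
  ref <- (ms[1] - ms[3]) / (ms[1] + ms[3] + 2 * (ms[2] - ms[3]) / 6)
  expect_equal(got$icc, ref, tolerance = 1e-12)
  # invariance under a common positive affine rescaling
  expect_equal(iccTwoWay(3 * xf + 10)$icc, got$icc, tolerance = 1e-12)
  expect_error(iccTwoWay(matrix(1, 6, 2)), "variance")
  expect_error(iccTwoWay(matrix(1:8, 2, 4)), "exactly 2")
  expect_error(iccTwoWay(cbind(1:2, 2:3)), "5 subjects")
})

test_that("Bland-Altman limits follow the 1.96-SD formula", {
  ba <- blandAltman(c(-1, 0, 1), c(0, 0, 0))
  expect_equal(ba$meanDiff, 0)
  expect_equal(ba$loaLow, -1.96)
  expect_equal(ba$loaHigh, 1.96)
  same <- blandAltman(1:5, 1:5)
  expect_equal(c(same$meanDiff, same$loaLow, same$loaHigh), c(0, 0, 0))
  # random fixture against direct recomputation
  set.seed(13)
  m1 <- stats::rnorm(50); m2 <- stats::rnorm(50)
  got <- blandAltman(m1, m2)
  d <- m1 - m2
  expect_equal(got$meanDiff, mean(d), tolerance = 1e-12)
  expect_equal(got$loaHigh, mean(d) + 1.96 * stats::sd(d), tolerance = 1e-12)
  # antisymmetry: swapping the pair order negates and mirrors
  swp <- blandAltman(m2, m1)
  expect_equal(swp$meanDiff, -got$meanDiff, tolerance = 1e-12)
  expect_equal(swp$loaLow, -got$loaHigh, tolerance = 1e-12)
  expect_error(blandAltman(1, 1), "pairs")
})

test_that("two-phase repeatability assembles ICC and limits per metric", {
  # bit-identical phases give perfect agreement
  qc <- data.frame(subject = rep(1:6, 2), phase = rep(1:2, each = 6),
                   iou = rep(seq(0.85, 0.95, length.out = 6), 2),
                   da_mm = rep(2:7, 2), db_mm = rep(3:8, 2))
  rep0 <- twoPhaseRepeatability(qc)
  for (m in c("iou", "da_mm", "db_mm")) {
    expect_equal(rep0$iccByMetric[[m]]$icc, 1)
    expect_equal(rep0$blandAltmanByMetric[[m]]$meanDiff, 0)
    expect_equal(rep0$blandAltmanByMetric[[m]]$loaHigh, 0)
  }
  # small independent per-phase noise at the designed between-subject
  # spread: all three ICCs exceed the "very good" threshold
  set.seed(31)
  n <- 40
  th <- list(iou = stats::rnorm(n, 0.9, 0.03), da_mm = stats::rnorm(n, 6, 1.8),
             db_mm = stats::rnorm(n, 6, 1.5))
  noise <- c(iou = 0.01, da_mm = 0.6, db_mm = 0.5)
  qc2 <- data.frame(subject = rep(1:n, 2), phase = rep(1:2, each = n))
  for (m in names(th)) qc2[[m]] <- rep(th[[m]], 2) +
      stats::rnorm(2 * n, 0, noise[[m]])
  rep2 <- twoPhaseRepeatability(qc2)
  for (m in names(th)) expect_gt(rep2$iccByMetric[[m]]$icc, 0.8)
  # a subject missing phase 2 is excluded with a message
  qc3 <- qc[-12, ]
  expect_message(rep3 <- twoPhaseRepeatability(qc3), "excluding")
  # a single subject cannot yield an ICC
  expect_error(twoPhaseRepeatability(qc[qc$subject == 1, ]), "5 subjects")
})
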