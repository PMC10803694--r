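test_that("the composite physiologic index is the printed linear formula", {
  expect_equal(computeCpi(100, 100, 100), 7)
  expect_equal(computeCpi(80, 80, 50), 43.3)
  # vectorised evaluation equals the scalar loop
  set.seed(17)
  fvc <- stats::runif(1000, 40, 120)
  fev1 <- stats::runif(1000, 40, 120)
  dlco <- stats::runif(1000, 20, 120)
  vec <- computeCpi(fvc, fev1, dlco)
  loop <- vapply(seq_len(1000),
                 function(i) computeCpi(fvc[i], fev1[i], dlco[i]), numeric(1))
  expect_identical(vec, loop)
  # exact partial derivatives (the formula is linear)
  base <- computeCpi(80, 90, 60)
  expect_equal(computeCpi(80, 90, 61) - base, -0.65)
  expect_equal(computeCpi(81, 90, 60) - base, -0.53)
  expect_equal(computeCpi(80, 91, 60) - base, 0.34)
  expect_error(computeCpi(-5, 90, 60), "nonnegative")
  expect_true(is.na(computeCpi(NA, 90, 60)))
})

test_that("group comparisons run the declared two-sided tests", {
  # symmetric 2x2 contingency: statistic 0, p = 1
  v <- rep(c("pos", "neg"), times = c(100, 100))
  g <- rep(c("a", "b"), 100)
  res <- compareGroups(v, g, kind = "chisq")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  # a 3-SD shift at n = 15/15 is detected
  set.seed(19)
  x <- c(stats::rnorm(15), stats::rnorm(15, mean = 3))
  gg <- rep(c("a", "b"), each = 15)
  expect_lt(compareGroups(x, gg, kind = "t")$p, 0.05)
  expect_lt(compareGroups(x, gg, kind = "wilcox")$p, 0.05)
  # the auto rule reports which test it chose
  auto <- compareGroups(x, gg, kind = "auto")
  expect_true(auto$test %in% c("t", "mann-whitney"))
  expect_equal(auto$direction, -1)
  expect_error(compareGroups(c(1, 2, 3), c("a", "b", "b"), kind = "t"),
               ">= 2 observations")
  expect_error(compareGroups(1:6, rep("a", 6)), "two groups")
})

test_that("Spearman correlation uses average ranks and monotone invariance", {
  x <- c(2, 4, 7, 9, 12, 15)
  expect_equal(spearmanCor(x, exp(x))$rho, 1)
  expect_equal(spearmanCor(x, -x)$rho, -1)
  # ties: matches an exhaustive average-rank computation
  set.seed(23)
  xt <- sample(1:4, 40, replace = TRUE)
  yt <- xt + sample(0:2, 40, replace = TRUE)
  got <- spearmanCor(xt, yt)$rho
  ref <- stats::cor(rank(xt), rank(yt))   # average ranks by definition
  expect_equal(got, ref, tolerance = 1e-12)
  # invariance under strictly monotone transforms
  set.seed(29)
  a <- stats::rnorm(30); b <- stats::rnorm(30)
  expect_equal(spearmanCor(exp(a), b)$rho, spearmanCor(a, b)$rho)
  cst <- spearmanCor(rep(1, 10), stats::rnorm(10))
  expect_true(is.na(cst$rho))
  expect_match(attr(cst, "diagnostic"), "constant")
  expect_error(spearmanCor(1:3, 1:3), "pairs")
})

test_that("severity analysis reports strata contrasts and signed correlations", {
  co <- makeCohort(10, 60, noiseSd = 0, seed = 3, withSubjects = FALSE)
  tab <- co$table
  # attach noise-free monotone endpoints (the stats layer under test)
  tab$jac_mean <- 0.3 - 0.25 * tab$severity
  tab$dice <- pmax(0, 1 - 1.1 * tab$severity)
  sa <- severityAnalysis(tab)
  # strata means strictly decreasing at zero noise
  strata <- cut(tab$mrc[tab$group == "IPF-like"], c(0, 1, 2, Inf))
  mns <- tapply(tab$jac_mean[tab$group == "IPF-like"], strata, mean)
  expect_true(all(diff(mns) < 0))
  expect_true(all(c("MRC1 vs MRC2", "MRC2 vs MRC3+", "MRC1 vs MRC3+") %in%
                    sa$mrcContrasts$contrast))
  ok <- sign(sa$correlations$rho) == sa$correlations$expected_sign
  expect_true(all(ok[!is.na(sa$correlations$rho)]))
  # BH adjustment is offered and flagged
  saBH <- severityAnalysis(tab, adjust = "BH")
  expect_true("p_adj" %in% names(saBH$correlations))
  # shuffled severity: no systematic sign pattern or strong correlations
  set.seed(41)
  tabS <- tab
  tabS$jac_mean <- sample(tabS$jac_mean)
  tabS$dice <- sample(tabS$dice)
  saS <- severityAnalysis(tabS)
  frac <- mean(abs(saS$correlations$rho) > 0.3, na.rm = TRUE)
  expect_lt(frac, 0.15)
})
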