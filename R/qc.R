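#' @include jacobian.R
NULL

#' Intersection over union of two masks
#'
#' Registration quality metric: overlap of the registered inspiratory lung
#' mask with the expiratory lung mask.  Undefined (NA) when both masks are
#' empty.
#'
#' @param maskA,maskB \linkS4class{BinaryMask}s on the same grid.
#' @return scalar in [0, 1], or NA.
#' @export
iouOverlap <- function(maskA, maskB) {
  if (!all(gridDim(maskA) == gridDim(maskB)))
    stop("masks must share a grid")
  a <- imageData(maskA) == 1; b <- imageData(maskB) == 1
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}

#' Mean landmark distances by category
#'
#' Per-category mean Euclidean distance (mm) between matching points of the
#' registered and reference landmark sets: DA for category A, DB for
#' category B.  Points are matched by category and side.
#'
#' @param registered,reference \linkS4class{LandmarkSet}s with matching
#'   labels.
#' @return named numeric c(da_mm, db_mm).
#' @export
landmarkDistances <- function(registered, reference) {
  keyR <- paste(registered@category, registered@side)
  keyF <- paste(reference@category, reference@side)
  if (!setequal(keyR, keyF) || anyDuplicated(keyR) != anyDuplicated(keyF))
    stop("landmark labels do not match between the two sets")
  ord <- match(keyR, keyF)
  if (any(is.na(ord))) stop("landmark labels do not match between the two sets")
  dist <- sqrt(rowSums((registered@points - reference@points[ord, ,
                                                             drop = FALSE])^2))
  c(da_mm = mean(dist[registered@category == "A"]),
    db_mm = mean(dist[registered@category == "B"]))
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC from
#' the ANOVA mean squares of a subjects x 2-measurements table, with the
#' conventional classification extended by the "very good" (> 0.80) and
#' "almost perfect" (> 0.95) labels.
#'
#' @param measures numeric matrix/data.frame, one row per subject, exactly 2
#'   repeated measurements (columns).
#' @return list(icc, classification, msr, msc, mse).
#' @export
iccTwoWay <- function(measures) {
  x <- as.matrix(measures)
  n <- nrow(x); k <- ncol(x)
  if (k != 2L) stop("exactly 2 repeated measurements per subject are required")
  if (n < 5L) stop("at least 5 subjects are required for the ICC")
  if (stats::var(as.vector(x)) == 0)
    stop("zero total variance: ICC undefined")
  grand <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm - grand)^2) / (k - 1)
  sse <- sum((x - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  cls <- if (icc > 0.95) "almost perfect" else if (icc > 0.80) "very good"
         else if (icc > 0.60) "good" else if (icc > 0.40) "moderate"
         else if (icc > 0.20) "fair" else if (icc > 0) "slight" else "null"
  list(icc = icc, classification = cls, msr = msr, msc = msc, mse = mse)
}

#' Bland-Altman agreement analysis
#'
#' Mean difference and 95% limits of agreement,
#' mean +/- 1.96 sd of the differences (sd with n-1 denominator).  Identical
#' pairs collapse the limits onto the mean (allowed).
#'
#' @param m1,m2 paired measurements (equal length >= 2), or \code{m1} a
#'   2-column matrix.
#' @return list(meanDiff, loaLow, loaHigh, sd, n).
#' @export
blandAltman <- function(m1, m2 = NULL) {
  if (is.null(m2)) { m2 <- m1[, 2]; m1 <- m1[, 1] }
  if (length(m1) != length(m2) || length(m1) < 2)
    stop("need >= 2 complete pairs")
  d <- m1 - m2
  s <- stats::sd(d)
  list(meanDiff = mean(d), loaLow = mean(d) - 1.96 * s,
       loaHigh = mean(d) + 1.96 * s, sd = s, n = length(d))
}

#' Two-phase repeatability report
#'
#' Assembles test-retest agreement (ICC(2,1) and Bland-Altman limits) of the
#' registration QC metrics across two acquisitions ("phases") of each
#' subject.  Subjects missing a phase are excluded with a message.
#'
#' @param qc data.frame with columns \code{subject}, \code{phase} (1/2) and
#'   one column per metric (default \code{iou}, \code{da_mm}, \code{db_mm}).
#' @param metrics metric column names to analyse.
#' @return list of class \code{QCReport}: per-metric ICC with classification
#'   and Bland-Altman (meanDiff, loaLow, loaHigh), plus the per-phase means.
#' @export
twoPhaseRepeatability <- function(qc, metrics = c("iou", "da_mm", "db_mm")) {
  stopifnot(all(c("subject", "phase") %in% names(qc)))
  metrics <- intersect(metrics, names(qc))
  wide <- function(metric) {
    p1 <- qc[qc$phase == 1, c("subject", metric)]
    p2 <- qc[qc$phase == 2, c("subject", metric)]
    keep <- intersect(p1$subject, p2$subject)
    dropped <- setdiff(unique(qc$subject), keep)
    if (length(dropped))
      message("excluding subject(s) missing a phase: ",
              paste(dropped, collapse = ", "))
    cbind(p1[match(keep, p1$subject), metric],
          p2[match(keep, p2$subject), metric])
  }
  out <- list(iccByMetric = list(), blandAltmanByMetric = list(),
              phaseMeans = list())
  for (m in metrics) {
    w <- wide(m)
    out$iccByMetric[[m]] <- iccTwoWay(w)
    out$blandAltmanByMetric[[m]] <- blandAltman(w)
    out$phaseMeans[[m]] <- colMeans(w)
  }
  class(out) <- "QCReport"
  out
}

#' @export
print.QCReport <- function(x, ...) {
  cat("Two-phase repeatability report\n")
  for (m in names(x$iccByMetric)) {
    icc <- x$iccByMetric[[m]]; ba <- x$blandAltmanByMetric[[m]]
    cat(sprintf("  %-6s ICC %.3f (%s); mean diff %.3g [%.3g, %.3g]\n",
                m, icc$icc, icc$classification, ba$meanDiff, ba$loaLow,
                ba$loaHigh))
  }
  invisible(x)
}

# Per-subject registration QC: IoU of the warped inspiratory mask against the
# expiratory mask, plus DA/DB of the registered landmarks against the true
# inspiration-space landmarks.
.subjectQC <- function(subject, regResult, maskInsp, maskExp) {
  warped <- warpImage(maskInsp, regResult@displacement)
  iou <- iouOverlap(warped, maskExp)
  reg <- transformPoints(subject@landmarksExp, regResult@displacement)
  dd <- landmarkDistances(reg, subject@landmarksInsp)
  c(iou = iou, dd)
}
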