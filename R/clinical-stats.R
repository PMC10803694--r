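#' @include qc.R
NULL

#' Composite physiologic index (CPI)
#'
#' \deqn{CPI = 91 - 0.65 \cdot DLco\% - 0.53 \cdot FVC\% + 0.34 \cdot FEV1\%}
#' Higher values indicate more severe functional impairment.  Missing inputs
#' propagate to a missing CPI (no imputation).
#'
#' @param fvcPct,fev1Pct,dlcoPct percent-predicted values (vectorised).
#' @return numeric CPI.
#' @examples
#' computeCpi(100, 100, 100)  # 7
#' @export
computeCpi <- function(fvcPct, fev1Pct, dlcoPct) {
  if (any(stats::na.omit(c(fvcPct, fev1Pct, dlcoPct)) < 0))
    stop("percent-predicted inputs must be nonnegative")
  91 - 0.65 * dlcoPct - 0.53 * fvcPct + 0.34 * fev1Pct
}

#' Two-group comparison
#'
#' Unpaired two-sided t-test or Mann-Whitney U (quantitative data), or
#' chi-square (categorical counts).  \code{kind = "auto"} screens both groups
#' with Shapiro-Wilk at alpha = 0.05 and picks the t-test when both pass; the
#' chosen test is always reported, never silent.
#'
#' @param values numeric vector (quantitative kinds) or factor/character
#'   (chi-square).
#' @param groups two-level factor of group labels.
#' @param kind "auto", "t", "wilcox" or "chisq".
#' @return one-row data.frame: test, statistic, p, direction (sign of
#'   group1 minus group2 location), n1, n2.
#' @export
compareGroups <- function(values, groups, kind = c("auto", "t", "wilcox",
                                                   "chisq")) {
  kind <- match.arg(kind)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  g1 <- values[groups == levels(groups)[1]]
  g2 <- values[groups == levels(groups)[2]]
  if (kind == "chisq" || (kind == "auto" && !is.numeric(values))) {
    tab <- table(values, groups)
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(data.frame(test = "chi-square", statistic = unname(ht$statistic),
                      p = ht$p.value, direction = NA_real_,
                      n1 = length(g1), n2 = length(g2)))
  }
  if (kind == "auto") {
    swp <- function(x) {
      if (length(unique(x)) < 3 || length(x) < 3) return(0)
      stats::shapiro.test(x[seq_len(min(length(x), 5000))])$p.value
    }
    kind <- if (swp(g1) > 0.05 && swp(g2) > 0.05) "t" else "wilcox"
  }
  if (kind == "t") {
    if (length(g1) < 2 || length(g2) < 2)
      stop("t-test needs >= 2 observations per group")
    ht <- stats::t.test(g1, g2)
    data.frame(test = "t", statistic = unname(ht$statistic), p = ht$p.value,
               direction = sign(mean(g1) - mean(g2)),
               n1 = length(g1), n2 = length(g2))
  } else {
    ht <- suppressWarnings(stats::wilcox.test(g1, g2))
    data.frame(test = "mann-whitney", statistic = unname(ht$statistic),
               p = ht$p.value,
               direction = sign(stats::median(g1) - stats::median(g2)),
               n1 = length(g1), n2 = length(g2))
  }
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, two-sided p value.
#' Constant input yields a missing result with a diagnostic attribute rather
#' than an error.
#'
#' @param x,y paired numeric vectors (>= 5 complete pairs).
#' @return one-row data.frame: rho, p, n.
#' @export
spearmanCor <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5) stop("need >= 5 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- data.frame(rho = NA_real_, p = NA_real_, n = length(x))
    attr(out, "diagnostic") <- "constant input: correlation undefined"
    return(out)
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  data.frame(rho = unname(ht$estimate), p = ht$p.value, n = length(x))
}

# Clinical columns correlated against the deformation endpoints, with the
# direction each is designed (and clinically expected) to show against
# severity.
.CLINICAL_COLUMNS <- c(fvc_pct = -1, fev1_pct = -1, tlc_pct = -1,
                       dlco_pct = -1, cpi = 1,
                       sgrq_symptoms = 1, sgrq_activity = 1, sgrq_impact = 1,
                       sgrq_total = 1, mwd6 = -1, fibrosis_pct = 1,
                       tpv_volume = -1, tpv_number = -1, tpv_tortuosity = 1,
                       pvv_number = -1, pvv_tortuosity = 1,
                       pav_volume = -1, pav_number = -1, pav_tortuosity = 1)

#' Severity analysis of a processed cohort
#'
#' (i) Dyspnea-strata comparison: \code{jac_mean} and \code{dice} across MRC
#' strata 1, 2 and >= 3 with the three pairwise contrasts; (ii) Spearman
#' correlations of \code{jac_mean} and \code{dice} against the pulmonary
#' function, quality-of-life, exercise, fibrosis-extent and vascular columns.
#' Correlations are computed on the disease-group rows (clinical severity
#' scores are only defined there); p values are unadjusted by default,
#' Benjamini-Hochberg optional (flagged in the output).
#'
#' @param cohort data.frame with \code{group}, \code{jac_mean}, \code{dice},
#'   \code{mrc} and clinical columns.
#' @param diseaseGroup label of the disease rows (default "IPF-like").
#' @param adjust "none" (default) or "BH".
#' @return list with data.frames \code{mrcContrasts} and \code{correlations}.
#' @export
severityAnalysis <- function(cohort, diseaseGroup = "IPF-like",
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  dz <- cohort[cohort$group == diseaseGroup, , drop = FALSE]
  if (!nrow(dz)) stop("no rows for disease group '", diseaseGroup, "'")

  strata <- cut(dz$mrc, breaks = c(0, 1, 2, Inf),
                labels = c("MRC1", "MRC2", "MRC3+"))
  contrasts <- list(c("MRC1", "MRC2"), c("MRC2", "MRC3+"), c("MRC1", "MRC3+"))
  rows <- list()
  for (metric in c("jac_mean", "dice")) {
    for (ct in contrasts) {
      sel <- strata %in% ct
      present <- table(droplevels(strata[sel]))
      if (length(present) < 2 || min(present) < 2) {
        message("contrast ", paste(ct, collapse = " vs "),
                " skipped: absent or too-small stratum")
        next
      }
      res <- compareGroups(dz[[metric]][sel], droplevels(strata[sel]),
                           kind = "auto")
      rows[[length(rows) + 1]] <-
        cbind(data.frame(metric = metric,
                         contrast = paste(ct, collapse = " vs ")), res)
    }
  }
  mrcContrasts <- if (length(rows)) do.call(rbind, rows) else
    data.frame()

  cors <- list()
  for (metric in c("jac_mean", "dice")) {
    for (colname in names(.CLINICAL_COLUMNS)) {
      if (!colname %in% names(dz)) next
      sc <- try(spearmanCor(dz[[metric]], dz[[colname]]), silent = TRUE)
      if (inherits(sc, "try-error")) next
      cors[[length(cors) + 1]] <-
        cbind(data.frame(metric = metric, variable = colname,
                         expected_sign = -.CLINICAL_COLUMNS[[colname]]), sc)
    }
  }
  correlations <- do.call(rbind, cors)
  if (adjust == "BH" && nrow(correlations)) {
    correlations$p_adj <- stats::p.adjust(correlations$p, method = "BH")
    correlations$adjust <- "BH"
  }
  list(mrcContrasts = mrcContrasts, correlations = correlations,
       adjust = adjust)
}
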