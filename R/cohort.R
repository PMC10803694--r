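#' @include phantom.R clinical-stats.R
NULL

# Column design for the synthetic clinical table: a strictly monotone mean
# trajectory over severity s in [0,1] plus additive Gaussian noise whose
# scale is set per column so that, at the default noise level, the rank
# correlation with severity equals the designed value.  Directions mirror
# the clinical expectations: lung function and walking distance fall with
# severity, symptom scores, fibrosis extent and vessel tortuosity rise.
.COLUMN_DESIGN <- list(
  fvc_pct        = list(f = function(s) 106 - 42 * s, rho = -0.70),
  fev1_pct       = list(f = function(s) 101 - 30 * s, rho = -0.60),
  fev1_fvc_pct   = list(f = function(s) 81.5 + 0 * s,  rho = 0.00),
  tlc_pct        = list(f = function(s) 100 - 46 * s, rho = -0.65),
  dlco_pct       = list(f = function(s) 103 - 70 * s, rho = -0.75),
  sgrq_symptoms  = list(f = function(s) 100 * stats::plogis(-2.4 + 4.8 * s),
                        rho = 0.60),
  sgrq_activity  = list(f = function(s) 100 * stats::plogis(-2.7 + 4.9 * s),
                        rho = 0.60),
  sgrq_impact    = list(f = function(s) 100 * stats::plogis(-3.3 + 4.6 * s),
                        rho = 0.55),
  mwd6           = list(f = function(s) 630 - 280 * s, rho = -0.60),
  fibrosis_pct   = list(f = function(s) 40 * stats::plogis(-3.2 + 5.2 * s),
                        rho = 0.55),
  tpv_volume     = list(f = function(s) 205 - 40 * s,  rho = -0.30),
  tpv_number     = list(f = function(s) 2750 - 1300 * s, rho = -0.55),
  tpv_tortuosity = list(f = function(s) 1.065 + 0.075 * s, rho = 0.45),
  pvv_number     = list(f = function(s) 1340 - 480 * s, rho = -0.40),
  pvv_tortuosity = list(f = function(s) 1.065 + 0.060 * s, rho = 0.35),
  pav_volume     = list(f = function(s) 103 - 17 * s,  rho = -0.35),
  pav_number     = list(f = function(s) 1360 - 620 * s, rho = -0.50),
  pav_tortuosity = list(f = function(s) 1.060 + 0.065 * s, rho = 0.45))

# Noise sd giving (approximately) Pearson rho between f(s) and the noisy
# column when noiseSd = 1: sd = sd(f) * sqrt(1/rho^2 - 1).  rho is signed:
# its sign is the designed direction of the rank correlation with severity.
.columnValues <- function(s, design, noiseSd) {
  f <- design$f(s)
  rho <- abs(design$rho)
  sdf <- stats::sd(f)
  sigma <- if (rho == 0 || sdf == 0) max(sdf, 1) * 2
           else sdf * sqrt(1 / rho^2 - 1)
  f + noiseSd * sigma * stats::rnorm(length(s))
}

# Severity -> deformation model.  Compliance beta and amplitude fall with
# severity; mild anatomical jitter (scaled by the cohort noise level)
# differentiates subjects.
.severityModel <- function(s, seed, jitterScale = 1) {
  set.seed(seed)
  jf <- function(sd) jitterScale * stats::rnorm(1, 0, sd)
  DeformationModel(
    affineScale = c(1.10, 1.10, 1.22) * (1 + jf(0.008)),
    lungRadii = c(42, 38, 48) * (1 + jitterScale * stats::rnorm(3, 0, 0.02)),
    amplitude = max(0.05, 0.22 * (1 - 0.30 * s) + jf(0.006)),
    peripheralAttenuation = min(1, max(0.02, 1 - 0.85 * s + jf(0.015))),
    shellFraction = 0.7,
    seed = seed)
}

#' Generate a synthetic breathing-lung cohort
#'
#' Controls draw a small severity (near-compliant lungs); disease-like
#' subjects draw severity from \code{severityRange}, which lowers the
#' peripheral compliance factor beta and the contraction amplitude of their
#' \linkS4class{DeformationModel} and shifts every clinical column along its
#' designed monotone trajectory.  With \code{noiseSd = 0} all designed
#' monotonicities are exact; the generator parameters (including each
#' column's designed rank correlation with severity) are recorded in the
#' \code{generator} attribute so the designed correlation structure is
#' recoverable.  Fully reproducible from \code{seed}.
#'
#' @param nControl,nIpf group sizes (>= 2 each).
#' @param severityRange range of disease severity in (0, 1].
#' @param noiseSd clinical noise multiplier (1 = designed calibration,
#'   0 = noise-free).
#' @param seed integer master seed.
#' @param gridShape,spacing phantom grid (see \code{\link{makePhantom}}).
#' @param withImages generate intensity volumes (FALSE = masks/landmarks
#'   only, the fast path for oracle-registration studies).
#' @param withSubjects generate phantom subjects at all (FALSE = clinical
#'   table only, for statistical studies that do not touch images).
#' @param imageNoiseSd acquisition noise passed to \code{\link{makePhantom}}.
#' @return list of class \code{ldCohort}: \code{subjects} (list of
#'   \linkS4class{SyntheticSubject}) and \code{table} (clinical data.frame
#'   with a \code{generator} attribute).
#' @export
makeCohort <- function(nControl = 15, nIpf = 15, severityRange = c(0.3, 0.95),
                       noiseSd = 1, seed = 1L, gridShape = c(64, 64, 64),
                       spacing = 2, withImages = TRUE, imageNoiseSd = 0,
                       withSubjects = TRUE) {
  stopifnot(nControl >= 2, nIpf >= 2)
  if (length(severityRange) != 2L || diff(severityRange) < 0 ||
      severityRange[2] > 1 || severityRange[1] < 0)
    stop("severityRange must be an increasing range within [0, 1]")
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs))
  set.seed(seed)

  n <- nControl + nIpf
  group <- rep(c("control", "IPF-like"), c(nControl, nIpf))
  sev <- c(stats::runif(nControl, 0, 0.12),
           stats::runif(nIpf, severityRange[1], severityRange[2]))
  subjSeeds <- sample.int(.Machine$integer.max %/% 2, n)
  ids <- sprintf("sub-%03d", seq_len(n))

  age <- round(ifelse(group == "control", stats::rnorm(n, 58, 4),
                      stats::rnorm(n, 62, 6)))
  sex <- ifelse(stats::runif(n) < 0.94, "M", "F")

  tab <- data.frame(subject_id = ids, group = group, severity = sev,
                    age = age, sex = sex, stringsAsFactors = FALSE)
  for (colname in names(.COLUMN_DESIGN))
    tab[[colname]] <- .columnValues(sev, .COLUMN_DESIGN[[colname]], noiseSd)

  # keep physical ranges without breaking noise-free monotonicity
  pctCols <- c("fvc_pct", "fev1_pct", "fev1_fvc_pct", "tlc_pct", "dlco_pct",
               "fibrosis_pct")
  for (colname in pctCols) tab[[colname]] <- pmax(tab[[colname]], 0)
  for (colname in grep("^sgrq", names(tab), value = TRUE))
    tab[[colname]] <- pmin(pmax(tab[[colname]], 0), 100)
  tab$mwd6 <- pmax(tab$mwd6, 50)
  tab$sgrq_total <- (tab$sgrq_symptoms + tab$sgrq_activity +
                       tab$sgrq_impact) / 3
  tab$cpi <- computeCpi(tab$fvc_pct, tab$fev1_pct, tab$dlco_pct)

  # dyspnea grade: monotone binning of severity with mild noise
  mrcScore <- sev + noiseSd * 0.06 * stats::rnorm(n)
  tab$mrc <- as.integer(cut(pmin(pmax(mrcScore, 0), 1),
                            breaks = c(-Inf, 0.42, 0.62, 0.80, 0.92, Inf)))
  tab$mrc[tab$group == "control"] <- 1L

  subjects <- list()
  if (withSubjects) {
    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      model <- .severityModel(sev[i], subjSeeds[i],
                              jitterScale = min(1, noiseSd))
      subjects[[i]] <- makePhantom(model, gridShape = gridShape,
                                   spacing = spacing, withImages = withImages,
                                   imageNoiseSd = imageNoiseSd,
                                   subjectId = ids[i], group = group[i])
      subjects[[i]]@record <- tab[i, , drop = FALSE]
    }
  }

  attr(tab, "generator") <- list(
    seed = seed, nControl = nControl, nIpf = nIpf,
    severityRange = severityRange, noiseSd = noiseSd,
    designedRho = vapply(.COLUMN_DESIGN, function(d) d$rho, numeric(1)),
    columnModel = "monotone trajectory of severity + additive Gaussian noise")
  structure(list(subjects = subjects, table = tab), class = "ldCohort")
}

#' @export
print.ldCohort <- function(x, ...) {
  cat("Synthetic cohort:", sum(x$table$group == "control"), "controls,",
      sum(x$table$group != "control"), "disease-like subjects,",
      ncol(x$table), "clinical columns\n")
  invisible(x)
}
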