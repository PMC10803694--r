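#' @include cohort.R
NULL

#' Pipeline configuration
#'
#' Every field is serialised into the run manifest; unknown keys are
#' rejected.  The default follows the reference workflow: 1 mm isotropic
#' resampling, a 10 mm peri-lung dilation, deformable registration of
#' inspiration to expiration, Jacobian analysis, common-space mapping to the
#' first control subject, and the 0.15 shrinkage cutoff.
#'
#' @param spacing isotropic working spacing in mm (NULL = keep native grid).
#' @param dilationMm peri-lung dilation radius in mm (converted to a voxel
#'   ball at the working spacing).
#' @param backend registration backend: "builtin" or "oracle" (the oracle
#'   uses each synthetic subject's ground-truth field).
#' @param registration \code{\link{registrationConfig}} for the builtin
#'   backend.
#' @param useAnalyticMasks use the generator's analytic lung masks instead of
#'   threshold segmentation (default TRUE for the oracle backend, which may
#'   run without intensity volumes).
#' @param commonSubject id of the common-space subject (NULL = the
#'   lexicographically first control; recorded in the manifest).
#' @param cutoff,cutoffRule marked-deformation threshold and sign rule (see
#'   \code{\link{markedDeformationMask}}).
#' @param minCoverage minimum per-voxel contributor count of the control
#'   average (NULL = half the controls).
#' @param meanOfAbs Jac-mean variant flag (see \code{\link{jacMean}}).
#' @param computeQC compute the per-subject registration QC metrics (IoU,
#'   DA/DB); switching this off speeds up large oracle-backend simulation
#'   studies where QC of an exact field is uninformative.
#' @param writeVolumes also write NIfTI volumes/fields/maps to outDir.
#' @param resume reuse cached per-subject intermediates in outDir if present.
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return list of class \code{ldConfig}.
#' @export
pipelineConfig <- function(spacing = 1, dilationMm = 10,
                           backend = c("builtin", "oracle"),
                           registration = registrationConfig(),
                           useAnalyticMasks = NULL,
                           commonSubject = NULL,
                           cutoff = 0.15,
                           cutoffRule = c("shrinkage", "literal"),
                           minCoverage = NULL, meanOfAbs = FALSE,
                           computeQC = TRUE,
                           writeVolumes = FALSE, resume = FALSE, seed = 1L) {
  backend <- match.arg(backend)
  cutoffRule <- match.arg(cutoffRule)
  if (is.null(useAnalyticMasks)) useAnalyticMasks <- backend == "oracle"
  structure(list(spacing = spacing, dilationMm = dilationMm,
                 backend = backend, registration = registration,
                 useAnalyticMasks = useAnalyticMasks,
                 commonSubject = commonSubject, cutoff = cutoff,
                 cutoffRule = cutoffRule, minCoverage = minCoverage,
                 meanOfAbs = meanOfAbs, computeQC = computeQC,
                 writeVolumes = writeVolumes,
                 resume = resume, seed = as.integer(seed)),
            class = "ldConfig")
}

# Preprocess + register + Jacobian-stage one subject; returns the per-subject
# intermediates used by the common-space stages.
.processSubject <- function(subject, config) {
  native <- voxelSpacing(subject@lungMaskExp)
  resamp <- !is.null(config$spacing) &&
    any(abs(native - config$spacing) > 1e-9)

  expi <- insp <- NULL
  if (!config$useAnalyticMasks || config$backend == "builtin") {
    if (is.null(subject@expiration))
      stop("subject ", subject@subjectId, " has no intensity volumes; ",
           "segmentation and the builtin backend require them")
    expi <- subject@expiration; insp <- subject@inspiration
    if (resamp) {
      expi <- resampleIsotropic(expi, config$spacing)
      insp <- resampleIsotropic(insp, config$spacing)
    }
  }
  if (config$useAnalyticMasks) {
    maskExp <- subject@lungMaskExp
    maskInsp <- subject@lungMaskInsp
    if (resamp) {
      maskExp <- resampleIsotropic(maskExp, config$spacing)
      maskInsp <- resampleIsotropic(maskInsp, config$spacing)
    }
  } else {
    maskExp <- segmentLungs(expi)
    maskInsp <- segmentLungs(insp)
  }
  sp <- voxelSpacing(maskExp)[1]
  roi <- dilateMask(maskExp, max(1L, round(config$dilationMm / sp)))

  if (config$backend == "oracle") {
    field <- .modelField(subject@model, maskExp, roi)
    reg <- new("RegistrationResult", displacement = field,
               backend = "oracle", metrics = list(), converged = TRUE)
  } else {
    reg <- registerElastic(expi, insp, roi, config = config$registration,
                           backend = "builtin")
  }

  jac <- jacobianMap(reg@displacement, mask = maskExp,
                     subjectId = subject@subjectId)
  jacnl <- logJac(normalizeJac(jac, lungVolume(maskInsp),
                               lungVolume(maskExp)))
  qc <- if (isFALSE(config$computeQC))
    c(iou = NA_real_, da_mm = NA_real_, db_mm = NA_real_)
  else tryCatch(.subjectQC(subject, reg, maskInsp, maskExp),
                error = function(e) c(iou = NA_real_, da_mm = NA_real_,
                                      db_mm = NA_real_))
  list(subjectId = subject@subjectId, group = subject@group,
       maskExp = maskExp, jacnl = jacnl, qc = qc,
       converged = reg@converged,
       clipped = jac@provenance$clippedVoxels)
}

#' Run the full deformation-analysis pipeline on a cohort
#'
#' Executes, per subject, preprocessing (isotropic resampling, lung masks,
#' peri-lung ROI), inspiration-to-expiration registration, the staged
#' Jacobian analysis (JAC, JAC-N, JAC-NL), then maps every subject into the
#' common space of a control subject, builds the healthy deformation template
#' from the controls, and derives per-subject Jac-mean and Dice, the
#' registration QC metrics, and the clinical severity statistics.  A failing
#' subject is recorded and skipped; the remaining cohort continues.
#'
#' @param cohort an \code{ldCohort} (from \code{\link{makeCohort}} or
#'   \code{\link{readCohort}}).
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional output directory for the derived TSVs, the run
#'   manifest, and (if configured) NIfTI volumes.
#' @return list of class \code{ldPipelineResult}: the augmented cohort
#'   \code{table}, \code{template}, \code{haj}, \code{iaj}, \code{maps}
#'   (per-subject JAC-NLC), \code{qc}, \code{stats}, \code{failures} and
#'   \code{manifest}.
#' @export
runPipeline <- function(cohort, config = pipelineConfig(), outDir = NULL) {
  stopifnot(inherits(cohort, "ldCohort"))
  subjects <- cohort$subjects
  tab <- cohort$table

  cacheDir <- if (!is.null(outDir) && config$resume)
    file.path(outDir, "cache") else NULL
  if (!is.null(cacheDir)) dir.create(cacheDir, recursive = TRUE,
                                     showWarnings = FALSE)

  failures <- character(0)
  proc <- vector("list", length(subjects))
  names(proc) <- vapply(subjects, function(s) s@subjectId, character(1))
  for (i in seq_along(subjects)) {
    sid <- subjects[[i]]@subjectId
    cf <- if (!is.null(cacheDir)) file.path(cacheDir, paste0(sid, ".rds"))
    if (!is.null(cacheDir) && file.exists(cf)) {
      proc[[i]] <- readRDS(cf)
      next
    }
    val <- tryCatch(.processSubject(subjects[[i]], config),
                    error = function(e) {
                      message("subject ", sid, " failed: ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(val)) {
      failures <- c(failures, sid)
      proc[i] <- list(NULL)   # keep the slot so names stay aligned
    } else {
      proc[[i]] <- val
      if (!is.null(cacheDir)) saveRDS(val, cf)
    }
  }
  ok <- !vapply(proc, is.null, logical(1))
  proc <- proc[ok]
  if (!length(proc)) stop("every subject failed")

  groups <- vapply(proc, `[[`, character(1), "group")
  controls <- names(proc)[groups == "control"]
  if (!length(controls)) stop("no control subjects: cannot define the ",
                              "common space or the healthy template")
  commonId <- if (is.null(config$commonSubject)) sort(controls)[1]
              else config$commonSubject
  commonMask <- proc[[commonId]]$maskExp

  maps <- list()
  for (sid in names(proc)) {
    aff <- if (sid == commonId) AffineTransform() else
      registerAffine(commonMask, proc[[sid]]$maskExp)
    maps[[sid]] <- toCommonSpace(proc[[sid]]$jacnl, aff, commonMask)
  }

  nCov <- if (is.null(config$minCoverage))
    max(1L, ceiling(length(controls) / 2)) else config$minCoverage
  haj <- groupAverage(maps[controls], group = "control", minCoverage = nCov)
  dzIds <- names(proc)[groups != "control"]
  iaj <- if (length(dzIds))
    groupAverage(maps[dzIds], group = "IPF-like", minCoverage = 1L) else NULL
  template <- healthyTemplate(haj, cutoff = config$cutoff,
                              rule = config$cutoffRule)

  res <- data.frame(subject_id = names(proc),
                    jac_mean = NA_real_, dice = NA_real_,
                    tp = NA_integer_, fn = NA_integer_, fp = NA_integer_,
                    iou = NA_real_, da_mm = NA_real_, db_mm = NA_real_,
                    converged = NA, clipped_voxels = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(proc)) {
    sid <- names(proc)[i]
    jm <- jacMean(maps[[sid]], mask = commonMask,
                  meanOfAbs = config$meanOfAbs)
    marked <- markedDeformationMask(maps[[sid]], cutoff = config$cutoff,
                                    rule = config$cutoffRule)
    db <- diceToTemplate(marked, template)
    res[i, c("jac_mean", "dice")] <- c(jm, db@dice)
    res[i, c("tp", "fn", "fp")] <- c(db@tp, db@fn, db@fp)
    res[i, c("iou", "da_mm", "db_mm")] <- proc[[i]]$qc
    res$converged[i] <- proc[[i]]$converged
    res$clipped_voxels[i] <- proc[[i]]$clipped
  }

  tab2 <- merge(tab, res, by = "subject_id", all.x = TRUE, sort = TRUE)
  tab2 <- tab2[order(tab2$subject_id), , drop = FALSE]
  rownames(tab2) <- NULL

  stats <- tryCatch(severityAnalysis(tab2), error = function(e) NULL)

  manifest <- list(
    package = "lungdeform",
    version = as.character(utils::packageVersion("lungdeform")),
    config = .serializableConfig(config),
    commonSubject = commonId,
    nSubjects = length(proc), failures = failures,
    warnings = list(
      nonConverged = names(proc)[!vapply(proc, `[[`, logical(1),
                                         "converged")],
      clippedVoxels = sum(res$clipped_voxels, na.rm = TRUE)),
    templateVoxels = sum(imageData(template)))

  out <- list(table = tab2, template = template, haj = haj, iaj = iaj,
              maps = maps, commonMask = commonMask,
              stats = stats, failures = failures, manifest = manifest,
              config = config)
  class(out) <- "ldPipelineResult"
  if (!is.null(outDir)) .writePipelineOutputs(out, outDir)
  if (length(failures))
    warning("pipeline finished with failed subject(s): ",
            paste(failures, collapse = ", "))
  out
}

.serializableConfig <- function(config) {
  cfg <- unclass(config)
  cfg$registration <- unclass(cfg$registration)
  cfg
}

# Derived TSV/JSON outputs; every written file is hashed into the manifest.
.writePipelineOutputs <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    path <- file.path(outDir, name)
    utils::write.table(format(df, digits = 10, trim = TRUE), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  files <- c(tsv(result$table, "cohort.tsv"))
  if (!is.null(result$stats)) {
    if (nrow(result$stats$mrcContrasts))
      files <- c(files, tsv(result$stats$mrcContrasts, "mrc_contrasts.tsv"))
    if (!is.null(result$stats$correlations))
      files <- c(files, tsv(result$stats$correlations, "correlations.tsv"))
  }
  if (isTRUE(result$config$writeVolumes)) {
    writeImageVolume(result$template, file.path(outDir, "template.nii.gz"))
    hajVol <- ImageVolume(result$haj@values, result$haj@spacing,
                          result$haj@origin)
    writeImageVolume(hajVol, file.path(outDir, "haj.nii.gz"))
    files <- c(files, file.path(outDir, c("template.nii.gz", "haj.nii.gz")))
  }
  manifest <- result$manifest
  manifest$files <- lapply(files, function(f)
    list(path = basename(f), md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}

#' @export
print.ldPipelineResult <- function(x, ...) {
  cat("Pipeline result:", nrow(x$table), "subjects | template",
      sum(imageData(x$template)), "voxels | common subject",
      x$manifest$commonSubject, "\n")
  jm <- stats::aggregate(jac_mean ~ group, data = x$table, FUN = mean)
  for (i in seq_len(nrow(jm)))
    cat(sprintf("  %-10s mean Jac-mean %.4f\n", jm$group[i], jm$jac_mean[i]))
  invisible(x)
}
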