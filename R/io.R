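#' @include pipeline.R
NULL

#' Write a volume to NIfTI
#'
#' Spacing and origin are stored in the sform (diagonal direction matrix).
#'
#' @param image \linkS4class{ImageVolume} or \linkS4class{BinaryMask}.
#' @param path output path (.nii or .nii.gz).
#' @export
writeImageVolume <- function(image, path) {
  sp <- voxelSpacing(image); o <- gridOrigin(image)
  xf <- rbind(cbind(diag(sp), o), c(0, 0, 0, 1))
  nii <- RNifti::asNifti(imageData(image), reference = NULL)
  nii <- RNifti::`sform<-`(nii, structure(xf, code = 2L))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file.
#' @param mask read as a \linkS4class{BinaryMask} (values binarised at 0.5)?
#' @return \linkS4class{ImageVolume} or \linkS4class{BinaryMask}.
#' @export
readImageVolume <- function(path, mask = FALSE) {
  nii <- RNifti::readNifti(path)
  xf <- RNifti::xform(nii)
  sp <- sqrt(colSums(xf[1:3, 1:3]^2))
  o <- xf[1:3, 4]
  arr <- array(as.numeric(nii), dim(nii)[1:3])
  if (mask) BinaryMask(array(as.numeric(arr >= 0.5), dim(arr)), sp, o)
  else ImageVolume(arr, sp, o)
}

#' Write a displacement field as 4D NIfTI (3 vector components, mm)
#' @param field a \linkS4class{DisplacementField}.
#' @param path output path.
#' @export
writeDisplacementField <- function(field, path) {
  sp <- voxelSpacing(field); o <- gridOrigin(field)
  xf <- rbind(cbind(diag(sp), o), c(0, 0, 0, 1))
  nii <- RNifti::asNifti(field@vectors, reference = NULL)
  nii <- RNifti::`sform<-`(nii, structure(xf, code = 2L))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

# model <-> plain list (for the JSON manifest)
.modelToList <- function(m) {
  list(affineScale = m@affineScale, center = m@center,
       lungRadii = m@lungRadii, amplitude = m@amplitude,
       peripheralAttenuation = m@peripheralAttenuation,
       shellFraction = m@shellFraction, seed = m@seed)
}
.modelFromList <- function(l) {
  DeformationModel(affineScale = unlist(l$affineScale),
                   center = unlist(l$center),
                   lungRadii = unlist(l$lungRadii),
                   amplitude = l$amplitude,
                   peripheralAttenuation = l$peripheralAttenuation,
                   shellFraction = l$shellFraction, seed = l$seed)
}

.landmarkTable <- function(lm, subject, phase) {
  data.frame(subject = subject, phase = phase, category = lm@category,
             side = lm@side, x_mm = lm@points[, 1], y_mm = lm@points[, 2],
             z_mm = lm@points[, 3], stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to a directory
#'
#' Layout: per-subject NIfTI volumes and masks
#' (\code{sub-XXX_phase-\{insp,exp\}_\{img,mask\}.nii.gz}), a landmark TSV, the
#' clinical cohort TSV, and a JSON manifest holding every generator
#' parameter (including each subject's deformation model, so a reloaded
#' cohort still supports the oracle backend).
#'
#' @param cohort an \code{ldCohort}.
#' @param dir output directory.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ldCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lms <- list()
  models <- list()
  for (s in cohort$subjects) {
    base <- file.path(dir, s@subjectId)
    if (!is.null(s@expiration)) {
      writeImageVolume(s@inspiration, paste0(base, "_phase-insp_img.nii.gz"))
      writeImageVolume(s@expiration, paste0(base, "_phase-exp_img.nii.gz"))
    }
    writeImageVolume(s@lungMaskInsp, paste0(base, "_phase-insp_mask.nii.gz"))
    writeImageVolume(s@lungMaskExp, paste0(base, "_phase-exp_mask.nii.gz"))
    lms[[length(lms) + 1]] <- rbind(
      .landmarkTable(s@landmarksInsp, s@subjectId, "insp"),
      .landmarkTable(s@landmarksExp, s@subjectId, "exp"))
    models[[s@subjectId]] <- c(.modelToList(s@model), list(group = s@group))
  }
  utils::write.table(do.call(rbind, lms), file.path(dir, "landmarks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$table, file.path(dir, "cohort.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(generator = attr(cohort$table, "generator"),
                            models = models),
                       file.path(dir, "generator.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by \code{\link{writeCohort}}
#'
#' @param dir cohort directory.
#' @return an \code{ldCohort}.
#' @export
readCohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "generator.json"))
  tab <- utils::read.delim(file.path(dir, "cohort.tsv"),
                           stringsAsFactors = FALSE)
  lms <- utils::read.delim(file.path(dir, "landmarks.tsv"),
                           stringsAsFactors = FALSE)
  attr(tab, "generator") <- man$generator
  subjects <- list()
  for (sid in names(man$models)) {
    ml <- man$models[[sid]]
    model <- .modelFromList(ml)
    base <- file.path(dir, sid)
    hasImg <- file.exists(paste0(base, "_phase-exp_img.nii.gz"))
    getLm <- function(phase) {
      sel <- lms$subject == sid & lms$phase == phase
      LandmarkSet(as.matrix(lms[sel, c("x_mm", "y_mm", "z_mm")]),
                  lms$category[sel], lms$side[sel], phase)
    }
    subjects[[length(subjects) + 1]] <- new("SyntheticSubject",
      subjectId = sid, group = ml$group, model = model,
      inspiration = if (hasImg)
        readImageVolume(paste0(base, "_phase-insp_img.nii.gz")) else NULL,
      expiration = if (hasImg)
        readImageVolume(paste0(base, "_phase-exp_img.nii.gz")) else NULL,
      lungMaskInsp = readImageVolume(paste0(base, "_phase-insp_mask.nii.gz"),
                                     mask = TRUE),
      lungMaskExp = readImageVolume(paste0(base, "_phase-exp_mask.nii.gz"),
                                    mask = TRUE),
      landmarksInsp = getLm("insp"), landmarksExp = getLm("exp"),
      record = tab[tab$subject_id == sid, , drop = FALSE])
  }
  structure(list(subjects = subjects, table = tab), class = "ldCohort")
}
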