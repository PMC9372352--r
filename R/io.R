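# NIfTI-based study I/O.  A study on disk is a directory of .nii.gz volumes
# (t1, t2, flair, brain_mask, ventricle_mask, truth) plus a JSON sidecar
# with the generating spec/seed.  All volumes of a study must share one
# geometry; registration is out of scope, so a mismatch is a hard error.

STUDY_FILES <- c(t1 = "t1.nii.gz", t2 = "t2.nii.gz", flair = "flair.nii.gz",
                 brain_mask = "brain_mask.nii.gz",
                 ventricle_mask = "ventricle_mask.nii.gz",
                 junction_mask = "junction_mask.nii.gz",
                 truth = "truth.nii.gz")

write_volume <- function(arr, spacing, path) {
  img <- RNifti::asNifti(arr * 1,
                         reference = list(pixdim = c(1, spacing, 1, 1, 1,
                                                     1)))
  aff <- diag(c(spacing, 1))
  RNifti::qform(img) <- structure(aff, code = 2L)   # scanner-anatomical
  RNifti::writeNifti(img, path)
}

#' Write a study to a directory of NIfTI files
#'
#' @param study a `wmh_study`.
#' @param dir output directory (created if needed); one `.nii.gz` per
#'   volume plus `study.json` recording spacing, ICV and the phantom spec.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(STUDY_FILES)) {
    if (is.null(study[[nm]])) next
    write_volume(study[[nm]], study$spacing, file.path(dir, STUDY_FILES[nm]))
  }
  sidecar <- list(spacing = study$spacing, icv_mm3 = study$icv_mm3,
                  preprocessed = isTRUE(study$preprocessed))
  if (!is.null(study$spec)) sidecar$spec <- unclass(study$spec)
  jsonlite::write_json(sidecar, file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  # canonicalize non-standard orientations so arrays align voxel-for-voxel
  if (!identical(RNifti::orientation(img), "RAS"))
    RNifti::orientation(img) <- "RAS"
  spacing <- RNifti::pixdim(img)[1:3]
  list(data = array(as.vector(img), dim(img)), spacing = spacing)
}

#' Read a study from a directory (or explicit manifest) of NIfTI files
#'
#' Volumes are reoriented to a canonical (RAS) axis order, then checked for
#' identical shape and spacing; any mismatch is reported with the offending
#' file, since co-registration is a precondition, not a service.
#'
#' @param manifest a directory containing the standard file names, or a
#'   named list/vector of paths (names as in the `t1`, `t2`, `flair`,
#'   `brain_mask`, `ventricle_mask`, `truth` convention).
#' @param tol relative tolerance for spacing agreement.
#' @return a `wmh_study`.
#' @export
read_study <- function(manifest, tol = 1e-4) {
  if (is.character(manifest) && length(manifest) == 1L &&
      dir.exists(manifest)) {
    paths <- file.path(manifest, STUDY_FILES)
    names(paths) <- names(STUDY_FILES)
    paths <- paths[file.exists(paths)]
    sidecar_path <- file.path(manifest, "study.json")
  } else {
    paths <- unlist(manifest)
    sidecar_path <- ""
  }
  if (!any(c("flair") %in% names(paths)))
    stop("a study needs at least a FLAIR volume")
  vols <- lapply(paths, read_volume)
  ref <- vols[[1]]
  for (nm in names(vols)) {
    v <- vols[[nm]]
    if (!identical(dim(v$data), dim(ref$data)))
      stop(sprintf("geometry mismatch in %s: %s vs %s (register first)",
                   paths[nm], paste(dim(v$data), collapse = "x"),
                   paste(dim(ref$data), collapse = "x")))
    if (any(abs(v$spacing - ref$spacing) > tol * ref$spacing))
      stop(sprintf("spacing mismatch in %s", paths[nm]))
  }
  study <- list(spacing = as.numeric(ref$spacing))
  for (nm in names(vols)) {
    a <- vols[[nm]]$data
    study[[nm]] <- switch(nm,
      truth = array(as.integer(round(a)), dim(a)),
      brain_mask = , ventricle_mask = , junction_mask = a > 0.5,
      a)
  }
  if (file.exists(sidecar_path)) {
    side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    study$icv_mm3 <- side$icv_mm3
    study$preprocessed <- isTRUE(side$preprocessed)
  }
  if (is.null(study$icv_mm3) && !is.null(study$brain_mask))
    study$icv_mm3 <- sum(study$brain_mask) * voxel_volume_mm3(study$spacing)
  class(study) <- "wmh_study"
  study
}
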