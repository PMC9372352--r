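# WMH subclassification by distance from the ventricles (and, for the
# 4-class scheme, from the corticomedullary junction).
#
# Class codes: 0 none, 1 juxtaventricular (JVWMH), 2 periventricular
# (PWMH), 3 deep (DWMH), 4 juxtacortical (JCWMH).

SUBCLASS_CODES <- c(JVWMH = 1L, PWMH = 2L, DWMH = 3L, JCWMH = 4L)

#' Distance map from a reference structure
#'
#' Voxels inside the reference have distance 0; every other voxel gets its
#' exact Euclidean distance (in mm, anisotropic spacing respected) to the
#' nearest reference voxel.
#'
#' @param reference_mask logical volume (e.g. the ventricle mask).
#' @param spacing voxel spacing `c(x, y, z)` in mm.
#' @param brain_mask optional; distances outside the brain are set to NA
#'   since only brain voxels are classified.
#' @return numeric distance volume in mm.
#' @export
distance_map <- function(reference_mask, spacing, brain_mask = NULL) {
  if (!any(reference_mask)) stop("reference mask is empty")
  d <- edt_mm(reference_mask, spacing)
  if (!is.null(brain_mask)) d[!as.logical(brain_mask)] <- NA_real_
  d
}

#' Four-class WMH subclassification (juxtaventricular / periventricular /
#' deep / juxtacortical)
#'
#' Each WMH voxel is assigned by ventricle distance first: within 3 mm of
#' the ventricle it is juxtaventricular, from 3 to 13 mm periventricular.
#' Beyond 13 mm, voxels within 4 mm of the corticomedullary junction are
#' juxtacortical and the remainder deep.  All interval edges are inclusive
#' on the far side ("within N mm" reads as `<= N`).
#'
#' @param wmh_mask logical WMH volume.
#' @param ventricle_dist distance map from the ventricles (mm).
#' @param cortex_dist distance map from the corticomedullary junction (mm).
#' @return a `subclass_map` integer volume (codes above, 0 off the WMH) with
#'   attribute `scheme = "kim4"`.
#' @export
classify_kim4 <- function(wmh_mask, ventricle_dist, cortex_dist) {
  assert_same_geometry(wmh_mask, ventricle_dist, "WMH and ventricle distance")
  assert_same_geometry(wmh_mask, cortex_dist, "WMH and cortex distance")
  out <- array(0L, dim(wmh_mask))
  m <- as.logical(wmh_mask)
  vd <- ventricle_dist; cd <- cortex_dist
  out[m & vd <= 3] <- SUBCLASS_CODES[["JVWMH"]]
  out[m & vd > 3 & vd <= 13] <- SUBCLASS_CODES[["PWMH"]]
  out[m & vd > 13 & cd <= 4] <- SUBCLASS_CODES[["JCWMH"]]
  out[m & vd > 13 & cd > 4] <- SUBCLASS_CODES[["DWMH"]]
  attr(out, "scheme") <- "kim4"
  out
}

#' Two-class WMH subclassification (periventricular vs deep)
#'
#' The traditional split: WMH within 10 mm of the lateral ventricle is
#' periventricular, the rest deep.
#'
#' @inheritParams classify_kim4
#' @return a `subclass_map` integer volume using codes 2 (PWMH) and
#'   3 (DWMH), attribute `scheme = "fazekas2"`.
#' @export
classify_fazekas2 <- function(wmh_mask, ventricle_dist) {
  assert_same_geometry(wmh_mask, ventricle_dist, "WMH and ventricle distance")
  out <- array(0L, dim(wmh_mask))
  m <- as.logical(wmh_mask)
  out[m & ventricle_dist <= 10] <- SUBCLASS_CODES[["PWMH"]]
  out[m & ventricle_dist > 10] <- SUBCLASS_CODES[["DWMH"]]
  attr(out, "scheme") <- "fazekas2"
  out
}

#' Per-subclass WMH volumes, absolute and as a fraction of ICV
#'
#' @param subclass a subclass map from [classify_kim4()] or
#'   [classify_fazekas2()].
#' @param spacing voxel spacing in mm.
#' @param icv_mm3 intracranial volume in mm^3 (normalizer).
#' @return data frame with one row per subclass: `class`, `code`,
#'   `volume_mm3`, `pct_icv`; the class volumes sum exactly to the total
#'   WMH volume.
#' @export
subclass_volumes <- function(subclass, spacing, icv_mm3) {
  if (icv_mm3 <= 0) stop("intracranial volume must be positive")
  vv <- voxel_volume_mm3(spacing)
  counts <- vapply(SUBCLASS_CODES, function(cd) sum(subclass == cd),
                   numeric(1))
  data.frame(class = names(SUBCLASS_CODES),
             code = unname(SUBCLASS_CODES),
             volume_mm3 = unname(counts) * vv,
             pct_icv = unname(counts) * vv / icv_mm3 * 100,
             row.names = NULL)
}
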