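# In-package preprocessing: quantile intensity normalization, in-plane
# resampling to a common pixel spacing, and brain-mask application.  Bias
# correction, multi-modal registration and skull stripping are the business
# of external tools; this package consumes their output and asserts that all
# volumes of a study share one geometry.

#' Quantile intensity normalization to \[0, 1\]
#'
#' Intensities are sorted and the values at the 0.1% and 99.9% quantiles
#' (nearest-rank rule) are taken as `p_low` and `p_high`.  The output is 0
#' below `p_low`, 1 above `p_high`, and linearly rescaled in between, so all
#' voxels land in \[0, 1\].  When a mask is supplied the quantiles are
#' estimated over the mask region only (after skull stripping the background
#' zeros would otherwise dominate the lower quantile), but the mapping is
#' applied to the whole volume.
#'
#' @param volume numeric 3D array.
#' @param mask optional logical array restricting quantile estimation.
#' @param probs the two quantile probabilities, default `c(0.001, 0.999)`.
#' @param modality name used in error messages.
#' @return list with `volume` (normalized array) and `params`
#'   (`p_low`, `p_high`).
#' @export
quantile_normalize <- function(volume, mask = NULL,
                               probs = c(0.001, 0.999),
                               modality = "image") {
  vals <- if (is.null(mask)) as.vector(volume) else volume[as.logical(mask)]
  if (length(vals) < 2L)
    stop(sprintf("%s: need at least 2 voxels to normalize", modality))
  s <- sort(vals)
  p_low <- nearest_rank(s, probs[1])
  p_high <- nearest_rank(s, probs[2])
  if (p_low == p_high)
    stop(sprintf("%s: constant intensities within the mask; cannot normalize",
                 modality))
  out <- (volume - p_low) / (p_high - p_low)
  out[volume < p_low] <- 0
  out[volume > p_high] <- 1
  list(volume = out, params = list(p_low = p_low, p_high = p_high))
}

# 1D linear resampling weights from n_in samples at spacing s_in to spacing
# s_target, voxel centres aligned at the first sample
resample_axis <- function(n_in, s_in, s_target) {
  n_out <- max(1L, as.integer(round(n_in * s_in / s_target)))
  pos <- (seq_len(n_out) - 1) * s_target / s_in   # fractional source index
  pos <- pmin(pmax(pos, 0), n_in - 1)
  i0 <- pmin(floor(pos), n_in - 2); i0 <- pmax(i0, 0)
  frac <- pos - i0
  list(n_out = n_out, i0 = as.integer(i0) + 1L, frac = frac,
       nearest = as.integer(round(pos)) + 1L)
}

#' Resample a volume in-plane to a target pixel spacing
#'
#' The x- and y-axes are resampled to `target_xy` mm; the slice axis is left
#' untouched.  Images use (bi)linear interpolation; labels and masks must use
#' nearest-neighbour so their value set is preserved.
#'
#' @param volume numeric 3D array.
#' @param spacing current voxel spacing `c(x, y, z)` in mm.
#' @param target_xy target in-plane spacing in mm (e.g. 0.5).
#' @param interpolation `"linear"` or `"nearest"`.
#' @return list with `volume` and the new `spacing`.
#' @export
resample_xy <- function(volume, spacing, target_xy,
                        interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(length(target_xy) == 1L)
  if (target_xy <= 0) stop("target spacing must be positive")
  d <- dim(volume)
  if (spacing[1] == target_xy && spacing[2] == target_xy)
    return(list(volume = volume, spacing = spacing))
  rx <- resample_axis(d[1], spacing[1], target_xy)
  ry <- resample_axis(d[2], spacing[2], target_xy)
  if (interpolation == "nearest") {
    out <- volume[rx$nearest, ry$nearest, , drop = FALSE]
  } else {
    # along x
    v1 <- volume[rx$i0, , , drop = FALSE] * (1 - rx$frac) +
      volume[pmin(rx$i0 + 1L, d[1]), , , drop = FALSE] * rx$frac
    # along y
    fy <- rep(ry$frac, each = rx$n_out)
    out <- v1[, ry$i0, , drop = FALSE] * (1 - fy) +
      v1[, pmin(ry$i0 + 1L, d[2]), , drop = FALSE] * fy
  }
  list(volume = out, spacing = c(target_xy, target_xy, spacing[3]))
}

#' Zero out voxels outside the brain mask
#'
#' @param volume numeric 3D array.
#' @param brain_mask logical array of the same geometry.
#' @return the masked volume.
#' @export
apply_brain_mask <- function(volume, brain_mask) {
  assert_same_geometry(volume, brain_mask, "volume and brain mask")
  volume * as.numeric(brain_mask)
}

#' Preprocess a study: normalize each modality, optionally resample in-plane
#'
#' @param study a `wmh_study` (phantom or loaded from disk).
#' @param target_xy in-plane spacing in mm to resample to, or `NULL` to keep
#'   the native spacing.
#' @return the study with normalized (and possibly resampled) modalities, a
#'   `normalization` element recording the per-modality quantile parameters,
#'   and `preprocessed = TRUE`.
#' @export
preprocess_study <- function(study, target_xy = NULL) {
  params <- list()
  for (m in c("t1", "t2", "flair")) {
    qn <- quantile_normalize(study[[m]], study$brain_mask, modality = m)
    study[[m]] <- apply_brain_mask(qn$volume, study$brain_mask)
    params[[m]] <- qn$params
  }
  if (!is.null(target_xy)) {
    for (m in c("t1", "t2", "flair"))
      study[[m]] <- resample_xy(study[[m]], study$spacing, target_xy)$volume
    for (m in c("brain_mask", "ventricle_mask", "junction_mask", "truth")) {
      if (is.null(study[[m]])) next
      r <- resample_xy(study[[m]] * 1L, study$spacing, target_xy, "nearest")
      study[[m]] <- if (m == "truth") array(as.integer(r$volume), dim(r$volume))
                    else r$volume > 0
    }
    study$spacing <- c(target_xy, target_xy, study$spacing[3])
  }
  study$normalization <- params
  study$preprocessed <- TRUE
  study
}
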