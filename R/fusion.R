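# Labeling-protocol computations: histogram-threshold lesion proposal,
# fusion of two raters into a union ground truth with a definite/suspected
# partition, the distance-based loss weight map, majority voting across
# raters, and inter-observer consistency reporting.

#' Histogram-threshold lesion proposal on FLAIR
#'
#' Proposes lesion voxels as those brighter than `mean + k * SD` of the
#' within-mask FLAIR intensities, then removes connected components smaller
#' than `min_size` voxels.  This is the semi-automated starting point that
#' raters subsequently edit.
#'
#' @param flair normalized FLAIR array.
#' @param brain_mask logical array.
#' @param k threshold in within-mask standard deviations (default 2.5).
#' @param min_size minimum component size in voxels.
#' @return logical array of proposed lesion voxels.
#' @export
histogram_threshold_proposal <- function(flair, brain_mask, k = 2.5,
                                         min_size = 3L) {
  assert_same_geometry(flair, brain_mask, "FLAIR and brain mask")
  inside <- flair[as.logical(brain_mask)]
  if (length(inside) == 0L) stop("brain mask is empty")
  thr <- mean(inside) + k * sd(inside)
  prop <- flair > thr & as.logical(brain_mask)
  if (any(prop) && min_size > 1L) {
    lab <- label_components(prop)
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_size)
    if (length(drop)) prop[lab %in% drop] <- FALSE
  }
  prop
}

#' Fuse two raters' label volumes into a union ground truth
#'
#' Per class, the union of the two delineations is the ground truth.  The
#' WMH class is additionally partitioned into *definite* WMH (labeled by
#' both raters) and *suspected* WMH (labeled by exactly one); these drive
#' the training weight map.  At voxels where the raters assign different
#' lesion classes, WMH takes precedence.
#'
#' @param rater_a,rater_b integer label volumes (0/1/2).
#' @return a `fusion_result` list: `union_label`, `definite_wmh`,
#'   `suspected_wmh`.
#' @export
fuse_pair <- function(rater_a, rater_b) {
  assert_same_geometry(rater_a, rater_b, "rater volumes")
  union_label <- array(0L, dim(rater_a))
  union_label[rater_a == 2L | rater_b == 2L] <- 2L
  union_label[rater_a == 1L | rater_b == 1L] <- 1L
  definite <- rater_a == 1L & rater_b == 1L
  suspected <- xor(rater_a == 1L, rater_b == 1L)
  structure(list(union_label = union_label, definite_wmh = definite,
                 suspected_wmh = suspected),
            class = "fusion_result")
}

#' Build the per-voxel loss weight map from a fusion result
#'
#' Definite WMH voxels receive weight 2.  A suspected voxel at distance
#' `dis` (in mm) from the centre of the nearest definite WMH component
#' receives `1 + f(dis)` with `f(dis) = 1 - dis / dis_max`, where `dis_max`
#' is the largest such distance among all suspected voxels of the volume, so
#' `f` spans \[0, 1\]: suspected voxels adjoining definite WMH are weighted
#' close to 2 and the most remote suspected voxel gets weight 1.  All other
#' voxels (background and non-WMH lesions) have weight 1.  "Centre" is the
#' voxel-centroid of a definite connected component (26-connectivity), in
#' physical mm.
#'
#' @param fusion a [fuse_pair()] result.
#' @param spacing voxel spacing `c(x, y, z)` in mm.
#' @return numeric array of weights in \[1, 2\].
#' @export
build_weight_map <- function(fusion, spacing) {
  stopifnot(inherits(fusion, "fusion_result"))
  w <- array(1, dim(fusion$union_label))
  w[fusion$definite_wmh] <- 2
  susp <- which(fusion$suspected_wmh)
  if (length(susp) == 0L) return(w)
  if (!any(fusion$definite_wmh)) return(w)   # no anchor: suspected stay at 1
  lab <- label_components(fusion$definite_wmh)
  ncomp <- max(lab)
  idx <- which(lab > 0)
  pos <- arrayInd(idx, dim(lab))
  centroids <- matrix(0, ncomp, 3)
  for (a in 1:3)
    centroids[, a] <- tapply(pos[, a] * spacing[a], lab[idx], mean)
  spos <- arrayInd(susp, dim(lab))
  smm <- sweep(spos, 2, spacing, `*`)
  d2 <- matrix(Inf, length(susp), ncomp)
  for (k in seq_len(ncomp))
    d2[, k] <- (smm[, 1] - centroids[k, 1])^2 +
      (smm[, 2] - centroids[k, 2])^2 + (smm[, 3] - centroids[k, 3])^2
  dis <- sqrt(apply(d2, 1, min))
  dis_max <- max(dis)
  f <- if (dis_max > 0) 1 - dis / dis_max else rep(0, length(dis))
  w[susp] <- 1 + f
  w
}

#' Merge several raters' labels by per-voxel majority vote
#'
#' @param labels list of at least 3 integer label volumes with identical
#'   geometry.
#' @return integer label volume; at tied voxels the lowest class code wins
#'   (background-conservative).  The number of tied voxels is attached as
#'   attribute `n_ties`.
#' @export
majority_vote <- function(labels) {
  if (length(labels) < 3L) stop("majority voting needs at least 3 raters")
  for (l in labels[-1]) assert_same_geometry(labels[[1]], l, "label volumes")
  codes <- sort(unique(unlist(lapply(labels, function(l) unique(as.vector(l))))))
  votes <- vapply(codes, function(cd)
    Reduce(`+`, lapply(labels, function(l) as.integer(l == cd))),
    integer(length(labels[[1]])))
  top <- apply(votes, 1, max)
  winner <- codes[max.col(votes, ties.method = "first")]  # first = lowest code
  n_ties <- sum(rowSums(votes == top) > 1L)
  out <- array(as.integer(winner), dim(labels[[1]]))
  attr(out, "n_ties") <- n_ties
  out
}

#' Inter-observer consistency check for one subject
#'
#' Computes the Dice overlap of two raters' delineations of one class and
#' flags whether it clears the acceptance threshold used during labeling
#' (delineations with Dice below 0.5 are sent back for re-delineation).
#' Two empty masks count as perfect agreement on absence (Dice 1).
#'
#' @param rater_a,rater_b integer label volumes.
#' @param class_code which class to compare (default 1, WMH).
#' @param threshold acceptance threshold (default 0.5).
#' @return data frame with `class`, `dice`, `pass`.
#' @export
consistency_report <- function(rater_a, rater_b, class_code = 1L,
                               threshold = 0.5) {
  assert_same_geometry(rater_a, rater_b, "rater volumes")
  a <- rater_a == class_code; b <- rater_b == class_code
  dice <- if (!any(a) && !any(b)) 1 else
    2 * sum(a & b) / (sum(a) + sum(b))
  data.frame(class = class_code, dice = dice, pass = dice >= threshold)
}

#' Cohort-level inter-observer consistency
#'
#' Per-subject Dice plus the Pearson correlation of the two raters'
#' per-subject lesion volumes.
#'
#' @param raters_a,raters_b lists of label volumes, one per subject.
#' @param class_code class to compare.
#' @param spacing voxel spacing (for volumes in mm^3).
#' @param threshold Dice acceptance threshold.
#' @return list with `per_subject` (data frame) and `volume_pearson`.
#' @export
cohort_consistency <- function(raters_a, raters_b, class_code = 1L,
                               spacing = c(1, 1, 1), threshold = 0.5) {
  stopifnot(length(raters_a) == length(raters_b))
  rows <- lapply(seq_along(raters_a), function(i) {
    r <- consistency_report(raters_a[[i]], raters_b[[i]], class_code,
                            threshold)
    r$subject <- i
    r$vol_a <- sum(raters_a[[i]] == class_code) * voxel_volume_mm3(spacing)
    r$vol_b <- sum(raters_b[[i]] == class_code) * voxel_volume_mm3(spacing)
    r
  })
  per_subject <- do.call(rbind, rows)
  vp <- if (sd(per_subject$vol_a) == 0 || sd(per_subject$vol_b) == 0)
    NA_real_ else cor(per_subject$vol_a, per_subject$vol_b)
  list(per_subject = per_subject, volume_pearson = vp)
}
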