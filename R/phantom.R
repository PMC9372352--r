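# Synthetic thick-slice multi-modal brain phantoms.
#
# The phantom emulates the routine-clinic acquisition regime the package
# targets: 2D axial series of 16-20 slices with ~5 mm slice thickness and
# ~1 mm in-plane spacing, three co-registered modalities (T1w, T2w, FLAIR),
# an ellipsoidal brain with lateral-ventricle structures, WMH lesions placed
# in ventricle-distance bands, and non-WMH lesions (label 2) in
# cortical/juxtacortical positions with a PVS-like intensity signature
# (bright on FLAIR/T2 but near-CSF on T1, so modalities must be combined to
# tell the classes apart).

BAND_NAMES <- c("juxtaventricular", "periventricular", "deep", "juxtacortical")

#' Specification of a synthetic thick-slice brain study
#'
#' @param shape integer length-3, voxel counts `c(nx, ny, n_slices)`.
#' @param spacing numeric length-3 voxel spacing in mm, `c(x, y, z)`;
#'   z-spacing must be at least the in-plane spacings (thick-slice regime).
#' @param n_wmh_lesions number of WMH (label 1) lesions.
#' @param n_other_lesions number of non-WMH intracranial lesions (label 2).
#' @param wmh_distance_profile mixture weights over the placement bands
#'   (juxtaventricular, periventricular, deep, juxtacortical); must sum to 1.
#' @param noise_sigma Gaussian intensity noise, as a fraction of the \[0,1\]
#'   intensity range.
#' @param rater_disagreement fraction in \[0,1\] of lesion-boundary voxels
#'   perturbed per simulated rater.
#' @param flair_margin margin (> 0) by which the mean FLAIR intensity of WMH
#'   exceeds that of normal-appearing white matter, before noise.
#' @param seed integer seed; the whole study is a deterministic function of
#'   the spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L, 18L),
                         spacing = c(1, 1, 5),
                         n_wmh_lesions = 6L,
                         n_other_lesions = 2L,
                         wmh_distance_profile = c(0.25, 0.35, 0.25, 0.15),
                         noise_sigma = 0.05,
                         rater_disagreement = 0.3,
                         flair_margin = 0.4,
                         seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape > 0),
            length(spacing) == 3L, all(spacing > 0),
            length(wmh_distance_profile) == 4L,
            n_wmh_lesions >= 0, n_other_lesions >= 0,
            noise_sigma >= 0, flair_margin > 0)
  if (spacing[3] < max(spacing[1:2]))
    stop("thick-slice regime requires z-spacing >= in-plane spacing")
  if (abs(sum(wmh_distance_profile) - 1) > 1e-8)
    stop("wmh_distance_profile must sum to 1")
  if (rater_disagreement < 0 || rater_disagreement > 1)
    stop("rater_disagreement must lie in [0, 1]")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_wmh_lesions = as.integer(n_wmh_lesions),
                 n_other_lesions = as.integer(n_other_lesions),
                 wmh_distance_profile = wmh_distance_profile /
                   sum(wmh_distance_profile),
                 noise_sigma = noise_sigma,
                 rater_disagreement = rater_disagreement,
                 flair_margin = flair_margin,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# mm coordinate grids for voxel centres, origin at the volume centre
coord_grids <- function(shape, spacing) {
  ax <- function(n, s) (seq_len(n) - (n + 1) / 2) * s
  list(x = ax(shape[1], spacing[1]),
       y = ax(shape[2], spacing[2]),
       z = ax(shape[3], spacing[3]))
}

ellipsoid_mask <- function(g, centre, radii) {
  nx <- length(g$x); ny <- length(g$y); nz <- length(g$z)
  fx <- ((g$x - centre[1]) / radii[1])^2
  fy <- ((g$y - centre[2]) / radii[2])^2
  fz <- ((g$z - centre[3]) / radii[3])^2
  q <- outer(outer(fx, fy, `+`), fz, `+`)
  q <= 1
}

# try to grow one irregular lesion blob around a centre voxel, confined to
# `allowed`; returns a logical array or NULL if the blob came out too small
grow_blob <- function(centre_idx, allowed, shape, spacing, radius_mm,
                      two_slice = FALSE) {
  cx <- centre_idx[1]; cy <- centre_idx[2]; cz <- centre_idx[3]
  rv <- ceiling(radius_mm / spacing[1:2]) + 3L
  xs <- max(1L, cx - rv[1]):min(shape[1], cx + rv[1])
  ys <- max(1L, cy - rv[2]):min(shape[2], cy + rv[2])
  zs <- cz
  if (two_slice && cz < shape[3]) zs <- c(cz, cz + 1L)
  blob <- array(FALSE, shape)
  for (iz in seq_along(zs)) {
    r_here <- radius_mm * if (iz == 1) 1 else 0.6   # smaller on the far slice
    dx <- (xs - cx) * spacing[1]
    dy <- (ys - cy) * spacing[2]
    dist2d <- sqrt(outer(dx^2, dy^2, `+`))
    field <- matrix(runif(length(xs) * length(ys)) - 0.5,
                    length(xs), length(ys))
    field <- as.matrix(smooth_xy(array(field, c(dim(field), 1L)), 1.2)[, , 1])
    blob[xs, ys, zs[iz]] <- dist2d <= r_here + 3 * field
  }
  blob <- blob & allowed
  if (sum(blob) < 3L) return(NULL)
  # keep only the component containing (or nearest in scan order to) the seed
  lab <- label_components(blob)
  keep <- lab[cx, cy, cz]
  if (keep == 0) keep <- min(lab[lab > 0])
  blob[] <- lab == keep
  if (sum(blob) < 3L) return(NULL)
  blob
}

#' Generate a synthetic multi-modal thick-slice brain study
#'
#' Builds a deterministic phantom from a [phantom_spec()]: ellipsoidal brain,
#' two lateral-ventricle structures, a 3 mm cortical ribbon whose inner edge
#' serves as the corticomedullary junction, WMH blobs confined to the
#' requested ventricle-distance bands, and non-WMH lesions near the cortex.
#' Lesions are irregular thresholded-noise blobs rather than ellipsoids.
#'
#' @param spec a [phantom_spec()].
#' @return a `wmh_study` list: `t1`, `t2`, `flair` (intensity arrays),
#'   `brain_mask`, `ventricle_mask`, `junction_mask`, `truth` (integer label
#'   array: 0 background, 1 WMH, 2 other lesion), `spacing`, `icv_mm3`, and
#'   `lesions` (a data frame recording each lesion's band and seed voxel).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  shape <- spec$shape; spacing <- spec$spacing
  g <- coord_grids(shape, spacing)
  extent <- shape * spacing
  brain <- ellipsoid_mask(g, c(0, 0, 0), 0.45 * extent)
  vent_r <- c(0.04, 0.18, 0.22) * extent
  vent <- ellipsoid_mask(g, c(-0.09 * extent[1], 0, 0), vent_r) |
    ellipsoid_mask(g, c(0.09 * extent[1], 0, 0), vent_r)
  vent <- vent & brain

  edge_dist <- edt_mm(!brain, spacing)      # depth below the brain surface
  ribbon <- brain & edge_dist <= 3
  interior <- brain & edge_dist > 3
  junction <- interior & (edt_mm(ribbon, spacing) <= max(spacing[1:2]))
  vent_dist <- edt_mm(vent, spacing)
  junc_dist <- edt_mm(junction, spacing)
  wm <- interior & !vent & vent_dist > 0.5

  bands <- list(
    juxtaventricular = wm & vent_dist <= 3,
    periventricular  = wm & vent_dist > 3 & vent_dist <= 13,
    deep             = wm & vent_dist > 13 & junc_dist > 4,
    juxtacortical    = wm & vent_dist > 13 & junc_dist <= 4)

  truth <- array(0L, shape)
  lesions <- list()
  if (spec$n_wmh_lesions > 0) {
    counts <- as.vector(rmultinom(1, spec$n_wmh_lesions,
                                  spec$wmh_distance_profile))
    for (b in seq_along(BAND_NAMES)) {
      for (i in seq_len(counts[b])) {
        blob <- place_lesion(bands[[b]], truth, shape, spacing,
                             radius_range = c(2, 5),
                             band = BAND_NAMES[b])
        truth[blob$mask] <- 1L
        lesions[[length(lesions) + 1L]] <-
          data.frame(band = BAND_NAMES[b], label = 1L,
                     seed_x = blob$centre[1], seed_y = blob$centre[2],
                     seed_z = blob$centre[3])
      }
    }
  }
  if (spec$n_other_lesions > 0) {
    cortical_zone <- brain & !vent & edge_dist <= 8 & vent_dist > 13
    for (i in seq_len(spec$n_other_lesions)) {
      blob <- place_lesion(cortical_zone, truth, shape, spacing,
                           radius_range = c(1.5, 3), band = "cortical (other)")
      truth[blob$mask] <- 2L
      lesions[[length(lesions) + 1L]] <-
        data.frame(band = "cortical (other)", label = 2L,
                   seed_x = blob$centre[1], seed_y = blob$centre[2],
                   seed_z = blob$centre[3])
    }
  }

  # piecewise-constant tissue model, then partial-volume smoothing and noise
  wmh <- truth == 1L; other <- truth == 2L
  flair_wm <- 0.45
  means <- list(
    t1    = c(wm = 0.70, ribbon = 0.55, vent = 0.12, wmh = 0.60, other = 0.15),
    t2    = c(wm = 0.35, ribbon = 0.45, vent = 0.95, wmh = 0.75, other = 0.85),
    flair = c(wm = flair_wm, ribbon = 0.50, vent = 0.10,
              wmh = flair_wm + spec$flair_margin, other = 0.80))
  paint <- function(m) {
    v <- array(0, shape)
    v[interior] <- m[["wm"]]
    v[ribbon] <- m[["ribbon"]]
    v[vent] <- m[["vent"]]
    v[wmh] <- m[["wmh"]]
    v[other] <- m[["other"]]
    v <- smooth_xy(v, 0.6)
    v <- v + array(rnorm(prod(shape), 0, spec$noise_sigma), shape)
    v[!brain] <- 0
    pmax(v, 0)
  }
  study <- list(t1 = paint(means$t1), t2 = paint(means$t2),
                flair = paint(means$flair),
                brain_mask = brain, ventricle_mask = vent,
                junction_mask = junction, truth = truth,
                spacing = spacing,
                icv_mm3 = sum(brain) * voxel_volume_mm3(spacing),
                lesions = if (length(lesions)) do.call(rbind, lesions)
                          else data.frame(),
                spec = spec)
  class(study) <- "wmh_study"
  study
}

# choose a centre in `band_mask`, away from existing lesions, and grow a blob
place_lesion <- function(band_mask, truth, shape, spacing, radius_range,
                         band, max_tries = 60L) {
  clearance <- dilate_xy(dilate_xy(truth > 0))
  candidates <- which(band_mask & !clearance)
  if (length(candidates) == 0L)
    stop(sprintf("no room to place a lesion in the %s band", band))
  allowed <- band_mask & !clearance
  for (try in seq_len(max_tries)) {
    centre <- arrayInd(sample(candidates, 1L), shape)[1, ]
    radius <- runif(1, radius_range[1], radius_range[2])
    blob <- grow_blob(centre, allowed, shape, spacing, radius,
                      two_slice = radius > 4 && spacing[3] <= 3)
    if (!is.null(blob)) return(list(mask = blob, centre = centre))
  }
  stop(sprintf("failed to place a lesion in the %s band after %d tries",
               band, max_tries))
}

#' Simulate two raters delineating the same lesions
#'
#' Each rater receives the true label volume with its one-voxel in-plane
#' boundary shell perturbed: inner-shell voxels are independently dropped by
#' each rater with probability `rater_disagreement`, and each outer-shell
#' voxel is pre-assigned to one rater, who includes it with the same
#' probability, reproducing boundary-only disagreement while leaving lesion
#' cores intact.  With `rater_disagreement = 0` both raters reproduce the
#' truth exactly.
#'
#' @param truth integer label volume (0/1/2).
#' @param spec the [phantom_spec()] that generated it (supplies
#'   `rater_disagreement` and the seed) .
#' @param brain_mask optional logical array; rater additions are confined to
#'   the brain.
#' @return list with elements `rater_a` and `rater_b`, integer label volumes.
#' @export
simulate_raters <- function(truth, spec, brain_mask = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$rater_disagreement
  with_seed(spec$seed + 77003L, {
    a <- truth; b <- truth
    for (cls in c(1L, 2L)) {
      m <- truth == cls
      if (!any(m)) next
      inner <- m & !erode_xy(m)
      outer <- dilate_xy(m) & truth == 0L
      if (!is.null(brain_mask)) outer <- outer & brain_mask
      ii <- which(inner)
      a[ii[runif(length(ii)) < d]] <- 0L
      b[ii[runif(length(ii)) < d]] <- 0L
      oo <- which(outer)
      owner_a <- runif(length(oo)) < 0.5
      take <- runif(length(oo)) < d
      add_a <- oo[owner_a & take]; add_b <- oo[!owner_a & take]
      a[add_a[a[add_a] == 0L]] <- cls
      b[add_b[b[add_b] == 0L]] <- cls
    }
    list(rater_a = a, rater_b = b)
  })
}
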