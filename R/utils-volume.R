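# Shared volume helpers.  All volumes are plain 3D arrays indexed [x, y, z]
# with voxel spacing given separately as c(x, y, z) in mm; the third axis is
# the slice (through-plane) direction.

#' Exact Euclidean distance transform in millimetres
#'
#' Distance from every voxel to the nearest `TRUE` voxel of `mask`, computed
#' with the separable lower-envelope algorithm so anisotropic spacing (thick
#' slices) is handled exactly.
#'
#' @param mask logical or 0/1 3D array.
#' @param spacing numeric length-3 voxel spacing in mm, `c(x, y, z)`.
#' @return numeric 3D array of distances in mm (0 on the mask).
#' @export
edt_mm <- function(mask, spacing) {
  d <- dim(mask)
  stopifnot(length(d) == 3L, length(spacing) == 3L, all(spacing > 0))
  m <- as.logical(mask)
  if (!any(m)) stop("distance transform of an empty mask is undefined")
  out <- edt_cpp(m, as.integer(d), as.numeric(spacing))
  dim(out) <- d
  out
}

#' Label 3D connected components (26-connectivity)
#'
#' @param mask logical or 0/1 3D array.
#' @return integer 3D array; components numbered 1..K in scan order, 0 off
#'   the mask.
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  out <- label_components_cpp(as.logical(mask), as.integer(d))
  dim(out) <- d
  out
}

# shift a 3D array by (dx, dy) within each slice, zero-filling the border
shift_xy <- function(a, dx, dy) {
  d <- dim(a)
  out <- array(0, d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2])
  xi <- xs - dx; yi <- ys - dy
  okx <- xi >= 1 & xi <= d[1]; oky <- yi >= 1 & yi <= d[2]
  out[xs[okx], ys[oky], ] <- a[xi[okx], yi[oky], , drop = FALSE]
  out
}

# one-voxel in-plane (4-neighbourhood) erosion, applied slice by slice
erode_xy <- function(mask) {
  m <- array(as.numeric(mask), dim(mask))
  keep <- m
  for (s in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
    keep <- keep * shift_xy(m, s[1], s[2])
  keep > 0
}

# one-voxel in-plane (4-neighbourhood) dilation, applied slice by slice
dilate_xy <- function(mask) {
  m <- array(as.numeric(mask), dim(mask))
  grow <- m
  for (s in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
    grow <- grow + shift_xy(m, s[1], s[2])
  grow > 0
}

# separable in-plane Gaussian smoothing (sigma in voxels); border handled by
# kernel renormalization via smoothing of an all-ones array
smooth_xy <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pass <- function(v) {
    out <- array(0, dim(v))
    for (i in seq_along(k)) out <- out + k[i] * shift_xy(v, (-r:r)[i], 0)
    out2 <- array(0, dim(v))
    for (i in seq_along(k)) out2 <- out2 + k[i] * shift_xy(out, 0, (-r:r)[i])
    out2
  }
  num <- pass(a)
  den <- pass(array(1, dim(a)))
  num / den
}

assert_same_geometry <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("geometry mismatch between %s: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  invisible(TRUE)
}

# evaluate expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# nearest-rank quantile on sorted data: smallest value with at least p*n
# observations at or below it
nearest_rank <- function(sorted_x, p) {
  n <- length(sorted_x)
  sorted_x[min(n, max(1L, ceiling(p * n)))]
}

voxel_volume_mm3 <- function(spacing) prod(spacing)
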