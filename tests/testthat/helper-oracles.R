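# Brute-force oracles, independent of the package's C++ implementations:
# distances by exhaustive minimization over the voxel set, connected
# components by plain BFS in R, percentiles and tallies by direct
# enumeration.

# exhaustive min-distance (mm) from each query voxel to a mask voxel set
bf_min_dist <- function(query_idx, mask, spacing) {
  dims <- dim(mask)
  pos <- arrayInd(which(mask), dims)
  q <- arrayInd(query_idx, dims)
  vapply(seq_len(nrow(q)), function(i) {
    min(sqrt(((pos[, 1] - q[i, 1]) * spacing[1])^2 +
             ((pos[, 2] - q[i, 2]) * spacing[2])^2 +
             ((pos[, 3] - q[i, 3]) * spacing[3])^2))
  }, numeric(1))
}

# BFS connected components with 26-connectivity, plain R
bf_components <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  nbh <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nbh <- nbh[rowSums(abs(nbh)) > 0, ]
  nxt <- 0L
  for (seed in which(mask & lab == 0L)) {
    if (lab[seed] != 0L) next
    nxt <- nxt + 1L
    queue <- seed
    lab[seed] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      p <- arrayInd(cur, dims)
      for (r in seq_len(nrow(nbh))) {
        q <- p + nbh[r, ]
        if (any(q < 1) || any(q > dims)) next
        qi <- q[1] + dims[1] * (q[2] - 1 + dims[2] * (q[3] - 1))
        if (mask[qi] && lab[qi] == 0L) {
          lab[qi] <- nxt
          queue <- c(queue, qi)
        }
      }
    }
  }
  lab
}

# all-pairs 95th-percentile Hausdorff (nearest-rank percentile)
bf_hausdorff95 <- function(a, b, spacing) {
  da <- sort(bf_min_dist(which(a), b, spacing))
  db <- sort(bf_min_dist(which(b), a, spacing))
  nr <- function(s) s[min(length(s), max(1, ceiling(0.95 * length(s))))]
  max(nr(da), nr(db))
}

# random small binary mask with a few blobs (never empty unless asked)
random_mask <- function(dims, p = 0.05, allow_empty = FALSE) {
  m <- array(runif(prod(dims)) < p, dims)
  if (!allow_empty && !any(m)) m[sample(length(m), 1)] <- TRUE
  m
}

# a small phantom study, cached per options to keep the suite fast
small_spec <- function(seed = 1, ...) {
  phantom_spec(shape = c(64L, 64L, 10L), spacing = c(2, 2, 5), seed = seed,
               ...)
}

local_study_cache <- new.env()
cached_phantom <- function(seed = 1, ...) {
  key <- paste0("s", seed, "_", paste(deparse(list(...)), collapse = ""))
  if (is.null(local_study_cache[[key]]))
    local_study_cache[[key]] <- generate_phantom(small_spec(seed, ...))
  local_study_cache[[key]]
}
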