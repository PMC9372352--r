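# Correlation of WMH volumes with ordinal visual rating scores, and the
# paired-bootstrap comparison of two dependent Spearman correlations.

#' Spearman rank correlation
#'
#' Thin wrapper over [stats::cor()] with `method = "spearman"` (average
#' ranks for ties), guarding the degenerate cases: vectors shorter than 5
#' are refused and a constant vector yields NaN with a warning.
#'
#' @param x,y numeric vectors of equal length (>= 5).
#' @return rank correlation in \[-1, 1\], or NaN for constant input.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5L) stop("need at least 5 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input vector; Spearman correlation undefined")
    return(NaN)
  }
  cor(x, y, method = "spearman")
}

#' Bootstrap comparison of manual vs algorithmic volume-score correlations
#'
#' Computes `delta_r = rho(manual volume, score) - rho(algorithm volume,
#' score)` and its bootstrap 95% confidence interval.  Because the two
#' correlations share subjects, subjects are resampled with replacement as
#' whole (manual, algorithm, score) triples and `delta_r` recomputed per
#' replicate (paired bootstrap); the percentile CI is taken from the
#' replicate distribution and the difference is called significant when the
#' CI excludes 0.  Replicates in which a resampled vector is constant (rank
#' correlation undefined) are dropped and counted.
#'
#' @param table data frame with columns `volume_manual`, `volume_algo`
#'   (e.g. %ICV) and `fazekas` (ordinal score).
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed for reproducibility.
#' @param conf confidence level (default 0.95).
#' @return list with `delta_r`, `r_manual`, `r_algo`, `ci_low`, `ci_high`,
#'   `significant`, `n_dropped`.
#' @export
bootstrap_delta_r <- function(table, n_boot = 1000L, seed = 1L,
                              conf = 0.95) {
  stopifnot(all(c("volume_manual", "volume_algo", "fazekas") %in%
                  names(table)))
  n <- nrow(table)
  if (n < 5L) stop("need at least 5 subjects")
  r_manual <- spearman_rho(table$volume_manual, table$fazekas)
  r_algo <- spearman_rho(table$volume_algo, table$fazekas)
  delta_r <- r_manual - r_algo
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      sm <- table$volume_manual[idx]
      sa <- table$volume_algo[idx]
      sc <- table$fazekas[idx]
      if (sd(sm) == 0 || sd(sa) == 0 || sd(sc) == 0) return(NA_real_)
      cor(sm, sc, method = "spearman") - cor(sa, sc, method = "spearman")
    }, numeric(1))
  })
  n_dropped <- sum(is.na(reps))
  reps <- reps[!is.na(reps)]
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(reps, c(alpha, 1 - alpha)))
  list(delta_r = delta_r, r_manual = r_manual, r_algo = r_algo,
       ci_low = ci[1], ci_high = ci[2],
       significant = ci[1] > 0 || ci[2] < 0,
       n_dropped = n_dropped)
}
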