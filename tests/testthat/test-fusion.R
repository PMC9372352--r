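# Rater fusion, weight maps, histogram proposal, majority voting and the
# consistency report.

test_that("histogram threshold proposal matches its definition", {
  dims <- c(20L, 20L, 4L)
  mask <- array(TRUE, dims)
  # uniform image: nothing exceeds mean + k*SD for k > 0
  flat <- array(0.5, dims)
  expect_equal(sum(histogram_threshold_proposal(flat, mask, k = 2.5,
                                                min_size = 1)), 0)
  # one bright blob far above background is recovered exactly
  img <- array(rnorm(prod(dims), 0.4, 0.02), dims)
  blob <- array(FALSE, dims); blob[8:11, 8:11, 2] <- TRUE
  img[blob] <- 0.9
  got <- histogram_threshold_proposal(img, mask, k = 5, min_size = 1)
  expect_identical(got, blob)
  # k = 0 proposes everything above the within-mask mean
  got0 <- histogram_threshold_proposal(img, mask, k = 0, min_size = 1)
  expect_identical(got0, img > mean(img))
  expect_error(histogram_threshold_proposal(img, array(FALSE, dims)),
               "empty")
})

test_that("fuse_pair partitions WMH into definite and suspected", {
  dims <- c(12L, 12L, 2L)
  a <- array(0L, dims); b <- array(0L, dims)
  a[2:5, 2:5, 1] <- 1L          # 4x4 square
  b[4:7, 4:7, 1] <- 1L          # 4x4 square, 2x2 overlap
  fu <- fuse_pair(a, b)
  expect_equal(sum(fu$definite_wmh), 4)
  expect_equal(sum(fu$suspected_wmh), 2 * 16 - 2 * 4)
  expect_true(all(fu$union_label[fu$definite_wmh] == 1L))
  expect_true(all(fu$union_label[fu$suspected_wmh] == 1L))
  expect_false(any(fu$definite_wmh & fu$suspected_wmh))
  expect_identical((fu$union_label == 1L),
                   fu$definite_wmh | fu$suspected_wmh)
  # symmetry in the raters
  fu2 <- fuse_pair(b, a)
  expect_identical(fu$union_label, fu2$union_label)
  expect_identical(fu$definite_wmh, fu2$definite_wmh)
})

test_that("identical and disjoint raters give the trivial partitions", {
  st <- cached_phantom(seed = 3)
  fu <- fuse_pair(st$truth, st$truth)
  expect_equal(sum(fu$suspected_wmh), 0)
  expect_identical(fu$definite_wmh, st$truth == 1L)
  a <- array(0L, c(6L, 6L, 1L)); b <- a
  a[2, 2, 1] <- 1L; b[5, 5, 1] <- 1L
  fu2 <- fuse_pair(a, b)
  expect_equal(sum(fu2$definite_wmh), 0)
  expect_equal(sum(fu2$suspected_wmh), 2)
})

test_that("weight map obeys the distance rule on a two-component fixture", {
  dims <- c(40L, 9L, 1L)
  sp <- c(1, 1, 5)
  def <- array(FALSE, dims)
  def[4:6, 4:6, 1] <- TRUE        # centroid at x = 5, y = 5
  def[30:32, 4:6, 1] <- TRUE      # centroid at x = 31, y = 5
  susp <- array(FALSE, dims)
  susp[9, 5, 1] <- TRUE           # 4 mm from first centroid
  susp[13, 5, 1] <- TRUE          # 8 mm from first centroid (the farthest)
  susp[29, 5, 1] <- TRUE          # 2 mm from second centroid
  fu <- structure(list(union_label = array(0L, dims) + def * 1L + susp * 1L,
                       definite_wmh = def, suspected_wmh = susp),
                  class = "fusion_result")
  w <- build_weight_map(fu, sp)
  expect_true(all(w[def] == 2))
  expect_equal(w[13, 5, 1], 1)                 # dis == dis_max -> weight 1
  expect_equal(w[9, 5, 1], 1 + (1 - 4 / 8))    # Eq: 1 + (1 - dis/dis_max)
  expect_equal(w[29, 5, 1], 1 + (1 - 2 / 8))
  expect_true(all(w[!def & !susp] == 1))
})

test_that("weight map degenerate cases and bounds hold on random pairs", {
  st <- cached_phantom(seed = 3)
  for (seed in 1:5) {
    r <- simulate_raters(st$truth, small_spec(seed = seed,
                                              rater_disagreement = 0.5))
    fu <- fuse_pair(r$rater_a, r$rater_b)
    w <- build_weight_map(fu, st$spacing)
    expect_true(all(w >= 1 & w <= 2))
    expect_true(all(w[fu$definite_wmh] == 2))
    expect_true(all(w[!fu$definite_wmh & !fu$suspected_wmh] == 1))
  }
  # empty suspected set: weights take only the values 1 and 2
  fu_same <- fuse_pair(st$truth, st$truth)
  w2 <- build_weight_map(fu_same, st$spacing)
  expect_true(all(w2 %in% c(1, 2)))
  # empty definite set: all suspected weights collapse to 1
  a <- array(0L, c(8L, 8L, 1L)); b <- a
  a[2, 2, 1] <- 1L; b[6, 6, 1] <- 1L
  w3 <- build_weight_map(fuse_pair(a, b), c(1, 1, 1))
  expect_true(all(w3 == 1))
})

test_that("majority vote agrees with an exhaustive per-voxel tally", {
  dims <- c(10L, 10L, 3L)
  set.seed(8)
  raters <- lapply(1:5, function(i)
    array(sample(0:2, prod(dims), replace = TRUE,
                 prob = c(0.7, 0.2, 0.1)), dims))
  mv <- majority_vote(raters)
  votes <- sapply(raters, as.vector)
  oracle <- apply(votes, 1, function(v) {
    tab <- table(factor(v, levels = 0:2))
    as.integer(names(tab)[which.max(tab)])   # which.max takes lowest on tie
  })
  expect_identical(as.vector(mv), oracle)
  # five identical volumes vote to themselves
  same <- replicate(5, raters[[1]], simplify = FALSE)
  expect_identical(as.vector(majority_vote(same)), as.vector(raters[[1]]))
  expect_error(majority_vote(raters[1:2]), "at least 3")
})

test_that("consistency report applies the Dice-0.5 acceptance rule", {
  a <- array(0L, c(8L, 8L, 1L)); b <- a
  a[1:4, 1:4, 1] <- 1L; b[1:4, 1:4, 1] <- 1L
  r <- consistency_report(a, b)
  expect_equal(r$dice, 1); expect_true(r$pass)
  b2 <- array(0L, dim(a)); b2[5:8, 5:8, 1] <- 1L
  r2 <- consistency_report(a, b2)
  expect_equal(r2$dice, 0); expect_false(r2$pass)
  # 9-voxel intersection of two 16-voxel squares: Dice 18/32, passes
  a3 <- array(0L, c(10L, 10L, 1L)); b3 <- a3
  a3[1:4, 1:4, 1] <- 1L; b3[2:5, 2:5, 1] <- 1L
  r3 <- consistency_report(a3, b3)
  expect_equal(r3$dice, 18 / 32)
  expect_true(r3$pass)
  # agreement on absence is perfect
  r4 <- consistency_report(array(0L, c(4, 4, 1)), array(0L, c(4, 4, 1)))
  expect_equal(r4$dice, 1)
})
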