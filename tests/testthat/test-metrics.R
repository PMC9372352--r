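# Evaluation metrics against brute-force oracles.

test_that("voxel metrics on counted fixtures and edge cases", {
  dims <- c(10L, 1L, 1L)
  pred <- array(FALSE, dims); truth <- array(FALSE, dims)
  # TP = 3, FP = 1, FN = 3 by construction
  truth[1:6, 1, 1] <- TRUE
  pred[4:7, 1, 1] <- TRUE
  vm <- voxel_metrics(pred, truth)
  expect_equal(vm$dice, 6 / 10)
  expect_equal(vm$recall, 0.5)
  expect_equal(vm$precision, 0.75)
  # identical non-empty masks
  vm2 <- voxel_metrics(truth, truth)
  expect_equal(c(vm2$dice, vm2$recall, vm2$precision), c(1, 1, 1))
  # disjoint non-empty masks
  p3 <- array(FALSE, dims); p3[7:9, 1, 1] <- TRUE
  t3 <- array(FALSE, dims); t3[1:3, 1, 1] <- TRUE
  vm3 <- voxel_metrics(p3, t3)
  expect_equal(c(vm3$dice, vm3$recall, vm3$precision), c(0, 0, 0))
  # both empty: perfect by convention; truth empty only: recall undefined
  e <- array(FALSE, dims)
  vm4 <- voxel_metrics(e, e)
  expect_equal(c(vm4$dice, vm4$recall, vm4$precision), c(1, 1, 1))
  expect_true(is.nan(voxel_metrics(p3, e)$recall))
})

test_that("definite recall counts covered definite voxels", {
  dims <- c(10L, 2L, 1L)
  def <- array(FALSE, dims); def[1:5, , 1] <- TRUE       # 10 voxels
  pred <- array(FALSE, dims)
  pred[1:3, , 1] <- TRUE                                 # 6 covered
  pred[4, 1, 1] <- TRUE                                  # 7th
  expect_equal(definite_recall(pred, def), 7 / 10)
  expect_equal(definite_recall(def, def), 1)
  expect_equal(definite_recall(!def, def), 0)
  expect_true(is.nan(definite_recall(pred, array(FALSE, dims))))
})

test_that("lesion metrics match a flood-fill oracle", {
  dims <- c(16L, 16L, 3L)
  truth <- array(FALSE, dims)
  truth[2:4, 2:4, 1] <- TRUE
  truth[10:12, 10:12, 2] <- TRUE
  # prediction hits the first lesion, misses the second, adds a spurious one
  pred <- array(FALSE, dims)
  pred[3, 3, 1] <- TRUE
  pred[14:15, 2:3, 3] <- TRUE
  lm <- lesion_metrics(pred, truth)
  expect_equal(lm$lesion_recall, 0.5)
  expect_equal(lm$lesion_precision, 0.5)
  expect_equal(lm$lesion_f1, 0.5)
  expect_equal(lm$n_truth_lesions, 2L)
  # perfect prediction of a 4-lesion layout
  st <- cached_phantom(seed = 3)
  wmh <- st$truth == 1L
  lmp <- lesion_metrics(wmh, wmh)
  expect_equal(lmp$lesion_recall, 1)
  expect_equal(lmp$lesion_f1, 1)
  expect_equal(lmp$n_truth_lesions, max(bf_components(wmh)))
})

test_that("lesion recall ignores predicted-component splitting", {
  dims <- c(12L, 12L, 1L)
  truth <- array(FALSE, dims); truth[2:9, 5, 1] <- TRUE
  whole <- array(FALSE, dims); whole[2:9, 5, 1] <- TRUE
  split <- array(FALSE, dims); split[c(2:4, 7:9), 5, 1] <- TRUE
  expect_equal(lesion_metrics(whole, truth)$lesion_recall,
               lesion_metrics(split, truth)$lesion_recall)
})

test_that("average volume difference is |A - B| / B x 100", {
  dims <- c(10L, 10L, 3L)
  a <- array(FALSE, dims); b <- array(FALSE, dims)
  a[1:150] <- TRUE; b[1:100] <- TRUE
  expect_equal(avd(a, b), 50)
  expect_equal(avd(b, b), 0)
  expect_equal(avd(array(FALSE, dims), b), 100)
  expect_true(is.nan(avd(a, array(FALSE, dims))))
})

test_that("hausdorff95 handles singletons and symmetry", {
  dims <- c(12L, 12L, 3L)
  sp <- c(1, 1, 5)
  a <- array(FALSE, dims); b <- array(FALSE, dims)
  a[3, 3, 2] <- TRUE; b[6, 3, 2] <- TRUE          # 3 mm apart in-plane
  expect_equal(hausdorff95(a, b, sp), 3)
  expect_equal(hausdorff95(a, a, sp), 0)
  expect_true(is.nan(hausdorff95(a, array(FALSE, dims), sp)))
  expect_equal(hausdorff95(array(FALSE, dims), array(FALSE, dims), sp), 0)
})

test_that("all metrics agree with brute-force oracles on random fixtures", {
  set.seed(31)
  for (rep in 1:30) {
    dims <- c(sample(6:14, 1), sample(6:14, 1), sample(2:5, 1))
    sp <- c(runif(1, 0.5, 2), runif(1, 0.5, 2), runif(1, 2, 6))
    pred <- random_mask(dims, p = runif(1, 0.03, 0.15))
    truth <- random_mask(dims, p = runif(1, 0.03, 0.15))
    # voxel counts by direct enumeration
    tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
    vm <- voxel_metrics(pred, truth)
    expect_identical(c(vm$tp, vm$fp, vm$fn), c(tp, fp, fn))
    expect_equal(vm$dice, 2 * tp / (2 * tp + fp + fn))
    # lesion tallies via BFS components
    lt <- bf_components(truth); lp <- bf_components(pred)
    lr <- length(unique(lt[truth & pred])) / max(lt)
    lpr <- length(unique(lp[pred & truth])) / max(lp)
    lm <- lesion_metrics(pred, truth)
    expect_equal(lm$lesion_recall, lr)
    expect_equal(lm$lesion_precision, lpr)
    # distances via all-pairs search
    expect_equal(hausdorff95(pred, truth, sp), bf_hausdorff95(pred, truth, sp),
                 tolerance = 1e-12)
    expect_equal(hausdorff95(pred, truth, sp), hausdorff95(truth, pred, sp))
  }
})

test_that("metrics_report evaluates both classes of a phantom against
          itself and a perturbed copy", {
  st <- cached_phantom(seed = 3)
  rep0 <- metrics_report(st$truth, st$truth, st$spacing)
  expect_equal(rep0$dice, c(1, 1))
  expect_equal(rep0$hausdorff95_mm, c(0, 0))
  r <- simulate_raters(st$truth, small_spec(seed = 3))
  rep1 <- metrics_report(r$rater_a, st$truth, st$spacing,
                         definite = st$truth == 1L)
  expect_true(all(rep1$dice < 1 & rep1$dice > 0))
  expect_true(rep1$definite_recall[1] <= 1)
  agg <- cohort_metrics(list(rep0, rep1))
  expect_true(all(c("mean", "sd") %in% names(agg)))
})
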