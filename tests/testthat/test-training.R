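# Dice losses, patch sampling and the optimization loop.

test_that("dice loss on hand-computed toy patches", {
  # perfect one-hot prediction: loss ~ 0 (only the epsilon keeps it > 0)
  g <- wmhseg:::one_hot(array(c(0L, 1L, 1L, 0L), c(2, 2, 1)), 2)
  expect_lt(dice_loss(g, g), 1e-5)
  # zero overlap in every class: loss = 1
  gl <- array(c(0L, 0L, 1L, 1L), c(2, 2, 1))
  p <- wmhseg:::one_hot(array(c(1L, 1L, 0L, 0L), c(2, 2, 1)), 2)
  expect_equal(dice_loss(p, wmhseg:::one_hot(gl, 2)), 1, tolerance = 1e-9)
  # 4-voxel 2-class patch evaluated by hand:
  # p(class0) = (.9,.6,.2,.1), g(class0) = (1,1,0,0)
  p2 <- array(0, c(2, 2, 2, 1))
  p2[, , 1, 1] <- c(0.9, 0.6, 0.2, 0.1)
  p2[, , 2, 1] <- 1 - p2[, , 1, 1]
  g2 <- wmhseg:::one_hot(array(c(0L, 0L, 1L, 1L), c(2, 2, 1)), 2)
  num0 <- 2 * (0.9 + 0.6)
  den0 <- (0.81 + 0.36 + 0.04 + 0.01) + 2
  num1 <- 2 * (0.8 + 0.9)
  den1 <- (0.01 + 0.16 + 0.64 + 0.81) + 2
  hand <- 1 - 0.5 * (num0 / (den0 + 1e-6) + num1 / (den1 + 1e-6))
  expect_equal(dice_loss(p2, g2), hand, tolerance = 1e-12)
})

test_that("weighted dice loss reduces exactly to dice loss at w = 1", {
  set.seed(6)
  for (rep in 1:10) {
    d <- c(sample(4:8, 1), sample(4:8, 1), 3L, sample(1:3, 1))
    z <- array(rnorm(prod(d)), d)
    p <- exp(z)
    tot <- array(apply(p, c(1, 2, 4), sum), d[c(1, 2, 4)])
    for (cc in 1:3) p[, , cc, ] <- array(p[, , cc, ], d[c(1, 2, 4)]) / tot
    g <- wmhseg:::one_hot(array(sample(0:2, prod(d[c(1, 2, 4)]), TRUE),
                                d[c(1, 2, 4)]), 3)
    w1 <- array(1, d[c(1, 2, 4)])
    expect_equal(weighted_dice_loss(p, g, w1), dice_loss(p, g),
                 tolerance = 1e-12)
    # and with real weights the loss stays in [0, 1]
    w <- array(runif(prod(d[c(1, 2, 4)]), 1, 2), d[c(1, 2, 4)])
    lw <- weighted_dice_loss(p, g, w)
    expect_gte(lw, 0); expect_lte(lw, 1)
  }
  expect_error(weighted_dice_loss(p, g, w * 3), "\\[1, 2\\]")
})

test_that("up-weighting one class changes only that class's term", {
  set.seed(7)
  d <- c(6L, 6L, 3L, 1L)
  p <- array(runif(prod(d), 0.05, 0.95), d)
  g <- wmhseg:::one_hot(array(sample(0:2, 36, TRUE), c(6, 6, 1)), 3)
  w1 <- array(1, c(6, 6, 1))
  w2 <- w1; w2[g[, , 2, 1] == 1] <- 2    # weight the WMH voxels only
  term <- function(p, g, w, cc) {
    pc <- p[, , cc, 1]; gc_ <- g[, , cc, 1]; wv <- w[, , 1]
    2 * sum(wv * pc * gc_) / (sum(wv * pc^2) + sum(wv * gc_^2) + 1e-6)
  }
  # per-class oracle: non-WMH background term is also touched because the
  # weighted voxels carry probability mass in every class map; the truth
  # one-hot term for class 2 changes, class terms without those voxels in
  # either accumulator are identical
  l1 <- weighted_dice_loss(p, g, w1)
  l2 <- weighted_dice_loss(p, g, w2)
  hand1 <- 1 - mean(sapply(1:3, function(cc) term(p, g, w1, cc)))
  hand2 <- 1 - mean(sapply(1:3, function(cc) term(p, g, w2, cc)))
  expect_equal(l1, hand1, tolerance = 1e-12)
  expect_equal(l2, hand2, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(l1, l2)))
})

test_that("loss gradient is larger in magnitude at a definite voxel than at
          an otherwise identical weight-1 voxel", {
  set.seed(8)
  d <- c(4L, 4L, 2L, 1L)
  p <- array(runif(prod(d), 0.2, 0.8), d)
  gl <- array(c(rep(1L, 8), rep(0L, 8)), c(4, 4, 1))
  g <- wmhseg:::one_hot(gl, 2)
  # two WMH voxels with identical probabilities; one definite (w=2)
  p[1, 1, , 1] <- p[2, 1, , 1]
  w <- array(1, c(4, 4, 1)); w[1, 1, 1] <- 2
  grad <- wmhseg:::weighted_dice_loss_grad(p, g, w)
  expect_gt(abs(grad[1, 1, 2, 1]), abs(grad[2, 1, 2, 1]))
  # finite-difference agreement at both voxels
  for (vox in list(c(1, 1), c(2, 1))) {
    eps <- 1e-6
    pp <- p; pp[vox[1], vox[2], 2, 1] <- pp[vox[1], vox[2], 2, 1] + eps
    pm <- p; pm[vox[1], vox[2], 2, 1] <- pm[vox[1], vox[2], 2, 1] - eps
    numg <- (weighted_dice_loss(pp, g, w) - weighted_dice_loss(pm, g, w)) /
      (2 * eps)
    expect_equal(grad[vox[1], vox[2], 2, 1], numg, tolerance = 1e-5)
  }
})

test_that("patch sampling is seeded and oversamples lesion slices", {
  st <- preprocess_study(cached_phantom(seed = 3))
  b1 <- sample_patches(st, st$truth, NULL, patch_size = 32, n = 6, seed = 9)
  b2 <- sample_patches(st, st$truth, NULL, patch_size = 32, n = 6, seed = 9)
  expect_identical(b1, b2)
  expect_equal(dim(b1$x), c(32L, 32L, 3L, 6L))
  expect_equal(dim(b1$g), c(32L, 32L, 3L, 6L))
  # single lesion slice at oversample 5: expected frequency 5/(5 + k - 1)
  dims <- c(16L, 16L, 6L)
  toy <- list(t1 = array(0, dims), t2 = array(0, dims),
              flair = array(0, dims), spacing = c(1, 1, 5))
  labels <- array(0L, dims); labels[8, 8, 4] <- 1L
  n <- 4000
  bt <- sample_patches(toy, labels, NULL, patch_size = 16, n = n, seed = 2,
                       oversample = 5)
  hits <- sum(vapply(seq_len(n), function(i) any(bt$labels[, , i] > 0),
                     logical(1)))
  expected <- 5 / (5 + 5)
  expect_lt(abs(hits / n - expected), 3 * sqrt(expected * 0.5 / n) + 0.02)
  # lesion-free study: uniform slice draws, and the batch is usable
  bt2 <- sample_patches(toy, array(0L, dims), NULL, patch_size = 16, n = 10,
                        seed = 3)
  expect_equal(dim(bt2$x), c(16L, 16L, 3L, 10L))
  # padding when the patch exceeds the slice
  bt3 <- sample_patches(toy, labels, NULL, patch_size = 32, n = 2, seed = 4)
  expect_equal(dim(bt3$x), c(32L, 32L, 3L, 2L))
})

test_that("short optimization reduces the training loss and is seeded; a
          zero learning rate freezes the weights", {
  studies <- list(preprocess_study(cached_phantom(seed = 3)))
  net <- build_network(vbnet_tiny_config(crop_size = 32L), seed = 1)
  cfg <- train_config(steps = 8, val_every = 8, patch_size = 32,
                      batch_size = 4, seed = 2)
  fit <- train_vbnet(net, studies, cfg)
  expect_lt(mean(tail(fit$history$train_loss, 3)),
            mean(head(fit$history$train_loss, 3)))
  fit2 <- train_vbnet(build_network(vbnet_tiny_config(crop_size = 32L),
                                    seed = 1), studies, cfg)
  expect_equal(fit$history$train_loss, fit2$history$train_loss,
               tolerance = 1e-12)
  frozen <- train_vbnet(build_network(vbnet_tiny_config(crop_size = 32L),
                                      seed = 1), studies,
                        train_config(lr = 0, steps = 3, val_every = 3,
                                     patch_size = 32, batch_size = 2,
                                     seed = 2))
  init <- build_network(vbnet_tiny_config(crop_size = 32L), seed = 1)
  expect_equal(frozen$net$params, init$params, tolerance = 1e-14)
})

test_that("prediction obeys the argmax and brain-mask contracts", {
  st <- preprocess_study(cached_phantom(seed = 3))
  net <- build_network(vbnet_tiny_config(), seed = 1)
  pr <- predict_vbnet(net, st)
  expect_equal(dim(pr$label), dim(st$truth))
  expect_true(all(pr$label[!st$brain_mask] == 0L))
  expect_true(all(pr$label %in% 0:2))
  # argmax with ties toward the lower code
  p <- array(0, c(2, 2, 3, 1))
  p[, , 1, 1] <- c(0.1, 0.4, 0.4, 1 / 3)
  p[, , 2, 1] <- c(0.7, 0.4, 0.2, 1 / 3)
  p[, , 3, 1] <- c(0.2, 0.2, 0.4, 1 / 3)
  lab <- wmhseg:::argmax_channel(p)
  expect_equal(as.vector(lab), c(1L, 0L, 0L, 0L))
})

test_that("checkpoints round-trip through disk", {
  net <- build_network(vbnet_tiny_config(), seed = 5)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(net, f, extra = list(note = "unit"))
  re <- load_checkpoint(f)
  expect_identical(re$params, net$params)
  expect_identical(re$config, net$config)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3, 1))
  expect_identical(vbnet_forward(re, x), vbnet_forward(net, x))
  unlink(f)
})
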