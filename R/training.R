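# Weighted Dice loss, patch sampling, the Adam training loop and
# whole-study inference.
#
# Loss inputs are arrays (H, W, C, N): p the network's per-class
# probabilities (summing to 1 over C at each voxel), g the one-hot ground
# truth, and w a per-voxel weight volume (H, W, N) in [1, 2].  The batch
# axis is folded into the voxel sums, so a batch behaves as one large patch.

#' Multi-class soft Dice loss
#'
#' `1 - (1/C) * sum_c 2*sum(p*g) / (sum(p^2) + sum(g^2) + eps)`, summed over
#' all voxels of the batch.  Zero for a perfect prediction, 1 when no class
#' overlaps; the smoothing `eps` appears in the denominator only.
#'
#' @param p probability array `(H, W, C, N)` (a 3D `(H, W, C)` array is
#'   treated as a single-patch batch).
#' @param g one-hot ground-truth array of the same shape.
#' @param eps denominator smoothing constant.
#' @return scalar loss in \[0, 1\].
#' @export
dice_loss <- function(p, g, eps = 1e-6) {
  weighted_dice_loss(p, g, w = NULL, eps = eps)
}

as_batch4 <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

#' Weighted multi-class soft Dice loss
#'
#' The Dice loss with every per-class accumulator weighted voxel-wise:
#' `2*sum(w*p*g) / (sum(w*p^2) + sum(w*g^2) + eps)`.  Definite WMH voxels
#' (weight 2) therefore pull the WMH class term twice as strongly as
#' ordinary voxels, while `w = 1` everywhere reduces the loss exactly to
#' [dice_loss()].
#'
#' @inheritParams dice_loss
#' @param w per-voxel weights `(H, W, N)` in \[1, 2\], or `NULL` for
#'   unweighted.
#' @return scalar loss in \[0, 1\].
#' @export
weighted_dice_loss <- function(p, g, w = NULL, eps = 1e-6) {
  p <- as_batch4(p); g <- as_batch4(g)
  stopifnot(identical(dim(p), dim(g)))
  d <- dim(p); C <- d[3]
  if (!is.null(w)) {
    if (any(w < 1 - 1e-12) || any(w > 2 + 1e-12))
      stop("weights must lie in [1, 2]")
    w <- array(w, c(d[1], d[2], d[4]))
  }
  total <- 0
  for (cc in seq_len(C)) {
    pc <- array(p[, , cc, ], c(d[1], d[2], d[4]))
    gc_ <- array(g[, , cc, ], c(d[1], d[2], d[4]))
    if (is.null(w)) {
      num <- 2 * sum(pc * gc_)
      den <- sum(pc^2) + sum(gc_^2) + eps
    } else {
      num <- 2 * sum(w * pc * gc_)
      den <- sum(w * pc^2) + sum(w * gc_^2) + eps
    }
    total <- total + num / den
  }
  1 - total / C
}

# gradient of the (weighted) Dice loss with respect to p
weighted_dice_loss_grad <- function(p, g, w = NULL) {
  p <- as_batch4(p); g <- as_batch4(g)
  d <- dim(p); C <- d[3]
  eps <- 1e-6
  grad <- array(0, d)
  wv <- if (is.null(w)) 1 else array(w, c(d[1], d[2], d[4]))
  for (cc in seq_len(C)) {
    pc <- array(p[, , cc, ], c(d[1], d[2], d[4]))
    gc_ <- array(g[, , cc, ], c(d[1], d[2], d[4]))
    num <- 2 * sum(wv * pc * gc_)
    den <- sum(wv * pc^2) + sum(wv * gc_^2) + eps
    gcell <- -(1 / C) * (2 * wv * gc_ * den - num * 2 * wv * pc) / den^2
    grad[, , cc, ] <- gcell
  }
  grad
}

one_hot <- function(labels, C) {
  d <- dim(labels)
  out <- array(0, c(d[1], d[2], C, d[3]))
  for (cc in seq_len(C)) out[, , cc, ] <- as.numeric(labels == cc - 1L)
  out
}

#' Sample training patches from a study
#'
#' Draws `n` axial patches of `patch_size` x `patch_size` voxels.  A slice
#' containing any lesion voxel is `oversample` times as likely to be drawn
#' as a lesion-free slice (lesions are sparse; uniform slice sampling would
#' starve the lesion classes).  Patches larger than the slice are
#' symmetrically zero-padded.
#'
#' @param study a preprocessed `wmh_study`.
#' @param labels integer label volume aligned with the study (e.g. the
#'   fused union ground truth).
#' @param weight_map per-voxel loss weights aligned with `labels` (or
#'   `NULL` for unweighted training).
#' @param patch_size patch edge in voxels.
#' @param n number of patches.
#' @param seed integer seed.
#' @param oversample lesion-slice oversampling factor (default 5).
#' @param n_classes number of classes for the one-hot encoding.
#' @return list with `x` `(S, S, 3, n)`, `g` `(S, S, C, n)`, `w`
#'   `(S, S, n)`.
#' @export
sample_patches <- function(study, labels, weight_map = NULL,
                           patch_size = 64L, n = 8L, seed = 1L,
                           oversample = 5, n_classes = 3L) {
  d <- dim(study$flair)
  S <- as.integer(patch_size)
  lesion_slice <- vapply(seq_len(d[3]), function(z) any(labels[, , z] > 0L),
                         logical(1))
  pslice <- ifelse(lesion_slice, oversample, 1)
  pslice <- pslice / sum(pslice)
  with_seed(seed, {
    x <- array(0, c(S, S, 3L, n))
    gl <- array(0L, c(S, S, n))
    w <- array(1, c(S, S, n))
    for (i in seq_len(n)) {
      z <- sample.int(d[3], 1L, prob = pslice)
      x0 <- if (d[1] > S) sample.int(d[1] - S + 1L, 1L) else 1L
      y0 <- if (d[2] > S) sample.int(d[2] - S + 1L, 1L) else 1L
      xs <- x0:min(d[1], x0 + S - 1L)
      ys <- y0:min(d[2], y0 + S - 1L)
      # symmetric zero-padding when the slice is smaller than the patch
      ox <- max(0L, (S - length(xs)) %/% 2L)
      oy <- max(0L, (S - length(ys)) %/% 2L)
      px <- ox + seq_along(xs); py <- oy + seq_along(ys)
      x[px, py, 1L, i] <- study$t1[xs, ys, z]
      x[px, py, 2L, i] <- study$t2[xs, ys, z]
      x[px, py, 3L, i] <- study$flair[xs, ys, z]
      gl[px, py, i] <- labels[xs, ys, z]
      if (!is.null(weight_map)) w[px, py, i] <- weight_map[xs, ys, z]
    }
    list(x = x, g = one_hot(gl, n_classes), w = w, labels = gl)
  })
}

zero_like <- function(p) {
  z <- p
  z[] <- 0
  z
}

adam_init <- function(params) {
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr, betas = c(0.9, 0.999),
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Training configuration
#'
#' The reference protocol uses Adam with first/second moment coefficients
#' 0.9/0.999, learning rate 0.001, mini-batch 48 and 256x256 patches; the
#' defaults here are the CPU-scale counterparts (batch 8, 64-voxel patches,
#' a fixed step budget with periodic validation) with the same optimizer
#' settings.
#'
#' @param lr learning rate.
#' @param betas Adam moment coefficients.
#' @param batch_size patches per step.
#' @param patch_size patch edge in voxels.
#' @param steps optimization steps.
#' @param val_every validate (and checkpoint the best state) every so many
#'   steps.
#' @param oversample lesion-slice oversampling factor for patch sampling.
#' @param seed integer seed controlling initialization and sampling.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, betas = c(0.9, 0.999), batch_size = 8L,
                         patch_size = 64L, steps = 400L, val_every = 50L,
                         oversample = 5, seed = 1L) {
  stopifnot(lr >= 0, batch_size > 0, patch_size > 0, steps >= 0)
  structure(list(lr = lr, betas = betas, batch_size = as.integer(batch_size),
                 patch_size = as.integer(patch_size),
                 steps = as.integer(steps),
                 val_every = as.integer(val_every), oversample = oversample,
                 seed = as.integer(seed)),
            class = "train_config")
}

# assemble per-study training material (labels + weight map) once
training_material <- function(study) {
  if (!is.null(study$fusion)) {
    labels <- study$fusion$union_label
    w <- build_weight_map(study$fusion, study$spacing)
  } else {
    labels <- study$truth
    w <- NULL
  }
  list(labels = labels, weights = w)
}

#' Train the network with weighted Dice loss
#'
#' Runs Kaiming-initialized Adam over patches sampled from the training
#' studies, minimizing [weighted_dice_loss()] (weight maps are taken from
#' each study's `fusion` element when present, otherwise weights are 1 and
#' the plain Dice loss is optimized).  Every `val_every` steps the loss on
#' patches from the validation studies is evaluated and the best-validation
#' parameters are kept.  Training aborts if the loss turns non-finite.
#'
#' @param net a [build_network()] result.
#' @param studies list of preprocessed training `wmh_study` objects.
#' @param config a [train_config()].
#' @param val_studies optional list of validation studies (defaults to the
#'   training studies).
#' @return list with `net` (best-validation parameters) and `history`
#'   (data frame: step, train_loss, val_loss).
#' @export
train_vbnet <- function(net, studies, config = train_config(),
                        val_studies = NULL) {
  stopifnot(length(studies) >= 1L)
  if (is.null(val_studies)) val_studies <- studies
  mats <- lapply(studies, training_material)
  val_mats <- lapply(val_studies, training_material)
  C <- net$config$out_channels
  state <- adam_init(net$params)
  history <- list()
  best_val <- Inf
  best_params <- net$params
  best_buffers <- net$buffers
  val_batches <- lapply(seq_along(val_studies), function(i)
    sample_patches(val_studies[[i]], val_mats[[i]]$labels,
                   val_mats[[i]]$weights, config$patch_size,
                   n = config$batch_size, seed = 900001L + i,
                   oversample = config$oversample, n_classes = C))
  validate <- function(net) {
    mean(vapply(val_batches, function(bt) {
      p <- net_forward(net, bt$x, train = FALSE, keep = FALSE)$output
      weighted_dice_loss(p, bt$g, bt$w)
    }, numeric(1)))
  }
  for (step in seq_len(config$steps)) {
    i <- with_seed(config$seed + 2L * step, sample.int(length(studies), 1L))
    bt <- sample_patches(studies[[i]], mats[[i]]$labels, mats[[i]]$weights,
                         config$patch_size, n = config$batch_size,
                         seed = config$seed + 2L * step + 1L,
                         oversample = config$oversample, n_classes = C)
    fwd <- net_forward(net, bt$x, train = TRUE, keep = TRUE)
    net <- fwd$net   # batch-norm running statistics advanced
    loss <- weighted_dice_loss(fwd$output, bt$g, bt$w)
    if (!is.finite(loss))
      stop(sprintf("training diverged at step %d (loss = %s)", step, loss))
    gout <- weighted_dice_loss_grad(fwd$output, bt$g, bt$w)
    grads <- net_backward(net, fwd, gout)
    upd <- adam_step(net$params, grads, state, config$lr, config$betas)
    net$params <- upd$params
    state <- upd$state
    val_loss <- NA_real_
    if (step %% config$val_every == 0L || step == config$steps) {
      val_loss <- validate(net)
      if (val_loss < best_val) {
        best_val <- val_loss
        best_params <- net$params
        best_buffers <- net$buffers
      }
    }
    history[[step]] <- data.frame(step = step, train_loss = loss,
                                  val_loss = val_loss)
  }
  if (config$steps > 0L && is.finite(best_val)) {
    net$params <- best_params
    net$buffers <- best_buffers
  }
  list(net = net, history = do.call(rbind, history))
}

argmax_channel <- function(p) {
  # first (lowest-code) class wins ties: background-conservative
  d <- dim(p)
  best <- array(1L, d[c(1, 2, 4)])
  bestv <- array(p[, , 1, ], d[c(1, 2, 4)])
  for (cc in seq_len(d[3])[-1]) {
    v <- array(p[, , cc, ], d[c(1, 2, 4)])
    upd <- v > bestv
    best[upd] <- cc
    bestv[upd] <- v[upd]
  }
  best - 1L
}

#' Segment a whole study with a trained network
#'
#' Runs a full-resolution forward pass per axial slice (the network is
#' fully convolutional, so no patching is needed at inference), pads each
#' slice symmetrically to the nearest size divisible by `2^(levels-1)`,
#' takes the per-voxel argmax (ties broken toward the lower class code) and
#' forces voxels outside the brain mask to background.
#'
#' @param net a trained `vbnet`.
#' @param study a preprocessed `wmh_study`.
#' @return list with `label` (integer volume) and `probs`
#'   (`(H, W, n_slices, C)` probability array).
#' @export
predict_vbnet <- function(net, study) {
  d <- dim(study$flair)
  assert_same_geometry(study$flair, study$brain_mask,
                       "image and brain mask")
  div <- 2^(net$config$levels - 1)
  H <- as.integer(ceiling(d[1] / div) * div)
  W <- as.integer(ceiling(d[2] / div) * div)
  ox <- (H - d[1]) %/% 2L; oy <- (W - d[2]) %/% 2L
  C <- net$config$out_channels
  probs <- array(0, c(d[1], d[2], d[3], C))
  x <- array(0, c(H, W, 3L, 1L))
  for (z in seq_len(d[3])) {
    x[] <- 0
    x[ox + seq_len(d[1]), oy + seq_len(d[2]), 1L, 1L] <- study$t1[, , z]
    x[ox + seq_len(d[1]), oy + seq_len(d[2]), 2L, 1L] <- study$t2[, , z]
    x[ox + seq_len(d[1]), oy + seq_len(d[2]), 3L, 1L] <- study$flair[, , z]
    p <- net_forward(net, x, train = FALSE, keep = FALSE)$output
    probs[, , z, ] <- p[ox + seq_len(d[1]), oy + seq_len(d[2]), , 1L]
  }
  p4 <- aperm(probs, c(1, 2, 4, 3))   # (H, W, C, n_slices) for the argmax
  label <- argmax_channel(p4)
  label[!as.logical(study$brain_mask)] <- 0L
  list(label = label, probs = probs)
}

#' Save / load a network checkpoint
#'
#' The checkpoint embeds the configuration, parameters, normalization
#' buffers and the training seed, so a run can be resumed or audited.
#'
#' @param net a `vbnet`.
#' @param path file path (`.rds`).
#' @param extra optional list stored alongside (e.g. training history).
#' @export
save_checkpoint <- function(net, path, extra = list()) {
  saveRDS(list(config = net$config, params = net$params,
               buffers = net$buffers, extra = extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- build_network(ck$config, seed = 1L)
  net$params <- ck$params
  net$buffers <- ck$buffers
  attr(net, "extra") <- ck$extra
  net
}
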