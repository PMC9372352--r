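# Layer-level forward and backward passes for the 2D network.
#
# Activations are arrays (H, W, C, N); convolution weights are arrays
# (kh, kw, C_in, C_out).  The network is a list of nodes in topological
# order; `net_forward()` walks it caching intermediate values, and
# `net_backward()` walks it in reverse, accumulating gradients for every
# trainable parameter.  Transposed convolution reuses the convolution
# primitives with the forward/backward roles exchanged.

# broadcast a per-channel vector over an (H, W, C, N) array
bcast_c <- function(v, d) rep(rep(v, each = d[1] * d[2]), times = 1)

chan_sum <- function(x) {
  d <- dim(x)
  cs <- .colSums(x, d[1] * d[2], d[3] * d[4])
  .rowSums(cs, d[3], d[4])
}

chan_mean <- function(x) {
  d <- dim(x)
  cm <- .colMeans(x, d[1] * d[2], d[3] * d[4])
  .rowMeans(cm, d[3], d[4])
}

tconv_out_size <- function(n_in, k, stride) (n_in - 1L) * stride + k

node_forward <- function(node, ins, params, buffers, train) {
  a <- node$args
  switch(node$op,
    conv = {
      y <- conv_fwd_cpp(ins[[1]], params[[node$w]], params[[node$b]],
                        a$stride, a$pad)
      list(y = y)
    },
    tconv = {
      x <- ins[[1]]
      d <- dim(x)
      oH <- tconv_out_size(d[1], a$k, a$stride)
      oW <- tconv_out_size(d[2], a$k, a$stride)
      y <- conv_grad_input_cpp(x, params[[node$w]], a$stride, 0L, oH, oW)
      dy <- dim(y)
      y <- y + bcast_c(params[[node$b]], dy)
      list(y = y)
    },
    bn = {
      x <- ins[[1]]
      d <- dim(x)
      eps <- a$eps
      if (train) {
        mu <- chan_mean(x)
        va <- chan_mean(x * x) - mu^2
        buffers[[node$rm]] <- (1 - a$momentum) * buffers[[node$rm]] +
          a$momentum * mu
        buffers[[node$rv]] <- (1 - a$momentum) * buffers[[node$rv]] +
          a$momentum * va
      } else {
        mu <- buffers[[node$rm]]
        va <- buffers[[node$rv]]
      }
      invstd <- 1 / sqrt(va + eps)
      xhat <- (x - bcast_c(mu, d)) * bcast_c(invstd, d)
      y <- xhat * bcast_c(params[[node$gamma]], d) +
        bcast_c(params[[node$beta]], d)
      list(y = y, cache = list(xhat = xhat, invstd = invstd),
           buffers = buffers)
    },
    prelu = {
      x <- ins[[1]]
      d <- dim(x)
      xn <- pmin(x, 0)
      y <- pmax(x, 0) + xn * bcast_c(params[[node$a]], d)
      list(y = y, cache = list(x = x, xn = xn))
    },
    add = list(y = ins[[1]] + ins[[2]]),
    concat = {
      x1 <- ins[[1]]; x2 <- ins[[2]]
      d1 <- dim(x1); d2 <- dim(x2)
      y <- array(0, c(d1[1], d1[2], d1[3] + d2[3], d1[4]))
      y[, , seq_len(d1[3]), ] <- x1
      y[, , d1[3] + seq_len(d2[3]), ] <- x2
      list(y = y)
    },
    softmax = {
      x <- ins[[1]]
      d <- dim(x)
      C <- d[3]
      m <- x[, , 1, , drop = FALSE]
      if (C > 1) for (cc in 2:C) m <- pmax(m, x[, , cc, , drop = FALSE])
      y <- array(0, d)
      tot <- array(0, dim(m))
      for (cc in seq_len(C)) {
        e <- exp(x[, , cc, , drop = FALSE] - m)
        y[, , cc, ] <- e
        tot <- tot + e
      }
      for (cc in seq_len(C)) y[, , cc, ] <- y[, , cc, , drop = FALSE] / tot
      list(y = y, cache = list(p = y))
    },
    stop("unknown op: ", node$op))
}

node_backward <- function(node, gout, ins, vals, params, cache) {
  a <- node$args
  switch(node$op,
    conv = {
      x <- ins[[1]]
      wd <- dim(params[[node$w]])
      gw <- conv_grad_weight_cpp(x, gout, wd[1], wd[2], a$stride, a$pad)
      gb <- chan_sum(gout)
      gin <- conv_grad_input_cpp(gout, params[[node$w]], a$stride, a$pad,
                                 dim(x)[1], dim(x)[2])
      list(gins = list(gin),
           gparams = setNames(list(gw, gb), c(node$w, node$b)))
    },
    tconv = {
      x <- ins[[1]]
      gin <- conv_fwd_cpp(gout, params[[node$w]], numeric(0), a$stride, 0L)
      gw <- conv_grad_weight_cpp(gout, x, a$k, a$k, a$stride, 0L)
      gb <- chan_sum(gout)
      list(gins = list(gin),
           gparams = setNames(list(gw, gb), c(node$w, node$b)))
    },
    bn = {
      d <- dim(gout)
      m <- d[1] * d[2] * d[4]
      xhat <- cache$xhat
      ggamma <- chan_sum(gout * xhat)
      gbeta <- chan_sum(gout)
      gmean <- gbeta / m
      gxhat_mean <- ggamma / m
      gin <- bcast_c(params[[node$gamma]] * cache$invstd, d) *
        (gout - bcast_c(gmean, d) - xhat * bcast_c(gxhat_mean, d))
      list(gins = list(gin),
           gparams = setNames(list(ggamma, gbeta),
                              c(node$gamma, node$beta)))
    },
    prelu = {
      d <- dim(gout)
      pos <- cache$x > 0
      gin <- gout * (pos + bcast_c(params[[node$a]], d) * !pos)
      ga <- chan_sum(gout * cache$xn)
      list(gins = list(gin), gparams = setNames(list(ga), node$a))
    },
    add = list(gins = list(gout, gout), gparams = list()),
    concat = {
      d1 <- dim(vals[[node$inputs[1]]])
      g1 <- gout[, , seq_len(d1[3]), , drop = FALSE]
      g2 <- gout[, , -seq_len(d1[3]), , drop = FALSE]
      list(gins = list(g1, g2), gparams = list())
    },
    softmax = {
      p <- cache$p
      d <- dim(p)
      C <- d[3]
      dot <- array(0, c(d[1], d[2], 1, d[4]))
      for (cc in seq_len(C))
        dot <- dot + gout[, , cc, , drop = FALSE] * p[, , cc, , drop = FALSE]
      gz <- array(0, d)
      for (cc in seq_len(C))
        gz[, , cc, ] <- p[, , cc, , drop = FALSE] *
          (gout[, , cc, , drop = FALSE] - dot)
      list(gins = list(gz), gparams = list())
    },
    stop("unknown op: ", node$op))
}

# Forward pass over the whole graph.  Returns the output array and, when
# `keep = TRUE`, the cached activations needed for the backward pass.
net_forward <- function(net, x, train = FALSE, keep = train) {
  vals <- list(input = x)
  caches <- list()
  for (node in net$nodes) {
    if (node$op == "input") next
    ins <- lapply(node$inputs, function(i) vals[[i]])
    res <- node_forward(node, ins, net$params, net$buffers, train)
    vals[[node$id]] <- res$y
    if (!is.null(res$cache)) caches[[node$id]] <- res$cache
    if (!is.null(res$buffers)) net$buffers <- res$buffers
  }
  list(output = vals[[net$nodes[[length(net$nodes)]]$id]], vals = vals,
       caches = caches, net = net)
}

# Backward pass: `gout` is dL/d(output of the final node).
# Returns gradients for every trainable parameter (named like net$params).
net_backward <- function(net, fwd, gout) {
  grads_v <- list()
  grads_p <- lapply(net$params, function(p) { z <- p; z[] <- 0; z })
  last_id <- net$nodes[[length(net$nodes)]]$id
  grads_v[[last_id]] <- gout
  for (k in rev(seq_along(net$nodes))) {
    node <- net$nodes[[k]]
    if (node$op == "input") next
    g <- grads_v[[node$id]]
    if (is.null(g)) next
    ins <- lapply(node$inputs, function(i) fwd$vals[[i]])
    bw <- node_backward(node, g, ins, fwd$vals, net$params,
                        fwd$caches[[node$id]])
    for (j in seq_along(node$inputs)) {
      src <- node$inputs[j]
      if (src == "input") next
      gi <- bw$gins[[j]]
      grads_v[[src]] <- if (is.null(grads_v[[src]])) gi
                        else grads_v[[src]] + gi
    }
    for (pn in names(bw$gparams))
      grads_p[[pn]] <- grads_p[[pn]] + bw$gparams[[pn]]
  }
  grads_p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
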