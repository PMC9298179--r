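# Minimal convolutional network stack with hand-derived backpropagation.
# Tensors are R arrays dimensioned (H, W, C, B); conv kernels run in C++
# (src/conv.cpp, im2col + GEMM). Supported layer types:
#   conv      k x k convolution, stride 1 or 2, zero "same" padding,
#             activation in {relu, lrelu, sigmoid, none}
#   resblock  x + conv(relu(conv(x))), 3x3, stride 1, channel-preserving
#   upsample  2x nearest-neighbour upsampling
#   gpool     global mean pool over H, W
# A net is a list of layer specs; weights are a parallel named list.

layer_conv <- function(k, stride, in_ch, out_ch, act = "relu",
                       pad = (k - 1L) %/% 2L) {
  list(type = "conv", k = as.integer(k), stride = as.integer(stride),
       in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
       act = act, pad = as.integer(pad))
}
layer_resblock <- function(ch) list(type = "resblock", ch = as.integer(ch))
layer_upsample <- function() list(type = "upsample")
layer_gpool <- function() list(type = "gpool")

# Weight init: sd = 0.02 gives the DCGAN convention used for the GAN nets;
# init = "he" gives sd = sqrt(2 / fan_in) (used for the frozen extractor so
# feature magnitudes stay O(1)).
init_net_weights <- function(net, seed, init = c("dcgan", "he")) {
  init <- match.arg(init)
  with_seed(seed, {
    weights <- vector("list", length(net))
    for (i in seq_along(net)) {
      l <- net[[i]]
      if (l$type == "conv") {
        sdv <- if (init == "he") sqrt(2 / (l$k * l$k * l$in_ch)) else 0.02
        weights[[i]] <- list(
          w = array(rnorm(l$k^2 * l$in_ch * l$out_ch, 0, sdv),
                    dim = c(l$k, l$k, l$in_ch, l$out_ch)),
          b = numeric(l$out_ch))
      } else if (l$type == "resblock") {
        sdv <- if (init == "he") sqrt(2 / (9 * l$ch)) else 0.02
        weights[[i]] <- list(
          w1 = array(rnorm(9 * l$ch^2, 0, sdv), dim = c(3, 3, l$ch, l$ch)),
          b1 = numeric(l$ch),
          w2 = array(rnorm(9 * l$ch^2, 0, sdv), dim = c(3, 3, l$ch, l$ch)),
          b2 = numeric(l$ch))
      } else {
        weights[[i]] <- list()
      }
    }
    weights
  })
}

act_fwd <- function(x, act) {
  switch(act,
         relu = pmax(x, 0),
         lrelu = pmax(x, 0) + 0.2 * pmin(x, 0),
         sigmoid = 1 / (1 + exp(-x)),
         none = x)
}
# grad wrt pre-activation given output `y` and upstream grad `g`
act_bwd <- function(g, y, act) {
  switch(act,
         relu = g * (y > 0),
         lrelu = g * (0.2 + 0.8 * (y > 0)),
         sigmoid = g * y * (1 - y),
         none = g)
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}
upsample2_bwd <- function(g) {
  d <- dim(g)
  H <- d[1] %/% 2L; W <- d[2] %/% 2L
  # sum each 2x2 block
  g1 <- g[seq(1, d[1], 2), , , , drop = FALSE] + g[seq(2, d[1], 2), , , , drop = FALSE]
  g1[, seq(1, d[2], 2), , , drop = FALSE] + g1[, seq(2, d[2], 2), , , drop = FALSE]
}

# Forward pass. Returns list(out, cache); cache[[i]] holds what layer i's
# backward needs (inputs and activation outputs).
net_forward <- function(net, weights, x, keep_cache = TRUE) {
  cache <- if (keep_cache) vector("list", length(net)) else NULL
  for (i in seq_along(net)) {
    l <- net[[i]]; wt <- weights[[i]]
    if (l$type == "conv") {
      y <- .conv2d_fwd(x, wt$w, wt$b, l$stride, l$pad)
      out <- act_fwd(y, l$act)
      if (keep_cache) cache[[i]] <- list(x = x, out = out)
      x <- out
    } else if (l$type == "resblock") {
      y1 <- .conv2d_fwd(x, wt$w1, wt$b1, 1L, 1L)
      a1 <- pmax(y1, 0)
      y2 <- .conv2d_fwd(a1, wt$w2, wt$b2, 1L, 1L)
      out <- x + y2
      if (keep_cache) cache[[i]] <- list(x = x, a1 = a1)
      x <- out
    } else if (l$type == "upsample") {
      out <- upsample2_fwd(x)
      if (keep_cache) cache[[i]] <- list(dim_in = dim(x))
      x <- out
    } else if (l$type == "gpool") {
      d <- dim(x)
      m <- apply(x, c(3, 4), mean)
      out <- array(m, dim = c(1L, 1L, d[3], d[4]))
      if (keep_cache) cache[[i]] <- list(dim_in = d)
      x <- out
    }
  }
  list(out = x, cache = cache)
}

# Backward pass from upstream gradient `gout` (same dim as net output).
# Returns list(gx = grad wrt input, gw = per-layer weight grads).
net_backward <- function(net, weights, cache, gout, want_weight_grads = TRUE) {
  g <- gout
  gw <- if (want_weight_grads) vector("list", length(net)) else NULL
  for (i in rev(seq_along(net))) {
    l <- net[[i]]; wt <- weights[[i]]; ch <- cache[[i]]
    if (l$type == "conv") {
      gpre <- act_bwd(g, ch$out, l$act)
      if (want_weight_grads) {
        bw <- .conv2d_bwd(ch$x, wt$w, gpre, l$stride, l$pad)
        gw[[i]] <- list(w = bw$gw, b = bw$gb)
        g <- bw$gx
      } else {
        d <- dim(ch$x)
        g <- .conv2d_bwd_input(wt$w, gpre, l$stride, l$pad, d[1], d[2])
      }
    } else if (l$type == "resblock") {
      # out = x + conv2(relu(conv1(x)))
      if (want_weight_grads) {
        bw2 <- .conv2d_bwd(ch$a1, wt$w2, g, 1L, 1L)
        ga1 <- bw2$gx * (ch$a1 > 0)
        bw1 <- .conv2d_bwd(ch$x, wt$w1, ga1, 1L, 1L)
        gw[[i]] <- list(w1 = bw1$gw, b1 = bw1$gb, w2 = bw2$gw, b2 = bw2$gb)
        g <- g + bw1$gx
      } else {
        d <- dim(ch$a1)
        ga1 <- .conv2d_bwd_input(wt$w2, g, 1L, 1L, d[1], d[2]) * (ch$a1 > 0)
        d0 <- dim(ch$x)
        g <- g + .conv2d_bwd_input(wt$w1, ga1, 1L, 1L, d0[1], d0[2])
      }
    } else if (l$type == "upsample") {
      g <- upsample2_bwd(g)
    } else if (l$type == "gpool") {
      d <- ch$dim_in
      g <- array(rep(as.numeric(g) / (d[1] * d[2]), each = d[1] * d[2]),
                 dim = d)
    }
    if (want_weight_grads && is.null(gw[[i]])) gw[[i]] <- list()
  }
  list(gx = g, gw = gw)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(weights) {
  zero_like <- function(w) lapply(w, function(a) if (length(a)) a * 0 else a)
  list(m = lapply(weights, zero_like), v = lapply(weights, zero_like), t = 0L)
}

adam_step <- function(weights, grads, state, lr = 2e-4,
                      beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(weights)) {
    for (nm in names(weights[[i]])) {
      gv <- grads[[i]][[nm]]
      if (is.null(gv)) next
      m <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * gv
      v <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * gv^2
      state$m[[i]][[nm]] <- m
      state$v[[i]][[nm]] <- v
      weights[[i]][[nm]] <- weights[[i]][[nm]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(weights = weights, state = state)
}
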