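#' Generator configuration
#'
#' The generator is an encoder–decoder fully convolutional network: a conv
#' stem, `n_down` stride-2 downsampling convs (the encoder producing the
#' latent representation), `n_residual` residual bottleneck blocks, `n_down`
#' nearest-neighbour-upsample + conv stages (the decoder), and a 1x1 conv
#' head. With `global_residual = TRUE` (the default) the head is linear and
#' predicts a correction added to the input image, and the sum is clamped
#' to `[0, 1]` — the identity mapping is then exactly representable and the
#' network spends its capacity on the sharpening correction, as
#' super-resolution generators do. With `global_residual = FALSE` the head
#' is a sigmoid and the image is reconstructed from the decoder alone.
#' There are no fully connected layers, following the DCGAN convention.
#' Input height and width must be divisible by `2^n_down`.
#'
#' @param base_channels Width of the stem; doubles at each downsampling.
#' @param n_down Number of stride-2 encoder stages.
#' @param n_residual Number of residual bottleneck blocks.
#' @param in_channels,out_channels Image channels (1 for grayscale).
#' @param global_residual Predict a correction to the input rather than the
#'   full image (requires `in_channels == out_channels`).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(base_channels = 16L, n_down = 2L,
                             n_residual = 2L, in_channels = 1L,
                             out_channels = 1L, global_residual = TRUE) {
  stopifnot(base_channels >= 1, n_down >= 1, n_residual >= 0)
  if (global_residual && in_channels != out_channels)
    stop("global_residual needs in_channels == out_channels")
  structure(list(base_channels = as.integer(base_channels),
                 n_down = as.integer(n_down),
                 n_residual = as.integer(n_residual),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 global_residual = isTRUE(global_residual)),
            class = "generator_config")
}

#' Discriminator configuration
#'
#' Four (or `n_down`) stride-2 leaky-ReLU convolutions followed by a global
#' mean pool and a 1x1 conv + sigmoid head giving one real/fake probability
#' per image. Fully convolutional (no dense layers).
#'
#' @param base_channels Width of the first conv; doubles per stage (capped
#'   at 4x).
#' @param n_down Number of stride-2 stages.
#' @param in_channels Image channels.
#' @return Object of class `discriminator_config`.
#' @export
discriminator_config <- function(base_channels = 16L, n_down = 4L,
                                 in_channels = 1L) {
  stopifnot(base_channels >= 1, n_down >= 1)
  structure(list(base_channels = as.integer(base_channels),
                 n_down = as.integer(n_down),
                 in_channels = as.integer(in_channels)),
            class = "discriminator_config")
}

build_generator_net <- function(config) {
  f <- config$base_channels
  net <- list(layer_conv(3, 1, config$in_channels, f, "relu"))
  ch <- f
  for (d in seq_len(config$n_down)) {
    net <- c(net, list(layer_conv(3, 2, ch, ch * 2L, "relu")))
    ch <- ch * 2L
  }
  for (r in seq_len(config$n_residual)) net <- c(net, list(layer_resblock(ch)))
  for (d in seq_len(config$n_down)) {
    net <- c(net, list(layer_upsample(), layer_conv(3, 1, ch, ch %/% 2L, "relu")))
    ch <- ch %/% 2L
  }
  head_act <- if (isTRUE(config$global_residual)) "none" else "sigmoid"
  c(net, list(layer_conv(1, 1, ch, config$out_channels, head_act)))
}

build_discriminator_net <- function(config) {
  f <- config$base_channels
  widths <- pmin(f * 2L^(seq_len(config$n_down) - 1L), f * 4L)
  net <- list()
  ch <- config$in_channels
  for (d in seq_len(config$n_down)) {
    net <- c(net, list(layer_conv(3, 2, ch, widths[d], "lrelu")))
    ch <- widths[d]
  }
  c(net, list(layer_gpool(), layer_conv(1, 1, ch, 1L, "sigmoid")))
}

#' Initialise a generator
#'
#' @param config A [generator_config()].
#' @param seed Integer seed for the weight initialisation (He-scaled
#'   normal, which keeps signal magnitudes stable through the narrow
#'   CPU-scale networks; `init = "dcgan"` gives the normal(0, 0.02)
#'   alternative).
#' @param init `"he"` or `"dcgan"`.
#' @return Object of class `generator`: list(config, net, weights).
#' @export
init_generator <- function(config = generator_config(), seed = 1L,
                           init = "he") {
  net <- build_generator_net(config)
  weights <- init_net_weights(net, seed, init)
  if (isTRUE(config$global_residual)) {
    # zero-init the correction head: the untrained generator is exactly
    # the identity, and training only ever moves it away deliberately
    last <- length(weights)
    weights[[last]]$w[] <- 0
    weights[[last]]$b[] <- 0
  }
  structure(list(config = config, net = net, weights = weights),
            class = "generator")
}

#' Initialise a discriminator
#'
#' @param config A [discriminator_config()].
#' @param seed Integer seed.
#' @param init `"he"` or `"dcgan"`.
#' @return Object of class `discriminator`.
#' @export
init_discriminator <- function(config = discriminator_config(), seed = 2L,
                               init = "he") {
  net <- build_discriminator_net(config)
  structure(list(config = config, net = net,
                 weights = init_net_weights(net, seed, init)),
            class = "discriminator")
}

check_gen_size <- function(batch, n_down) {
  d <- dim(batch)
  div <- 2L^n_down
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop(sprintf(paste0("input size %dx%d incompatible with %d downsampling ",
                        "stages: height and width must be divisible by %d"),
                 d[1], d[2], n_down, div))
  if (d[1] < 32L || d[2] < 32L)
    stop("images entering the model path must be at least 32x32 px")
  invisible(TRUE)
}

#' Run the generator forward
#'
#' @param batch Array (H, W, C, B) with values in `[0, 1]`; H and W must be
#'   divisible by `2^n_down`.
#' @param gen A `generator`.
#' @param keep_cache Keep the activations needed for backpropagation
#'   (training use only).
#' @return The enhanced batch, same dim as the input (plus `cache` attribute
#'   when requested).
#' @export
generate <- function(batch, gen, keep_cache = FALSE) {
  stopifnot(inherits(gen, "generator"))
  check_gen_size(batch, gen$config$n_down)
  fw <- net_forward(gen$net, gen$weights, batch, keep_cache = keep_cache)
  if (isTRUE(gen$config$global_residual)) {
    pre <- batch + fw$out
    out <- pmin(pmax(pre, 0), 1)
    if (keep_cache) {
      attr(out, "cache") <- fw$cache
      # clamp pass-through mask for the backward pass
      attr(out, "residual_mask") <- (pre > 0) & (pre < 1)
    }
  } else {
    out <- fw$out
    if (keep_cache) attr(out, "cache") <- fw$cache
  }
  out
}

# Backward through the generator given dL/d(output); handles the global
# residual head's clamp mask. Returns net_backward()'s result.
generator_backward <- function(gen, x_hat, gout) {
  cache <- attr(x_hat, "cache")
  if (isTRUE(gen$config$global_residual))
    gout <- gout * attr(x_hat, "residual_mask")
  net_backward(gen$net, gen$weights, cache, gout)
}

#' Run the discriminator forward
#'
#' @param batch Array (H, W, C, B).
#' @param disc A `discriminator`.
#' @param keep_cache Keep activations for backpropagation.
#' @return Numeric vector of B probabilities in (0, 1) (with a `cache`
#'   attribute when requested).
#' @export
discriminate <- function(batch, disc, keep_cache = FALSE) {
  stopifnot(inherits(disc, "discriminator"))
  fw <- net_forward(disc$net, disc$weights, batch, keep_cache = keep_cache)
  p <- as.numeric(fw$out)
  if (keep_cache) attr(p, "cache") <- fw$cache
  p
}
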