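#' Perceptual feature extractor
#'
#' The feature and style perceptual losses compare deep feature maps
#' `Phi_i` of the two images. The reference choice in the literature is a
#' VGG network pretrained on ImageNet; pretrained weights cannot be assumed
#' here, so the default extractor is a frozen, seed-fixed random
#' convolutional network with the same tap structure (one relu tap per
#' stage, He-initialised so feature magnitudes are O(1)). Random frozen
#' convolutional features are an established stand-in for trained ones in
#' perceptual objectives. An identity extractor (`Phi_1 = x`) is provided:
#' it reduces the feature loss to the reconstruction loss exactly and makes
#' the style loss testable against a direct Gram-matrix oracle.
#'
#' @param type `"random"` or `"identity"`.
#' @param seed Seed for the random weights (frozen thereafter).
#' @param n_taps Number of feature taps (stages) for the random extractor.
#' @param base_channels Width of the first stage; doubles at stage 2.
#' @param in_channels Expected input channels (gray batches are replicated
#'   to this count automatically).
#' @return Object of class `feature_extractor` with a `descriptor` string
#'   recording provenance, e.g. `"random-cnn-seed17"`.
#' @export
feature_extractor <- function(type = c("random", "identity"), seed = 17L,
                              n_taps = 3L, base_channels = 8L,
                              in_channels = 3L) {
  type <- match.arg(type)
  if (type == "identity") {
    return(structure(list(type = "identity", n_taps = 1L,
                          in_channels = NA_integer_,
                          descriptor = "identity"),
                     class = "feature_extractor"))
  }
  stopifnot(n_taps >= 1)
  ch <- as.integer(base_channels)
  net <- list(layer_conv(3, 1, in_channels, ch, "relu"))
  widths <- ch
  if (n_taps >= 2) {
    net <- c(net, list(layer_conv(3, 2, ch, ch * 2L, "relu")))
    widths <- c(widths, ch * 2L)
    ch <- ch * 2L
  }
  if (n_taps >= 3) for (i in 3:n_taps) {
    net <- c(net, list(layer_conv(3, 2, ch, ch, "relu")))
    widths <- c(widths, ch)
  }
  structure(list(type = "random", net = net,
                 weights = init_net_weights(net, seed, "he"),
                 n_taps = as.integer(n_taps), in_channels = as.integer(in_channels),
                 tap_widths = widths,
                 descriptor = sprintf("random-cnn-seed%d", seed)),
            class = "feature_extractor")
}

# Replicate a 1-channel batch to `ch` channels. Returns list(x, replicated).
replicate_channels <- function(x, ch) {
  d <- dim(x)
  if (is.na(ch) || d[3] == ch) return(list(x = x, replicated = FALSE))
  if (d[3] != 1L) stop("cannot adapt a multi-channel batch to the extractor")
  y <- array(0, dim = c(d[1], d[2], ch, d[4]))
  for (k in seq_len(ch)) y[, , k, ] <- x[, , 1, ]
  list(x = y, replicated = TRUE)
}

#' Extract feature maps
#'
#' @param extractor A [feature_extractor()].
#' @param batch Array (H, W, C, B); single-channel input is replicated to
#'   the extractor's channel count.
#' @param keep_cache Keep activations for backpropagation.
#' @return List of `n_taps` arrays (H_i, W_i, C_i, B); carries attributes
#'   `cache` and `replicated` when `keep_cache`.
#' @export
extract_features <- function(extractor, batch, keep_cache = FALSE) {
  stopifnot(inherits(extractor, "feature_extractor"))
  if (extractor$type == "identity") {
    out <- list(batch)
    if (keep_cache) attr(out, "replicated") <- FALSE
    return(out)
  }
  rep_ <- replicate_channels(batch, extractor$in_channels)
  fw <- net_forward(extractor$net, extractor$weights, rep_$x, keep_cache = TRUE)
  # every layer here is a conv whose activation output is a tap
  feats <- lapply(fw$cache, function(cc) cc$out)
  if (keep_cache) {
    attr(feats, "cache") <- fw$cache
    attr(feats, "replicated") <- rep_$replicated
  }
  feats
}

# Backpropagate gradients at every tap through the extractor to the input
# batch. `tap_grads` is a list parallel to the taps (NULL entries allowed).
extractor_backward <- function(extractor, feats, batch_dim, tap_grads) {
  if (extractor$type == "identity") {
    g <- tap_grads[[1]]
    return(g)
  }
  cache <- attr(feats, "cache")
  replicated <- attr(feats, "replicated")
  net <- extractor$net
  weights <- extractor$weights
  n <- length(net)
  g <- NULL
  for (i in rev(seq_len(n))) {
    ch <- cache[[i]]; l <- net[[i]]
    if (is.null(g)) g <- array(0, dim = dim(ch$out))
    if (!is.null(tap_grads[[i]])) g <- g + tap_grads[[i]]
    gpre <- act_bwd(g, ch$out, l$act)
    d <- dim(ch$x)
    g <- .conv2d_bwd_input(weights[[i]]$w, gpre, l$stride, l$pad, d[1], d[2])
  }
  if (replicated) {
    # grad of replication = sum over replicated channels
    d <- dim(g)
    gs <- array(0, dim = c(d[1], d[2], 1L, d[4]))
    for (k in seq_len(d[3])) gs[, , 1, ] <- gs[, , 1, ] + g[, , k, ]
    g <- gs
  }
  g
}
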