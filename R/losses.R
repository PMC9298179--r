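#' Loss weights for the generator objective
#'
#' The generator loss is the weighted sum
#' `L_G = lambda_rec*L_rec + lambda_feat*L_feat + lambda_style*L_style +
#' lambda_tv*L_tv + lambda_adv_g*L_advG`. The reconstruction term anchors
#' pixel fidelity; the perceptual terms restore texture statistics; the
#' total-variation term suppresses spikey artifacts; the adversarial term
#' pushes outputs onto the manifold of sharp images. Defaults were
#' calibrated once on the synthetic benchmark so that the auxiliary terms
#' are subdominant to reconstruction at typical loss magnitudes (see the
#' methods vignette for the calibration).
#'
#' @param lambda_rec,lambda_feat,lambda_style,lambda_tv,lambda_adv_g
#'   Non-negative weights; at least one must be positive.
#' @return Object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_rec = 1, lambda_feat = 0.01,
                         lambda_style = 1e-5, lambda_tv = 1e-4,
                         lambda_adv_g = 1e-3) {
  w <- c(lambda_rec, lambda_feat, lambda_style, lambda_tv, lambda_adv_g)
  stopifnot(all(w >= 0), any(w > 0))
  structure(list(lambda_rec = lambda_rec, lambda_feat = lambda_feat,
                 lambda_style = lambda_style, lambda_tv = lambda_tv,
                 lambda_adv_g = lambda_adv_g),
            class = "loss_weights")
}

.eps_prob <- 1e-7

#' Adversarial losses (minimisation form)
#'
#' Given discriminator outputs on real images `d_real` and on generated
#' images `d_fake`, returns
#' `l_adv_d = -mean(log d_real + log(1 - d_fake))` (the negated
#' discriminator objective) and the non-saturating generator loss
#' `l_adv_g = -mean(log d_fake)`. Probabilities are clamped to
#' `[1e-7, 1 - 1e-7]` before taking logs.
#'
#' @param d_real,d_fake Numeric vectors of probabilities.
#' @return List with elements `l_adv_d` and `l_adv_g`.
#' @export
adversarial_losses <- function(d_real, d_fake) {
  dr <- pmin(pmax(d_real, .eps_prob), 1 - .eps_prob)
  df <- pmin(pmax(d_fake, .eps_prob), 1 - .eps_prob)
  list(l_adv_d = -mean(log(dr) + log(1 - df)),
       l_adv_g = -mean(log(df)))
}

#' Pixel-wise reconstruction loss
#'
#' `(1 / (B*C*H*W)) * ||x - x_hat||_2^2`, i.e. the mean squared error over
#' all batch entries.
#'
#' @param x,x_hat Arrays of identical dim (H, W, C, B).
#' @return Scalar loss.
#' @export
reconstruction_loss <- function(x, x_hat) {
  if (!identical(dim(x), dim(x_hat))) stop("shape mismatch between x and x_hat")
  mean((x - x_hat)^2)
}

#' Gram matrix of a feature map
#'
#' For a single feature map with `C` channels, unfold it into the
#' `C x (H*W)` matrix `A` and return `A %*% t(A)` — the channel
#' co-occurrence matrix, which discards spatial arrangement.
#'
#' @param features Array (H, W, C) or (H, W, C, 1).
#' @return Symmetric positive-semidefinite `C x C` matrix.
#' @export
gram <- function(features) {
  d <- dim(features)
  if (length(d) == 4L) { stopifnot(d[4] == 1L); dim(features) <- d[1:3]; d <- d[1:3] }
  stopifnot(length(d) == 3L)
  A <- t(matrix(features, d[1] * d[2], d[3]))   # C x (H*W)
  A %*% t(A)
}

#' Feature perceptual loss
#'
#' Sum over extractor taps `i` of
#' `(1 / (B*C_i*H_i*W_i)) * ||Phi_i(x) - Phi_i(x_hat)||_2^2`.
#'
#' @param x,x_hat Arrays of identical dim.
#' @param extractor A [feature_extractor()].
#' @return Scalar loss.
#' @export
feature_loss <- function(x, x_hat, extractor) {
  if (!identical(dim(x), dim(x_hat))) stop("shape mismatch between x and x_hat")
  fx <- extract_features(extractor, x)
  fh <- extract_features(extractor, x_hat)
  sum(vapply(seq_along(fx),
             function(i) mean((fx[[i]] - fh[[i]])^2),
             numeric(1)))
}

#' Style perceptual loss
#'
#' Sum over extractor taps of
#' `(1 / (B*C_i*H_i*W_i)) * ||Gram_i(x) - Gram_i(x_hat)||_F^2`, the Gram
#' matrices computed per batch item and the squared Frobenius norms summed
#' over the batch. The Gram matrices themselves are not normalised (the
#' `1/(BCHW)` factor sits outside the norm); set
#' `normalize_gram = TRUE` for the conventional `1/(C*H*W)` Gram scaling.
#'
#' @param x,x_hat Arrays of identical dim.
#' @param extractor A [feature_extractor()].
#' @param normalize_gram Divide each Gram matrix by `C*H*W` of its tap.
#' @return Scalar loss.
#' @export
style_loss <- function(x, x_hat, extractor, normalize_gram = FALSE) {
  if (!identical(dim(x), dim(x_hat))) stop("shape mismatch between x and x_hat")
  fx <- extract_features(extractor, x)
  fh <- extract_features(extractor, x_hat)
  total <- 0
  for (i in seq_along(fx)) {
    d <- dim(fx[[i]])
    norm_g <- if (normalize_gram) d[1] * d[2] * d[3] else 1
    acc <- 0
    for (b in seq_len(d[4])) {
      gx <- gram(fx[[i]][, , , b, drop = FALSE]) / norm_g
      gh <- gram(fh[[i]][, , , b, drop = FALSE]) / norm_g
      acc <- acc + sum((gx - gh)^2)
    }
    total <- total + acc / (d[4] * d[3] * d[1] * d[2])
  }
  total
}

#' Total-variation regulariser
#'
#' `(1 / (B*C*H*W)) * sum` of squared differences between vertically and
#' horizontally adjacent pixels of the generated batch.
#'
#' @param x_hat Array (H, W, C, B) with H, W >= 2.
#' @return Scalar loss (0 iff every image is constant).
#' @export
tv_loss <- function(x_hat) {
  d <- dim(x_hat)
  if (d[1] < 2L || d[2] < 2L) stop("total variation needs H and W >= 2")
  dh <- x_hat[-1, , , , drop = FALSE] - x_hat[-d[1], , , , drop = FALSE]
  dw <- x_hat[, -1, , , drop = FALSE] - x_hat[, -d[2], , , drop = FALSE]
  (sum(dh^2) + sum(dw^2)) / prod(d)
}

#' Generator total loss
#'
#' Computes every term of the generator objective and their weighted sum.
#'
#' @param x Target batch.
#' @param x_hat Generated batch.
#' @param d_fake Discriminator probabilities on `x_hat`, or `NULL` to skip
#'   the adversarial term (pre-adversarial training phase).
#' @param extractor A [feature_extractor()].
#' @param weights A [loss_weights()].
#' @return A `loss_report`: list with the unweighted terms `l_rec`,
#'   `l_feat`, `l_style`, `l_tv`, `l_adv_g` (NA when skipped) and the
#'   weighted total `l_g_total`.
#' @export
generator_total_loss <- function(x, x_hat, d_fake, extractor,
                                 weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  l_rec <- reconstruction_loss(x, x_hat)
  l_feat <- feature_loss(x, x_hat, extractor)
  l_style <- style_loss(x, x_hat, extractor)
  l_tv <- tv_loss(x_hat)
  l_adv_g <- if (is.null(d_fake)) NA_real_ else adversarial_losses(1, d_fake)$l_adv_g
  total <- weights$lambda_rec * l_rec + weights$lambda_feat * l_feat +
    weights$lambda_style * l_style + weights$lambda_tv * l_tv +
    (if (is.na(l_adv_g)) 0 else weights$lambda_adv_g * l_adv_g)
  structure(list(l_rec = l_rec, l_feat = l_feat, l_style = l_style,
                 l_tv = l_tv, l_adv_g = l_adv_g, l_g_total = total),
            class = "loss_report")
}

# ---- gradients w.r.t. x_hat (training use) ---------------------------------

grad_reconstruction <- function(x, x_hat) {
  2 * (x_hat - x) / length(x)
}

grad_tv <- function(x_hat) {
  d <- dim(x_hat)
  g <- array(0, dim = d)
  dh <- x_hat[-1, , , , drop = FALSE] - x_hat[-d[1], , , , drop = FALSE]
  dw <- x_hat[, -1, , , drop = FALSE] - x_hat[, -d[2], , , drop = FALSE]
  g[-1, , , ] <- g[-1, , , , drop = FALSE] + 2 * dh
  g[-d[1], , , ] <- g[-d[1], , , , drop = FALSE] - 2 * dh
  g[, -1, , ] <- g[, -1, , , drop = FALSE] + 2 * dw
  g[, -d[2], , ] <- g[, -d[2], , , drop = FALSE] - 2 * dw
  g / prod(d)
}

# Combined feature + style gradient through the extractor (one backward
# pass). Either lambda may be zero.
grad_perceptual <- function(x, x_hat, extractor, lambda_feat, lambda_style,
                            normalize_gram = FALSE) {
  fx <- extract_features(extractor, x)
  fh <- extract_features(extractor, x_hat, keep_cache = TRUE)
  tap_grads <- vector("list", length(fh))
  for (i in seq_along(fh)) {
    d <- dim(fh[[i]])
    norm <- d[1] * d[2] * d[3] * d[4]
    g <- array(0, dim = d)
    if (lambda_feat > 0)
      g <- g + lambda_feat * 2 * (fh[[i]] - fx[[i]]) / norm
    if (lambda_style > 0) {
      norm_g <- if (normalize_gram) d[1] * d[2] * d[3] else 1
      for (b in seq_len(d[4])) {
        Ah <- t(matrix(fh[[i]][, , , b], d[1] * d[2], d[3]))  # C x HW
        Ax <- t(matrix(fx[[i]][, , , b], d[1] * d[2], d[3]))
        dG <- (Ah %*% t(Ah) - Ax %*% t(Ax)) / norm_g
        # d/dA ||A A^T - G0||_F^2 = 4 (A A^T - G0) A   (dG symmetric)
        gA <- (4 * lambda_style / (norm_g * norm)) * (dG %*% Ah)
        g[, , , b] <- g[, , , b] + as.numeric(t(gA))
      }
    }
    tap_grads[[i]] <- g
  }
  extractor_backward(extractor, fh, dim(x_hat), tap_grads)
}

# Gradient of the non-saturating generator adversarial loss w.r.t. x_hat,
# backpropagated through a frozen discriminator. `d_fake` must carry the
# forward cache (discriminate(..., keep_cache = TRUE)).
grad_adversarial_g <- function(d_fake, disc, batch_dim) {
  cache <- attr(d_fake, "cache")
  p <- pmin(pmax(as.numeric(d_fake), .eps_prob), 1 - .eps_prob)
  B <- length(p)
  # dL/dp = -1/(B p); clamp regions have zero gradient by convention
  gp <- array(-1 / (B * p), dim = c(1L, 1L, 1L, B))
  bw <- net_backward(disc$net, disc$weights, cache, gp,
                     want_weight_grads = FALSE)
  bw$gx
}
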