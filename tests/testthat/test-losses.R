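test_that("adversarial losses hit their closed-form fixed points", {
  # balanced discriminator: L_D = 2 ln 2, L_G = ln 2, at any batch size
  for (B in c(1, 4, 9)) {
    l <- adversarial_losses(rep(0.5, B), rep(0.5, B))
    expect_equal(l$l_adv_d, 2 * log(2), tolerance = 1e-12)
    expect_equal(l$l_adv_g, log(2), tolerance = 1e-12)
  }
  # perfect discriminator -> L_D ~ 0; fooled discriminator -> L_G ~ 0
  eps <- 1e-7
  l <- adversarial_losses(1 - eps, eps)
  expect_lt(l$l_adv_d, 1e-5)
  l <- adversarial_losses(0.5, 1 - eps)
  expect_lt(l$l_adv_g, 1e-5)
  # exact 0/1 probabilities are clamped, not infinite
  l <- adversarial_losses(c(0, 1), c(0, 1))
  expect_true(all(is.finite(unlist(l))))
})

test_that("reconstruction loss matches its definition and scaling law", {
  x <- array(1, dim = c(2, 2, 1, 1))
  xh <- array(0, dim = c(2, 2, 1, 1))
  expect_equal(reconstruction_loss(x, xh), 1)
  expect_equal(reconstruction_loss(x, x), 0)
  a <- fixture_batch(); b <- fixture_batch(seed = 8)
  expect_equal(reconstruction_loss(a, a + 2 * (b - a)),
               4 * reconstruction_loss(a, b), tolerance = 1e-12)
  expect_equal(reconstruction_loss(a, b), oracle_rec_loss(a, b),
               tolerance = 1e-12)
  expect_error(reconstruction_loss(a, fixture_batch(H = 8)), "mismatch")
})

test_that("gram matrices match the triple-loop oracle", {
  # identity unfolding: 2 channels, one-hot spatial patterns
  f <- array(0, dim = c(2, 1, 2))
  f[1, 1, 1] <- 1; f[2, 1, 2] <- 1
  expect_equal(gram(f), diag(2))
  # single channel: 1x1 Gram = sum of squares
  f1 <- array(rnorm(12), dim = c(3, 4, 1))
  expect_equal(gram(f1)[1, 1], sum(f1^2), tolerance = 1e-12)
  set.seed(9)
  f3 <- array(rnorm(48), dim = c(4, 4, 3))
  G <- gram(f3)
  expect_equal(G, oracle_gram(f3), tolerance = 1e-8)
  expect_equal(G, t(G))
  expect_true(all(eigen(G, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
})

test_that("feature loss reduces to reconstruction loss under identity taps", {
  exi <- feature_extractor("identity")
  a <- fixture_batch(); b <- fixture_batch(seed = 10)
  expect_equal(feature_loss(a, b, exi), reconstruction_loss(a, b),
               tolerance = 1e-12)
  expect_equal(feature_loss(a, a, exi), 0)
})

test_that("feature and style losses match scalar-loop oracles (random CNN)", {
  ex <- feature_extractor("random", seed = 17, n_taps = 3, base_channels = 4)
  a <- fixture_batch(); b <- fixture_batch(seed = 11)
  fa <- extract_features(ex, a); fb <- extract_features(ex, b)
  expect_equal(feature_loss(a, b, ex), oracle_feature_loss(fa, fb),
               tolerance = 1e-6)
  expect_equal(style_loss(a, b, ex), oracle_style_loss(fa, fb),
               tolerance = 1e-6)
  expect_equal(feature_loss(a, a, ex), 0)
  expect_equal(style_loss(a, a, ex), 0)
  # the extractor is frozen: identical inputs give identical features
  expect_identical(extract_features(ex, a), extract_features(ex, a))
})

test_that("style loss ignores spatial arrangement; feature loss does not", {
  exi <- feature_extractor("identity")
  a <- fixture_batch(H = 8, W = 8, B = 1)
  set.seed(3)
  perm <- array(as.numeric(a)[sample(64)], dim = dim(a))
  expect_equal(style_loss(a, perm, exi), 0, tolerance = 1e-10)
  expect_gt(feature_loss(a, perm, exi), 0)
})

test_that("total variation matches hand summation and smoothing lowers it", {
  x <- array(c(0, 1, 0), dim = c(1, 3, 1, 1))
  expect_error(tv_loss(x), "H and W")        # H = 1 has no row neighbours
  x2 <- array(c(0, 1, 0, 0, 1, 0), dim = c(2, 3, 1, 1))
  # rows: 3 zero diffs; cols: (1,1,1,1) squared -> 4; norm = 6
  expect_equal(tv_loss(x2), 4 / 6)
  b <- fixture_batch(H = 24, W = 24)
  expect_equal(tv_loss(b), oracle_tv_loss(b), tolerance = 1e-12)
  expect_equal(tv_loss(array(0.3, dim = c(4, 4, 1, 2))), 0)
  g <- fixture_grid(24)
  blurred <- degrade(g, degradation_spec(blur_sigma = 2, noise_sigma = 0))
  expect_lt(tv_loss(to_batch(list(blurred))), tv_loss(to_batch(list(g))))
})

test_that("the generator total is the lambda-weighted sum of its terms", {
  ex <- feature_extractor("random", seed = 17, n_taps = 2, base_channels = 4)
  a <- fixture_batch(); b <- fixture_batch(seed = 12)
  d_fake <- c(0.3, 0.6)
  w <- loss_weights(lambda_rec = 1, lambda_feat = 0.05, lambda_style = 1e-4,
                    lambda_tv = 1e-4, lambda_adv_g = 1e-3)
  rep_ <- generator_total_loss(a, b, d_fake, ex, w)
  manual <- w$lambda_rec * reconstruction_loss(a, b) +
    w$lambda_feat * feature_loss(a, b, ex) +
    w$lambda_style * style_loss(a, b, ex) +
    w$lambda_tv * tv_loss(b) +
    w$lambda_adv_g * adversarial_losses(0.5, d_fake)$l_adv_g
  expect_equal(rep_$l_g_total, manual, tolerance = 1e-6)
  # doubling every lambda doubles the total
  w2 <- loss_weights(2, 0.1, 2e-4, 2e-4, 2e-3)
  expect_equal(generator_total_loss(a, b, d_fake, ex, w2)$l_g_total,
               2 * rep_$l_g_total, tolerance = 1e-9)
  # rec-only weights reduce the total to the reconstruction loss
  w0 <- loss_weights(1, 0, 0, 0, 0)
  expect_equal(generator_total_loss(a, b, d_fake, ex, w0)$l_g_total,
               reconstruction_loss(a, b), tolerance = 1e-12)
})

test_that("losses are invariant to batch permutation", {
  ex <- feature_extractor("random", seed = 17, n_taps = 2, base_channels = 4)
  a <- fixture_batch(B = 4); b <- fixture_batch(B = 4, seed = 13)
  pa <- a[, , , c(3, 1, 4, 2), drop = FALSE]
  pb <- b[, , , c(3, 1, 4, 2), drop = FALSE]
  expect_equal(reconstruction_loss(a, b), reconstruction_loss(pa, pb),
               tolerance = 1e-12)
  expect_equal(tv_loss(b), tv_loss(pb), tolerance = 1e-12)
  expect_equal(feature_loss(a, b, ex), feature_loss(pa, pb, ex),
               tolerance = 1e-10)
  expect_equal(style_loss(a, b, ex), style_loss(pa, pb, ex),
               tolerance = 1e-10)
})
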