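test_that("full-reference metrics hit their analytic values", {
  # identity
  g <- fixture_grid(96)
  fr <- suppressWarnings(full_reference(g, g))
  expect_equal(fr$nrmse, 0)
  expect_equal(fr$psnr_db, 100)
  expect_equal(as.numeric(fr$ms_ssim), 1)
  # uniform +1/16 offset with a clamp-free fixture: MSE = 1/256
  set.seed(50)
  ref <- matrix(runif(96 * 96, 0, 15 / 16), 96, 96)
  ref[1, 1] <- 0; ref[2, 1] <- 15 / 16        # pin range to [0, 15/16]
  fr2 <- suppressWarnings(full_reference(image_grid(ref + 1 / 16),
                                         image_grid(ref)))
  expect_equal(fr2$psnr_db, 10 * log10(256), tolerance = 1e-9)
  expect_equal(fr2$nrmse, (1 / 16) / (15 / 16), tolerance = 1e-9)
})

test_that("ms-ssim matches the scalar sliding-window oracle", {
  set.seed(51)
  a <- matrix(runif(48 * 48), 48, 48)
  b <- pmin(pmax(a + rnorm(48 * 48, 0, 0.05), 0), 1)
  w2 <- c(0.6, 0.4)
  expect_equal(as.numeric(ms_ssim(a, b, weights = w2)),
               oracle_ms_ssim(a, b, w2), tolerance = 1e-4)
  # symmetry and the identity fixed point
  expect_equal(as.numeric(ms_ssim(a, b, weights = w2)),
               as.numeric(ms_ssim(b, a, weights = w2)), tolerance = 1e-9)
  expect_equal(as.numeric(ms_ssim(a, a, weights = w2)), 1)
})

test_that("ms-ssim reduces scales for small images and records it", {
  g <- fixture_grid(64)
  expect_warning(v <- ms_ssim(g$pixels, g$pixels), "scales")
  expect_lt(attr(v, "scales"), 5)
  big <- matrix(runif(200 * 200), 200, 200)
  expect_silent(v5 <- ms_ssim(big, big))
  expect_equal(attr(v5, "scales"), 5)
})

test_that("entropy matches its closed-form cases", {
  expect_equal(img_entropy(image_grid(matrix(0.5, 16, 16))), 0)
  u <- image_grid(matrix(rep(0:255 / 255, each = 4), 32, 32))
  expect_equal(img_entropy(u), 8)
  half <- image_grid(matrix(c(0, 1), 32, 32))
  expect_equal(img_entropy(half), 1)
  expect_gte(img_entropy(fixture_grid(32)), 0)
})

test_that("mutual information matches joint-table enumeration", {
  # 2x2 hand case: a splits rows, b splits columns -> independent -> I = 0
  a <- image_grid(matrix(c(0, 0, 1, 1), 2, 2))
  b <- image_grid(matrix(c(0, 1, 0, 1), 2, 2))
  la <- c(0, 0, 255, 255); lb <- c(0, 255, 0, 255)
  expect_equal(mutual_information(a, b), oracle_mutual_information(la, lb),
               tolerance = 1e-12)
  expect_equal(mutual_information(a, b), 0, tolerance = 1e-12)
  # perfectly dependent 2x2: I = H = 1 bit
  expect_equal(mutual_information(a, a), 1)
  # general fixture: oracle agreement, symmetry, self-information identity
  g1 <- fixture_grid(24, seed = 52); g2 <- fixture_grid(24, seed = 53)
  l1 <- as.integer(round(g1$pixels * 255)); l2 <- as.integer(round(g2$pixels * 255))
  expect_equal(mutual_information(g1, g2), oracle_mutual_information(l1, l2),
               tolerance = 1e-10)
  expect_equal(mutual_information(g1, g2), mutual_information(g2, g1),
               tolerance = 1e-12)
  expect_equal(mutual_information(g1, g1), img_entropy(g1), tolerance = 1e-12)
  # degenerate marginal: constant image carries no information
  cg <- image_grid(matrix(0.3, 24, 24))
  expect_equal(mutual_information(g1, cg), 0, tolerance = 1e-12)
})

test_that("mutual information respects the entropy bound", {
  for (seed in 54:57) {
    g1 <- fixture_grid(32, seed = seed)
    g2 <- degrade(g1, degradation_spec(blur_sigma = 1, noise_sigma = 0.02,
                                       seed = seed))
    expect_lte(mutual_information(g1, g2),
               min(img_entropy(g1), img_entropy(g2)) + 1e-9)
  }
})

test_that("PSNR and NRMSE are inversely ordered across a blur sweep", {
  g <- synth_sharp_image(tiny_scene(58, size = 96, n_cells = 8))
  psnr <- nrmse <- numeric(4)
  for (i in seq_along(c(0.5, 1, 2, 4))) {
    b <- degrade(g, degradation_spec(blur_sigma = c(0.5, 1, 2, 4)[i],
                                     noise_sigma = 0))
    fr <- suppressWarnings(full_reference(b, g))
    psnr[i] <- fr$psnr_db; nrmse[i] <- fr$nrmse
  }
  expect_identical(order(psnr), rev(order(nrmse)))
})

test_that("resolution formula and recovery of a known band limit", {
  # kc = 1 at 0.65 um/px gives 1.3 um by the formula
  res <- estimate_resolution(fixture_grid(64))
  expect_equal(res$resolution_um, 2 * 0.65 / res$kc)
  # ideal low-pass at normalized cutoff 0.5 is recovered within +-0.1
  bandlimited <- function(n, cutoff, seed) {
    set.seed(seed)
    z <- matrix(rnorm(n * n), n, n)
    F <- fft(z)
    fy <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) / (n / 2)
    rad <- sqrt(outer(fy^2, fy^2, `+`))
    F[rad > cutoff] <- 0
    x <- Re(fft(F, inverse = TRUE)) / (n * n)
    image_grid((x - min(x)) / (max(x) - min(x)))
  }
  for (seed in 1:3) {
    k <- estimate_resolution(bandlimited(128, 0.5, seed))$kc
    expect_gt(k, 0.4); expect_lt(k, 0.6)
  }
})

test_that("resolution estimate is invariant to intensity gain", {
  g <- synth_sharp_image(tiny_scene(59, size = 96, n_cells = 8))
  half <- image_grid(g$pixels * 0.5, pixel_size = g$pixel_size)
  expect_equal(estimate_resolution(g)$kc, estimate_resolution(half)$kc)
  expect_error(estimate_resolution(fixture_grid(32)), "64")
})

test_that("metrics_report assembles the full panel", {
  g <- synth_sharp_image(tiny_scene(60, size = 64))
  b <- degrade(g, degradation_spec(blur_sigma = 2, noise_sigma = 0.01))
  r <- suppressWarnings(metrics_report(b, g))
  expect_named(r, c("nrmse", "psnr_db", "ms_ssim", "mutual_information_bits",
                    "entropy_bits", "kc", "resolution_um"))
  expect_true(all(vapply(r, is.finite, logical(1))))
})
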