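# Small configurations keep these runs to seconds; the scaled-down
# end-to-end benchmark lives in test-acceptance.R.

tiny_dataset <- function(n = 8, seed = 41) {
  build_dataset(n, tiny_scene(size = 32, n_cells = 3),
                degradations = list(blur_sigma = 1.5, noise_sigma = 0.01),
                master_seed = seed)
}

tiny_config <- function(p1 = 4, p2 = 4, p3 = 6, seed = 5, ...) {
  training_config(
    input_size = 32, batch_size = 4,
    steps_phase1_g = p1, steps_phase2_d = p2, steps_phase3_game = p3,
    gen_config = generator_config(base_channels = 4, n_down = 1,
                                  n_residual = 1),
    disc_config = discriminator_config(base_channels = 4, n_down = 2),
    extractor = feature_extractor("random", seed = 17, n_taps = 2,
                                  base_channels = 4),
    seed = seed, ...)
}

test_that("training walks the three phases in order and logs every step", {
  res <- train(tiny_dataset(), tiny_config())
  h <- res$history
  expect_equal(nrow(h), 14)
  expect_identical(h$step, 1:14)
  expect_identical(h$phase, rep(c(1L, 2L, 3L), c(4, 4, 6)))
  # phase 1 logs generator terms only; phase 2 discriminator only
  expect_true(all(is.na(h$l_adv_d[h$phase == 1])))
  expect_true(all(!is.na(h$l_rec[h$phase == 1])))
  expect_true(all(is.na(h$l_rec[h$phase == 2])))
  expect_true(all(!is.na(h$l_adv_d[h$phase == 2])))
  # phase 3 logs everything
  expect_true(all(!is.na(h$l_adv_g[h$phase == 3])))
  expect_equal(res$checkpoint$step, 14)
})

test_that("logged totals equal the lambda-weighted sum of logged terms", {
  cfg <- tiny_config()
  res <- train(tiny_dataset(), cfg)
  h <- res$history[!is.na(res$history$l_g_total), ]
  lw <- cfg$loss_weights
  adv <- ifelse(is.na(h$l_adv_g), 0, lw$lambda_adv_g * h$l_adv_g)
  manual <- lw$lambda_rec * h$l_rec + lw$lambda_feat * h$l_feat +
    lw$lambda_style * h$l_style + lw$lambda_tv * h$l_tv + adv
  expect_equal(h$l_g_total, manual, tolerance = 1e-6)
})

test_that("runs are bit-reproducible from the seed", {
  a <- train(tiny_dataset(), tiny_config(seed = 9))
  b <- train(tiny_dataset(), tiny_config(seed = 9))
  expect_identical(a$checkpoint$gen$weights, b$checkpoint$gen$weights)
  expect_identical(a$checkpoint$disc$weights, b$checkpoint$disc$weights)
  expect_equal(a$history, b$history)
  c_ <- train(tiny_dataset(), tiny_config(seed = 10))
  expect_false(identical(a$checkpoint$gen$weights, c_$checkpoint$gen$weights))
})

test_that("phase 1 freezes the discriminator and phase 2 the generator", {
  ds <- tiny_dataset()
  r1 <- train(ds, tiny_config(p1 = 5, p2 = 0, p3 = 0, seed = 3))
  d_init <- init_discriminator(tiny_config(seed = 3)$disc_config, seed = 4L)
  expect_identical(r1$checkpoint$disc$weights, d_init$weights)
  r2 <- train(ds, tiny_config(p1 = 0, p2 = 5, p3 = 0, seed = 3))
  g_init <- init_generator(tiny_config(seed = 3)$gen_config, seed = 3L)
  expect_identical(r2$checkpoint$gen$weights, g_init$weights)
  # in phase 3 both nets move
  r3 <- train(ds, tiny_config(p1 = 0, p2 = 0, p3 = 5, seed = 3))
  expect_false(identical(r3$checkpoint$gen$weights, g_init$weights))
  expect_false(identical(r3$checkpoint$disc$weights, d_init$weights))
})

test_that("resume reproduces an unsplit run bit for bit", {
  ds <- tiny_dataset()
  full <- train(ds, tiny_config(p1 = 4, p2 = 4, p3 = 8, seed = 6))
  half_cfg <- tiny_config(p1 = 4, p2 = 4, p3 = 2, seed = 6)
  half <- train(ds, half_cfg)
  resumed <- resume(half$checkpoint, ds,
                    tiny_config(p1 = 4, p2 = 4, p3 = 8, seed = 6))
  expect_identical(resumed$checkpoint$gen$weights,
                   full$checkpoint$gen$weights)
  expect_identical(resumed$checkpoint$disc$weights,
                   full$checkpoint$disc$weights)
  expect_equal(resumed$history, full$history)
  # resume lands in the phase the step arithmetic dictates
  expect_identical(resumed$history$phase[11], 3L)
})

test_that("resume rejects incompatible configurations", {
  ds <- tiny_dataset()
  half <- train(ds, tiny_config(p1 = 2, p2 = 2, p3 = 2, seed = 6))
  bad <- tiny_config(p1 = 2, p2 = 2, p3 = 4, seed = 6)
  bad$batch_size <- 2L
  expect_error(resume(half$checkpoint, ds, bad), "batch_size")
  bad2 <- tiny_config(p1 = 2, p2 = 2, p3 = 4, seed = 6)
  bad2$gen_config <- generator_config(base_channels = 8, n_down = 1,
                                      n_residual = 1)
  expect_error(resume(half$checkpoint, ds, bad2), "gen_config")
})

test_that("checkpoints round-trip through disk", {
  d <- withr::local_tempdir()
  res <- train(tiny_dataset(), tiny_config(p1 = 2, p2 = 2, p3 = 2))
  p <- file.path(d, "t.ckpt")
  save_checkpoint(res$checkpoint, p)
  ck <- load_checkpoint(p)
  expect_identical(ck$gen$weights, res$checkpoint$gen$weights)
  saveRDS(list(1), file.path(d, "bad.ckpt"))
  expect_error(load_checkpoint(file.path(d, "bad.ckpt")), "checkpoint")
})
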