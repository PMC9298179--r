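test_that("scene generation is a pure function of spec and seed", {
  s <- tiny_scene(seed = 11)
  expect_identical(synth_sharp_image(s)$pixels, synth_sharp_image(s)$pixels)
  s2 <- tiny_scene(seed = 12)
  expect_false(identical(synth_sharp_image(s)$pixels,
                         synth_sharp_image(s2)$pixels))
})

test_that("empty featureless scene is a constant background", {
  s <- scene_spec(image_size = 64, n_cells = 0, dead_cell_dot_rate = 0,
                  illumination_gradient = 0, texture_amplitude = 0, seed = 1)
  g <- synth_sharp_image(s)
  expect_equal(diff(range(g$pixels)), 0)
})

test_that("bright-pixel fraction tracks the analytic ellipse area", {
  # cells are brighter than background; compare the above-midpoint pixel
  # count with the expected total ellipse area
  s <- scene_spec(image_size = 256, n_cells = 20, cell_radius_range = c(8, 14),
                  cluster_probability = 0, dead_cell_dot_rate = 0,
                  illumination_gradient = 0, texture_amplitude = 0, seed = 5)
  g <- synth_sharp_image(s)
  frac <- mean(g$pixels > 0.45 + 0.125)   # background + half the cell amplitude
  # mean ellipse area with a ~ U(8,14), b = a * U(0.6,1): E[pi a b]
  ea <- pi * mean(replicate(20000, {a <- runif(1, 8, 14); a * a * runif(1, 0.6, 1)}))
  expected <- s$n_cells * ea / 256^2
  expect_gt(frac, expected * 0.5)
  expect_lt(frac, expected * 1.5)
})

test_that("degradation identity spec returns the image unchanged", {
  g <- synth_sharp_image(tiny_scene(2))
  expect_identical(degrade(g, degradation_spec(blur_sigma = 0, noise_sigma = 0,
                                               brightness_scale = 1,
                                               contrast_scale = 1))$pixels,
                   g$pixels)
})

test_that("blur reduces total variation and full-reference quality", {
  g <- synth_sharp_image(tiny_scene(3))
  b <- degrade(g, degradation_spec(blur_sigma = 2, noise_sigma = 0))
  tv0 <- tv_loss(to_batch(list(g)))
  tv1 <- tv_loss(to_batch(list(b)))
  expect_lt(tv1, tv0)
  expect_lt(full_reference(b, g)$psnr_db, full_reference(g, g)$psnr_db)
  expect_gt(estimate_resolution(b)$resolution_um,
            estimate_resolution(g)$resolution_um)
})

test_that("PSNR degrades monotonically with blur strength", {
  for (seed in 1:3) {
    g <- synth_sharp_image(tiny_scene(seed))
    psnr <- vapply(c(0.5, 1, 2, 4), function(s)
      full_reference(degrade(g, degradation_spec(blur_sigma = s,
                                                 noise_sigma = 0)), g)$psnr_db,
      numeric(1))
    expect_true(all(diff(psnr) < 0))
  }
})

test_that("z-stacks record the right span, focus and blur symmetry", {
  st <- simulate_z_stack(tiny_scene(4), n_layers = 11, interval_um = 1.5)
  expect_equal(attr(st, "span_um"), 15)
  expect_equal(attr(st, "focal_index"), 6)
  # symmetric layers have identical blur (noise is off in the stack)
  expect_identical(st[[5]]$meta$degradation$blur_sigma,
                   st[[7]]$meta$degradation$blur_sigma)
  expect_identical(st[[1]]$meta$degradation$blur_sigma,
                   st[[11]]$meta$degradation$blur_sigma)
  # the focal layer is sharpest by the decorrelation metric
  st5 <- simulate_z_stack(tiny_scene(4, size = 128, n_cells = 10),
                          n_layers = 5, interval_um = 18)
  res <- vapply(st5, function(g) estimate_resolution(g)$resolution_um,
                numeric(1))
  expect_equal(which.min(res), attr(st5, "focal_index"))
  # single-layer stack is the sharp scene itself
  st1 <- simulate_z_stack(tiny_scene(4), n_layers = 1, interval_um = 1.5)
  expect_identical(st1[[1]]$pixels, synth_sharp_image(tiny_scene(4))$pixels)
  # even layer count: focal layer is the lower-middle
  st4 <- simulate_z_stack(tiny_scene(4), n_layers = 4, interval_um = 6)
  expect_equal(attr(st4, "focal_index"), 2)
})

test_that("datasets are reproducible from the master seed", {
  a <- build_dataset(5, tiny_scene(), master_seed = 99)
  b <- build_dataset(5, tiny_scene(), master_seed = 99)
  for (i in 1:5) {
    expect_identical(a$pairs[[i]]$input$pixels, b$pairs[[i]]$input$pixels)
    expect_identical(a$pairs[[i]]$target$pixels, b$pairs[[i]]$target$pixels)
  }
  c_ <- build_dataset(5, tiny_scene(), master_seed = 100)
  expect_false(identical(a$pairs[[1]]$input$pixels, c_$pairs[[1]]$input$pixels))
})

test_that("GT targets equal the sharp sources; EGT raises mean entropy", {
  gt <- build_dataset(6, tiny_scene(), target_mode = "GT", master_seed = 3)
  # every GT target is exactly the sharp render of its recorded scene spec
  for (i in seq_along(gt$pairs))
    expect_identical(gt$pairs[[i]]$target$pixels,
                     synth_sharp_image(gt$scene_specs[[i]])$pixels)
  egt <- build_dataset(6, tiny_scene(), target_mode = "EGT", master_seed = 3)
  h_gt <- mean(vapply(gt$pairs, function(p) img_entropy(p$target), numeric(1)))
  h_egt <- mean(vapply(egt$pairs, function(p) img_entropy(p$target), numeric(1)))
  expect_gte(h_egt, h_gt)
  # EGT provenance: inputs identical to the GT dataset, targets enhanced
  expect_identical(egt$pairs[[1]]$input$pixels, gt$pairs[[1]]$input$pixels)
  expect_false(identical(egt$pairs[[1]]$target$pixels,
                         gt$pairs[[1]]$target$pixels))
})

test_that("datasets round-trip through disk (8-bit quantization)", {
  d <- withr::local_tempdir()
  ds <- build_dataset(3, tiny_scene(), master_seed = 21)
  save_dataset(ds, d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  ds2 <- load_dataset(d)
  expect_equal(length(ds2$pairs), 3)
  expect_lt(max(abs(ds2$pairs[[2]]$input$pixels - ds$pairs[[2]]$input$pixels)),
            1 / 255)
})
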