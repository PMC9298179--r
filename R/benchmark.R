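#' Scaled-down synthetic deblurring benchmark
#'
#' The full-scale study conditions (thousands of 256 px brightfield frames,
#' ~10k adversarial steps) are out of reach for a desk-scale CPU run, so
#' the package defines one fixed scaled-down benchmark used by its
#' validation suite: 64 px scenes with about six textured cells each,
#' degraded by Gaussian blur of sigma 2 px (the blur-only degradation the
#' training-pair simulation prescribes); 200 training pairs and 20
#' held-out pairs; a narrow generator
#' (base width 8, 2 downsamplings, 2 residual blocks) trained for
#' 300/300/1500 steps of the three phases at batch size 8. Success is
#' measured on the held-out pairs as the mean PSNR gain of the enhanced
#' images over the blurred inputs and the reduction in mean
#' decorrelation resolution.
#'
#' @param master_seed Seed for the paired dataset (default 7).
#' @param n_train,n_holdout Pair counts.
#' @return `toy_benchmark_dataset()`: list with `train` and `holdout`
#'   `paired_dataset`s.
#' @export
toy_benchmark_dataset <- function(master_seed = 7L, n_train = 200L,
                                  n_holdout = 20L) {
  ds <- build_dataset(
    n_train + n_holdout,
    scene = scene_spec(image_size = 64L, n_cells = 6L,
                       cell_radius_range = c(4, 10),
                       cluster_probability = 0.4,
                       dead_cell_dot_rate = 1,
                       illumination_gradient = 0.08,
                       texture_amplitude = 0.05),
    degradations = list(blur_sigma = 2, noise_sigma = 0,
                        brightness_scale = 1, contrast_scale = 1),
    target_mode = "GT", master_seed = master_seed)
  split_dataset(ds, n_train)
}

split_dataset <- function(ds, n_first) {
  mk <- function(idx) structure(
    list(pairs = ds$pairs[idx], target_mode = ds$target_mode,
         provenance = ds$provenance[idx], scene_specs = ds$scene_specs[idx],
         master_seed = ds$master_seed),
    class = "paired_dataset")
  list(train = mk(seq_len(n_first)),
       holdout = mk(seq(n_first + 1L, length(ds$pairs))))
}

#' @rdname toy_benchmark_dataset
#' @param seed Training seed.
#' @param steps Integer length-3: steps for the three training phases.
#' @return `toy_training_config()`: a [training_config()] for the
#'   benchmark.
#' @export
toy_training_config <- function(seed = 1L, steps = c(300L, 300L, 1500L)) {
  training_config(
    input_size = 64L, batch_size = 8L,
    steps_phase1_g = steps[1], steps_phase2_d = steps[2],
    steps_phase3_game = steps[3],
    lr = 1e-3, lr_game = 2e-4,
    gen_config = generator_config(base_channels = 8L, n_down = 2L,
                                  n_residual = 2L),
    disc_config = discriminator_config(base_channels = 8L, n_down = 3L),
    extractor = feature_extractor("random", seed = 17L, n_taps = 3L,
                                  base_channels = 8L),
    seed = seed)
}

#' Evaluate a trained generator on held-out pairs
#'
#' @param checkpoint A `ciegan_checkpoint` (or generator).
#' @param holdout A `paired_dataset`.
#' @return List with mean PSNR of input and enhanced images against the
#'   targets, the PSNR gain in dB, and mean decorrelation resolutions of
#'   input and enhanced images.
#' @export
evaluate_benchmark <- function(checkpoint, holdout) {
  gen <- if (inherits(checkpoint, "ciegan_checkpoint")) checkpoint$gen else checkpoint
  psnr_in <- psnr_enh <- res_in <- res_enh <- numeric(length(holdout$pairs))
  for (i in seq_along(holdout$pairs)) {
    p <- holdout$pairs[[i]]
    enh <- batch_to_grids(generate(grid_to_batch1(p$input), gen),
                          pixel_size = p$input$pixel_size)[[1]]
    psnr_in[i] <- full_reference(p$input, p$target)$psnr_db
    psnr_enh[i] <- full_reference(enh, p$target)$psnr_db
    res_in[i] <- estimate_resolution(p$input)$resolution_um
    res_enh[i] <- estimate_resolution(enh)$resolution_um
  }
  list(mean_psnr_input = mean(psnr_in), mean_psnr_enhanced = mean(psnr_enh),
       psnr_gain_db = mean(psnr_enh) - mean(psnr_in),
       mean_resolution_input_um = mean(res_in),
       mean_resolution_enhanced_um = mean(res_enh))
}
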