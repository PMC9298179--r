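#' Scene specification for synthetic cell images
#'
#' Describes a sharp synthetic field of view emulating a brightfield
#' monolayer culture: soft-edged textured elliptical cells (optionally
#' clustered), small dark dead-cell dots, a smooth illumination gradient and
#' fine Poisson-like texture. These are the features the enhancement model
#' is trained to preserve and the degradation model is trained to remove.
#'
#' @param image_size Side length in pixels (square images).
#' @param n_cells Number of cells to place.
#' @param cell_radius_range Numeric length-2, min/max semi-major axis in px.
#' @param cluster_probability Probability that a cell is placed adjacent to
#'   an already-placed cell rather than uniformly at random.
#' @param dead_cell_dot_rate Expected number of small dark debris dots per
#'   image (Poisson).
#' @param illumination_gradient Peak-to-trough amplitude of a linear shading
#'   ramp, in intensity units (0 disables).
#' @param texture_amplitude Standard deviation of the smoothed intra-scene
#'   texture (0 disables).
#' @param seed Integer seed; the image is a pure function of the spec.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = 256L, n_cells = 20L,
                       cell_radius_range = c(8, 20),
                       cluster_probability = 0.5,
                       dead_cell_dot_rate = 3,
                       illumination_gradient = 0.1,
                       texture_amplitude = 0.05,
                       seed = 1L) {
  stopifnot(image_size >= 32, n_cells >= 0,
            length(cell_radius_range) == 2L,
            cell_radius_range[1] > 0,
            cell_radius_range[1] <= cell_radius_range[2],
            cluster_probability >= 0, cluster_probability <= 1,
            dead_cell_dot_rate >= 0,
            illumination_gradient >= 0, illumination_gradient <= 0.5,
            texture_amplitude >= 0, texture_amplitude <= 0.5)
  structure(list(image_size = as.integer(image_size),
                 n_cells = as.integer(n_cells),
                 cell_radius_range = as.numeric(cell_radius_range),
                 cluster_probability = cluster_probability,
                 dead_cell_dot_rate = dead_cell_dot_rate,
                 illumination_gradient = illumination_gradient,
                 texture_amplitude = texture_amplitude,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Degradation specification
#'
#' The forward model taking a sharp image to its blurred observation:
#' Gaussian defocus blur, then contrast/brightness attenuation about the
#' image mean (optics and medium), then additive Gaussian read noise, then
#' clamping to `[0, 1]`.
#'
#' @param blur_sigma Gaussian blur sigma in pixels (0 = no blur).
#' @param noise_sigma Additive noise sd on the `[0, 1]` scale, in `[0, 0.2]`.
#' @param brightness_scale Multiplier on the mean level, in `(0, 1]`.
#' @param contrast_scale Multiplier on deviations from the mean, in `(0, 1]`.
#' @param z_offset_layers Optional integer defocus offset in simulated
#'   Z-stack layers (provenance only).
#' @param seed Integer seed for the noise draw.
#' @return Object of class `degradation_spec`.
#' @export
degradation_spec <- function(blur_sigma = 2, noise_sigma = 0.01,
                             brightness_scale = 1, contrast_scale = 1,
                             z_offset_layers = NA_integer_, seed = 1L) {
  stopifnot(blur_sigma >= 0, noise_sigma >= 0, noise_sigma <= 0.2,
            brightness_scale > 0, brightness_scale <= 1,
            contrast_scale > 0, contrast_scale <= 1)
  structure(list(blur_sigma = blur_sigma, noise_sigma = noise_sigma,
                 brightness_scale = brightness_scale,
                 contrast_scale = contrast_scale,
                 z_offset_layers = z_offset_layers, seed = as.integer(seed)),
            class = "degradation_spec")
}

identity_degradation <- function(seed = 1L) {
  degradation_spec(blur_sigma = 0, noise_sigma = 0, brightness_scale = 1,
                   contrast_scale = 1, seed = seed)
}

# Smoothed Gaussian random field: white noise blurred to correlation
# length `scale` px, normalised to unit sd.
smooth_noise_field <- function(n, scale) {
  z <- matrix(rnorm(n * n), n, n)
  z <- gaussian_blur_matrix(z, scale)
  s <- sd(z)
  if (s > 0) z / s else z
}

#' Generate a sharp synthetic cell image
#'
#' @param spec A [scene_spec].
#' @return An [image_grid]; `meta$n_cells_placed` records the number of
#'   cells actually placed (placement retries are bounded).
#' @export
synth_sharp_image <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  n <- spec$image_size
  with_seed(spec$seed, {
    base_level <- 0.45
    img <- matrix(base_level, n, n)

    if (spec$illumination_gradient > 0) {
      theta <- runif(1, 0, 2 * pi)
      gx <- outer(seq(-0.5, 0.5, length.out = n),
                  rep(1, n)) * cos(theta) +
            outer(rep(1, n), seq(-0.5, 0.5, length.out = n)) * sin(theta)
      img <- img + spec$illumination_gradient * gx
    }

    rr <- row(img); cc <- col(img)
    centers <- matrix(numeric(0), ncol = 2)
    placed <- 0L
    for (i in seq_len(spec$n_cells)) {
      a <- runif(1, spec$cell_radius_range[1], spec$cell_radius_range[2])
      b <- a * runif(1, 0.6, 1)
      phi <- runif(1, 0, pi)
      ok <- FALSE
      for (try in 1:20) {
        if (placed > 0L && runif(1) < spec$cluster_probability) {
          anchor <- centers[sample.int(placed, 1L), ]
          cx <- anchor[1] + rnorm(1, 0, 1.5 * a)
          cy <- anchor[2] + rnorm(1, 0, 1.5 * a)
        } else {
          cx <- runif(1, 1, n); cy <- runif(1, 1, n)
        }
        if (cx >= 1 - a && cx <= n + a && cy >= 1 - a && cy <= n + a) { ok <- TRUE; break }
      }
      if (!ok) next
      placed <- placed + 1L
      centers <- rbind(centers, c(cx, cy))
      # signed elliptical distance (1 on the boundary)
      dx <- rr - cx; dy <- cc - cy
      u <-  dx * cos(phi) + dy * sin(phi)
      v <- -dx * sin(phi) + dy * cos(phi)
      d <- sqrt((u / a)^2 + (v / b)^2)
      edge <- 1 / (1 + exp((d - 1) * 8))      # soft membership
      interior <- 0.25 * edge                  # cells brighter than background
      rim <- -0.18 * exp(-((d - 1) / 0.12)^2)  # dark membrane ring
      tex <- if (spec$texture_amplitude > 0)
        spec$texture_amplitude * edge * matrix(rnorm(n * n), n, n) * 0.8 else 0
      img <- img + interior + rim + tex
    }

    n_dots <- rpois(1, spec$dead_cell_dot_rate)
    for (i in seq_len(n_dots)) {
      cx <- runif(1, 3, n - 2); cy <- runif(1, 3, n - 2)
      r0 <- runif(1, 2, 5)
      d <- sqrt((rr - cx)^2 + (cc - cy)^2)
      img <- img - 0.3 * exp(-(d / r0)^2)
    }

    if (spec$texture_amplitude > 0)
      img <- img + spec$texture_amplitude * smooth_noise_field(n, 1.0)

    img <- pmin(pmax(img, 0), 1)
    image_grid(img, meta = list(n_cells_placed = placed,
                                centers = centers))
  })
}

# Gaussian blur on a plain matrix (replicate boundary); sigma in pixels.
# The kernel support is +-3 sigma, truncated (and renormalised) if it would
# exceed the image.
gaussian_blur_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  radius <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  max_r <- min(dim(m))
  if (radius > max_r) radius <- max_r - (1L - max_r %% 2L)  # largest odd <= min dim
  out <- EBImage::gblur(m, sigma = sigma, radius = radius,
                        boundary = "replicate")
  matrix(as.numeric(out), nrow(m), ncol(m))
}

#' Degrade a sharp image into its blurred observation
#'
#' Applies, in order: Gaussian blur, contrast/brightness attenuation about
#' the mean, additive Gaussian noise, clamp to `[0, 1]`. The identity spec
#' (no blur, unit scales, zero noise) returns the input unchanged.
#'
#' @param sharp An [image_grid].
#' @param spec A [degradation_spec].
#' @return An [image_grid] with `meta$degradation` recording the spec.
#' @export
degrade <- function(sharp, spec) {
  assert_grid(sharp)
  stopifnot(inherits(spec, "degradation_spec"))
  x <- sharp$pixels
  x <- gaussian_blur_matrix(x, spec$blur_sigma)
  if (spec$brightness_scale != 1 || spec$contrast_scale != 1) {
    m <- mean(x)
    x <- spec$brightness_scale * m + spec$contrast_scale * (x - m)
  }
  if (spec$noise_sigma > 0) {
    x <- with_seed(spec$seed,
                   x + matrix(rnorm(length(x), 0, spec$noise_sigma), nrow(x)))
  }
  x <- pmin(pmax(x, 0), 1)
  image_grid(x, pixel_size = sharp$pixel_size,
             bit_depth_origin = sharp$bit_depth_origin,
             meta = c(sharp$meta, list(degradation = spec)))
}

#' Simulate a defocus Z-stack of one scene
#'
#' Returns `n_layers` views of the same synthetic scene with blur growing
#' linearly in the axial distance from the focal layer:
#' `sigma_px = defocus_slope * |z - z_focus| / pixel_size`. For an even
#' number of layers the lower-middle layer is the focal one.
#'
#' @param spec A [scene_spec].
#' @param n_layers Number of layers (>= 1).
#' @param interval_um Axial spacing between layers in micrometres.
#' @param pixel_size Micrometres per pixel.
#' @param defocus_slope Blur sigma (px) gained per micrometre of defocus,
#'   scaled by the pixel size; default 0.15.
#' @return List of [image_grid]s; each carries `meta$z_um` (axial offset)
#'   and the list carries attributes `span_um` and `focal_index`.
#' @export
simulate_z_stack <- function(spec, n_layers, interval_um, pixel_size = 0.65,
                             defocus_slope = 0.15) {
  stopifnot(n_layers >= 1, interval_um > 0)
  sharp <- synth_sharp_image(spec)
  sharp$pixel_size <- pixel_size
  focal <- (n_layers + 1L) %/% 2L   # lower-middle for even counts
  layers <- lapply(seq_len(n_layers), function(i) {
    dz <- abs(i - focal) * interval_um
    sig <- defocus_slope * dz / pixel_size
    g <- degrade(sharp, degradation_spec(blur_sigma = sig, noise_sigma = 0,
                                         z_offset_layers = i - focal,
                                         seed = spec$seed + i))
    g$meta$z_um <- (i - focal) * interval_um
    g
  })
  attr(layers, "span_um") <- (n_layers - 1) * interval_um
  attr(layers, "focal_index") <- focal
  layers
}

#' Build a paired degraded/sharp dataset
#'
#' Generates `n_pairs` independent scenes from a template [scene_spec]
#' (per-pair seeds derived from `master_seed`), degrades each with
#' parameters sampled from the given ranges, and pairs the degraded image
#' with either the sharp source (`target_mode = "GT"`) or its classical
#' enhancement (`target_mode = "EGT"`, see [traditional_enhance()]).
#'
#' @param n_pairs Number of pairs.
#' @param scene Template [scene_spec]; its seed field is ignored.
#' @param degradations Named list of sampling ranges, each a length-2
#'   numeric `c(lo, hi)` (a scalar fixes the value): `blur_sigma`,
#'   `noise_sigma`, `brightness_scale`, `contrast_scale`.
#' @param target_mode `"GT"` or `"EGT"`.
#' @param master_seed Integer; the dataset is a pure function of
#'   (arguments, master_seed).
#' @param te_params [enhance_params()] used when `target_mode = "EGT"`.
#' @return Object of class `paired_dataset`: list with elements `pairs`
#'   (list of `list(input, target)`), `target_mode`, `provenance`
#'   (per-pair [degradation_spec]s) and `scene_specs`.
#' @export
build_dataset <- function(n_pairs, scene = scene_spec(),
                          degradations = list(blur_sigma = c(1, 3),
                                              noise_sigma = 0.01,
                                              brightness_scale = c(0.9, 1),
                                              contrast_scale = c(0.8, 1)),
                          target_mode = c("GT", "EGT"),
                          master_seed = 1L,
                          te_params = enhance_params()) {
  stopifnot(n_pairs >= 1)
  target_mode <- match.arg(target_mode)
  draw <- function(range, u) {
    if (length(range) == 1L) range else range[1] + u * (range[2] - range[1])
  }
  defaults <- list(blur_sigma = 2, noise_sigma = 0.01,
                   brightness_scale = 1, contrast_scale = 1)
  degradations <- modifyList(defaults, degradations)

  tab <- with_seed(master_seed, {
    data.frame(seed_scene = sample.int(.Machine$integer.max - 1L, n_pairs),
               seed_noise = sample.int(.Machine$integer.max - 1L, n_pairs),
               u_blur = runif(n_pairs), u_noise = runif(n_pairs),
               u_bright = runif(n_pairs), u_contrast = runif(n_pairs))
  })

  pairs <- vector("list", n_pairs)
  provenance <- vector("list", n_pairs)
  scene_specs <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    sc <- scene; sc$seed <- tab$seed_scene[i]
    sharp <- synth_sharp_image(sc)
    dspec <- degradation_spec(
      blur_sigma = draw(degradations$blur_sigma, tab$u_blur[i]),
      noise_sigma = draw(degradations$noise_sigma, tab$u_noise[i]),
      brightness_scale = draw(degradations$brightness_scale, tab$u_bright[i]),
      contrast_scale = draw(degradations$contrast_scale, tab$u_contrast[i]),
      seed = tab$seed_noise[i])
    input <- degrade(sharp, dspec)
    target <- if (target_mode == "EGT") traditional_enhance(sharp, te_params) else sharp
    pairs[[i]] <- list(input = input, target = target)
    provenance[[i]] <- dspec
    scene_specs[[i]] <- sc
  }
  structure(list(pairs = pairs, target_mode = target_mode,
                 provenance = provenance, scene_specs = scene_specs,
                 te_params = if (target_mode == "EGT") te_params else NULL,
                 master_seed = as.integer(master_seed)),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  d <- dim(x$pairs[[1]]$input$pixels)
  cat(sprintf("<paired_dataset: %d pairs, %dx%d px, targets = %s>\n",
              length(x$pairs), d[1], d[2], x$target_mode))
  invisible(x)
}

#' @export
length.paired_dataset <- function(x) length(x$pairs)

#' Write a paired dataset to disk as PNGs plus a JSON manifest
#'
#' Files follow the naming convention `pair####__input.png` /
#' `pair####__target.png`.
#'
#' @param dataset A `paired_dataset`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
save_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$pairs)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    fi <- sprintf("pair%04d__input.png", i)
    ft <- sprintf("pair%04d__target.png", i)
    write_image(dataset$pairs[[i]]$input, file.path(dir, fi))
    write_image(dataset$pairs[[i]]$target, file.path(dir, ft))
    entries[[i]] <- list(input = fi, target = ft,
                         degradation = unclass(dataset$provenance[[i]]))
  }
  manifest <- list(n_pairs = n, target_mode = dataset$target_mode,
                   master_seed = dataset$master_seed, pairs = entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a paired dataset written by [save_dataset()]
#'
#' @param dir Directory containing `manifest.json`.
#' @return A `paired_dataset` (8-bit quantised images).
#' @export
load_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  pairs <- lapply(manifest$pairs, function(e) {
    list(input = read_image(file.path(dir, e$input)),
         target = read_image(file.path(dir, e$target)))
  })
  structure(list(pairs = pairs, target_mode = manifest$target_mode,
                 provenance = lapply(manifest$pairs, function(e) e$degradation),
                 master_seed = manifest$master_seed),
            class = "paired_dataset")
}
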