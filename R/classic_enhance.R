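#' Parameters for the classical enhancement baseline
#'
#' The traditional-enhancement (TE) baseline is unsharp masking (sharpness)
#' followed by contrast-limited adaptive histogram equalisation (contrast).
#' The same operator applied to ground-truth images produces the enhanced
#' ground truth (EGT) used to train the CIEGANP variant.
#'
#' @param unsharp_radius Gaussian sigma of the unsharp blur, px.
#' @param unsharp_amount High-pass gain (0 = identity).
#' @param clahe_clip_limit Histogram clip limit as a fraction of the tile
#'   pixel count per bin (0.01 is a mild, standard setting).
#' @param clahe_tiles Number of CLAHE tiles per image side.
#' @return Object of class `enhance_params`.
#' @export
enhance_params <- function(unsharp_radius = 2, unsharp_amount = 1,
                           clahe_clip_limit = 0.01, clahe_tiles = 8L) {
  stopifnot(unsharp_radius > 0, unsharp_amount >= 0,
            clahe_clip_limit > 0, clahe_tiles >= 1)
  structure(list(unsharp_radius = unsharp_radius,
                 unsharp_amount = unsharp_amount,
                 clahe_clip_limit = clahe_clip_limit,
                 clahe_tiles = as.integer(clahe_tiles)),
            class = "enhance_params")
}

#' Unsharp masking
#'
#' `out = clamp(img + amount * (img - gaussian_blur(img, radius)))`: adds a
#' scaled high-pass back to the image, steepening edges (with the usual
#' overshoot/undershoot bracketing them).
#'
#' @param img An [image_grid].
#' @param radius Gaussian sigma in px.
#' @param amount High-pass gain (>= 0).
#' @return An [image_grid].
#' @export
unsharp_mask <- function(img, radius = 2, amount = 1) {
  assert_grid(img)
  stopifnot(radius > 0, amount >= 0)
  x <- img$pixels
  lo <- gaussian_blur_matrix(x, radius)
  out <- pmin(pmax(x + amount * (x - lo), 0), 1)
  image_grid(out, pixel_size = img$pixel_size,
             bit_depth_origin = img$bit_depth_origin, meta = img$meta)
}

#' Contrast-limited adaptive histogram equalisation
#'
#' Per-tile clipped-histogram equalisation with bilinear interpolation
#' between tile mappings. If the image is too small for the requested tile
#' grid the tile count is reduced with a warning.
#'
#' @param img An [image_grid].
#' @param clip_limit Clip limit as a fraction of tile pixels per bin.
#' @param tiles Tiles per side.
#' @param bins Number of histogram bins.
#' @return An [image_grid] in `[0, 1]`.
#' @export
clahe <- function(img, clip_limit = 0.01, tiles = 8L, bins = 256L) {
  assert_grid(img)
  stopifnot(clip_limit > 0, tiles >= 1)
  x <- img$pixels
  if (diff(range(x)) == 0) return(img)   # degenerate mapping: constant in/out
  # EBImage requires tile sides to be even and >= 2 px
  max_tiles <- max(1L, min(dim(x)) %/% 2L)
  if (tiles > max_tiles) {
    warning(sprintf("image too small for %d tiles per side; using %d",
                    tiles, max_tiles))
    tiles <- max_tiles
  }
  limit <- clip_limit * bins   # EBImage's limit is relative to the uniform bin level
  out <- EBImage::clahe(x, nx = as.integer(tiles), ny = as.integer(tiles),
                        bins = as.integer(bins), limit = limit)
  out <- matrix(pmin(pmax(as.numeric(out), 0), 1), nrow(x), ncol(x))
  image_grid(out, pixel_size = img$pixel_size,
             bit_depth_origin = img$bit_depth_origin, meta = img$meta)
}

#' Traditional enhancement (unsharp masking + CLAHE)
#'
#' The TE baseline: sharpen first, then equalise contrast. Applied to a
#' ground-truth image this produces the enhanced ground truth (EGT).
#'
#' @param img An [image_grid].
#' @param params An [enhance_params()].
#' @return An [image_grid] with `meta$enhance_params` recording the call.
#' @export
traditional_enhance <- function(img, params = enhance_params()) {
  assert_grid(img)
  stopifnot(inherits(params, "enhance_params"))
  out <- unsharp_mask(img, params$unsharp_radius, params$unsharp_amount)
  out <- clahe(out, params$clahe_clip_limit, params$clahe_tiles)
  out$meta$enhance_params <- params
  out
}
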