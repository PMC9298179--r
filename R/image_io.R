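#' Create an image grid
#'
#' The basic raster container of the package: a single-channel 2-D intensity
#' image stored as a numeric matrix in `[0, 1]`, together with the physical
#' pixel size (micrometres per pixel) and the bit depth of the file it was
#' loaded from. All model, enhancement and metric code operates on this type.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]` (rows = image
#'   height, columns = width).
#' @param pixel_size Physical pixel size in micrometres per pixel. The
#'   default, 0.65, matches a 2048 px camera chip at 10x magnification as
#'   used for long-term brightfield acquisition of cardiomyocyte cultures.
#' @param bit_depth_origin Bit depth of the source file (8 or 16); retained
#'   as provenance only, all computation is on the float scale.
#' @param meta Optional named list of free-form metadata.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(pixels, pixel_size = 0.65, bit_depth_origin = 8L,
                       meta = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("image intensities must be finite")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("image intensities must lie in [0, 1]")
  if (!bit_depth_origin %in% c(8L, 16L))
    stop("`bit_depth_origin` must be 8 or 16")
  structure(
    list(pixels = pixels, pixel_size = as.numeric(pixel_size),
         bit_depth_origin = as.integer(bit_depth_origin), meta = meta),
    class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid %d x %d px, %.3g um/px, range [%.3f, %.3f]>\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.image_grid <- function(x) dim(x$pixels)

is_image_grid <- function(x) inherits(x, "image_grid")

assert_grid <- function(x, arg = deparse(substitute(x))) {
  if (!is_image_grid(x)) stop(sprintf("`%s` must be an image_grid", arg))
  invisible(x)
}

# Rec. 601 luma weights for RGB -> grayscale conversion.
.luma <- c(0.299, 0.587, 0.114)

#' Read a PNG or TIFF image as an image grid
#'
#' Intensities are normalised to `[0, 1]` by dividing integer sample values
#' by `2^bit_depth - 1`; RGB images are collapsed to luminance (Rec. 601
#' weights). An alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param pixel_size Micrometres per pixel to record on the grid.
#' @return An [image_grid].
#' @export
read_image <- function(path, pixel_size = 0.65) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    bits <- 8L
    info <- attr(img, "info")
    if (!is.null(info) && !is.null(info$bit.depth)) bits <- as.integer(info$bit.depth)
    attr(img, "info") <- NULL
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    bits <- attr_bits(path)
    img <- img / (2^bits - 1)
  } else {
    stop(sprintf("unsupported image format '.%s' (PNG or TIFF expected)", ext))
  }
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc >= 3L) {
      img <- .luma[1] * img[, , 1] + .luma[2] * img[, , 2] + .luma[3] * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  img <- pmin(pmax(img, 0), 1)
  if (max(img) == min(img) && max(img) %in% c(0, 1))
    warning("image is constant and saturated")
  image_grid(img, pixel_size = pixel_size, bit_depth_origin = bits)
}

# Bits-per-sample of a TIFF file (readTIFF drops this on as.is reads).
attr_bits <- function(path) {
  info <- tiff::readTIFF(path, payload = FALSE)
  b <- info$bits.per.sample
  if (is.null(b)) 8L else as.integer(b[1])
}

#' Write an image grid to PNG or TIFF
#'
#' Intensities outside `[0, 1]` are clamped with a warning. 8-bit output may
#' be PNG or TIFF; 16-bit output requires TIFF.
#'
#' @param grid An [image_grid].
#' @param path Output path; the extension selects the codec.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(grid, path, bit_depth = 8L) {
  assert_grid(grid)
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  px <- grid$pixels
  if (min(px) < 0 || max(px) > 1) {
    warning("intensities outside [0, 1] clamped on write")
    px <- pmin(pmax(px, 0), 1)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bit_depth == 16L)
      stop("16-bit output requires TIFF (PNG codec writes 8-bit samples)")
    png::writePNG(px, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, where = path, bits.per.sample = as.integer(bit_depth))
  } else {
    stop(sprintf("unsupported output format '.%s'", ext))
  }
  invisible(path)
}

#' Stack image grids into a batch array
#'
#' Produces the 4-D array (H, W, C, B) that flows through the generator,
#' discriminator and loss functions. With `channels = 3` the single gray
#' channel is replicated, as required by 3-channel perceptual extractors.
#'
#' @param grids List of [image_grid]s sharing one height/width.
#' @param channels 1 or 3.
#' @return Numeric array of class `image_batch`, dim `c(H, W, channels, B)`.
#' @export
to_batch <- function(grids, channels = 1L) {
  if (is_image_grid(grids)) grids <- list(grids)
  if (length(grids) == 0L) stop("empty list of grids")
  if (!channels %in% c(1L, 3L)) stop("`channels` must be 1 or 3")
  dims <- vapply(grids, function(g) dim(assert_grid(g)$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all grids must share the same height and width")
  H <- dims[1, 1]; W <- dims[2, 1]; B <- length(grids)
  x <- array(0, dim = c(H, W, channels, B))
  for (b in seq_len(B)) for (ch in seq_len(channels))
    x[, , ch, b] <- grids[[b]]$pixels
  class(x) <- c("image_batch", class(x))
  x
}

#' Split a batch array back into image grids
#'
#' Channels are averaged if the batch has more than one.
#'
#' @param batch Array of dim (H, W, C, B).
#' @param pixel_size Micrometres per pixel to stamp on the grids.
#' @return List of [image_grid]s of length B.
#' @export
batch_to_grids <- function(batch, pixel_size = 0.65) {
  d <- dim(batch)
  stopifnot(length(d) == 4L)
  lapply(seq_len(d[4]), function(b) {
    m <- if (d[3] == 1L) batch[, , 1, b] else apply(batch[, , , b, drop = FALSE], c(1, 2), mean)
    image_grid(pmin(pmax(m, 0), 1), pixel_size = pixel_size)
  })
}

# Internal: grid -> (H, W, 1, 1) array without copy ceremony.
grid_to_batch1 <- function(grid) {
  x <- array(grid$pixels, dim = c(dim(grid$pixels), 1L, 1L))
  x
}
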