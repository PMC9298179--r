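#' Tiling specification for large-image inference
#'
#' A trained generator accepts fixed-divisibility inputs of moderate size;
#' larger images are enhanced by splitting into overlapping tiles, running
#' each through the generator, and reassembling. Overlaps are blended
#' either by linear feathering or by keeping each tile's centre.
#'
#' @param tile_size Tile side in px (default 256).
#' @param overlap Overlap between neighbouring tiles in px
#'   (< `tile_size / 2`).
#' @param blend `"feather"` (linear ramp across the overlap) or
#'   `"crop-center"` (mosaic of tile centres).
#' @return Object of class `tile_spec`.
#' @export
tile_spec <- function(tile_size = 256L, overlap = 32L,
                      blend = c("feather", "crop-center")) {
  blend <- match.arg(blend)
  stopifnot(tile_size >= 32, overlap >= 0, overlap < tile_size / 2)
  structure(list(tile_size = as.integer(tile_size),
                 overlap = as.integer(overlap), blend = blend),
            class = "tile_spec")
}

# Tile start positions covering [1, n] with side `ts` and overlap `ov`;
# the last tile is aligned to the edge.
tile_starts <- function(n, ts, ov) {
  if (ts >= n) return(1L)
  step <- ts - ov
  s <- seq(1L, n - ts, by = step)
  if (tail(s, 1L) + ts - 1L < n) s <- c(s, n - ts + 1L)
  as.integer(s)
}

reflect_pad <- function(m, top, bottom, left, right) {
  H <- nrow(m); W <- ncol(m)
  ri <- c(rev(seq_len(top) + 1L), seq_len(H), H - seq_len(bottom))
  ci <- c(rev(seq_len(left) + 1L), seq_len(W), W - seq_len(right))
  m[ri, ci, drop = FALSE]
}

# 1-D feather weight profile for a tile: ramps 0..1 across the overlap at
# sides that have a neighbour.
feather_profile <- function(ts, ov, at_start, at_end) {
  w <- rep(1, ts)
  if (ov > 0) {
    ramp <- seq_len(ov) / (ov + 1)
    if (at_start) w[seq_len(ov)] <- ramp
    if (at_end) w[ts + 1L - seq_len(ov)] <- ramp
  }
  w
}

# Resolve the model argument: a generator, a checkpoint (or its path), or a
# plain function(batch) -> batch (test hook, e.g. the identity).
resolve_generator <- function(model) {
  if (is.function(model)) return(list(fn = model, n_down = 0L))
  if (is.character(model)) model <- load_checkpoint(model)
  if (inherits(model, "ciegan_checkpoint")) model <- model$gen
  if (inherits(model, "generator"))
    return(list(fn = function(batch) generate(batch, model),
                n_down = model$config$n_down))
  stop("`model` must be a generator, checkpoint, checkpoint path or function")
}

#' Enhance an image of arbitrary size
#'
#' Runs the generator tile-by-tile and reassembles the full-size output.
#' Images smaller than the tile (or not divisible by the generator's
#' downsampling factor) are reflect-padded and cropped back, avoiding the
#' dark-border bias that zero padding would introduce into the
#' no-reference metrics.
#'
#' @param img An [image_grid].
#' @param model A trained `generator`, a `ciegan_checkpoint`, a checkpoint
#'   path, or a function mapping a (H, W, 1, 1) batch to a like batch.
#' @param tiles A [tile_spec()].
#' @return The enhanced [image_grid], same shape as the input.
#' @export
enhance_image <- function(img, model, tiles = tile_spec()) {
  assert_grid(img)
  gen <- resolve_generator(model)
  ts <- tiles$tile_size; ov <- tiles$overlap
  x <- img$pixels
  H <- nrow(x); W <- ncol(x)
  div <- max(1L, 2L^gen$n_down)
  ts_eff <- min(ts, max(32L, div * (min(H, W) %/% div)))
  ts_eff <- div * (ts_eff %/% div)
  pad_b <- max(0L, ts_eff - H)
  pad_r <- max(0L, ts_eff - W)
  xp <- if (pad_b > 0 || pad_r > 0) reflect_pad(x, 0L, pad_b, 0L, pad_r) else x
  Hp <- nrow(xp); Wp <- ncol(xp)
  sr <- tile_starts(Hp, ts_eff, ov)
  sc <- tile_starts(Wp, ts_eff, ov)
  acc <- matrix(0, Hp, Wp)
  wacc <- matrix(0, Hp, Wp)
  for (i in seq_along(sr)) for (j in seq_along(sc)) {
    r0 <- sr[i]; c0 <- sc[j]
    tile <- xp[r0:(r0 + ts_eff - 1L), c0:(c0 + ts_eff - 1L), drop = FALSE]
    batch <- array(tile, dim = c(ts_eff, ts_eff, 1L, 1L))
    out <- gen$fn(batch)
    if (any(!is.finite(out)))
      stop(sprintf("non-finite generator output in tile (%d, %d)", i, j))
    ot <- out[, , 1, 1]
    if (tiles$blend == "feather") {
      wr <- feather_profile(ts_eff, ov, i > 1, i < length(sr))
      wc <- feather_profile(ts_eff, ov, j > 1, j < length(sc))
      wt <- outer(wr, wc)
    } else {
      # crop-center: unit weight on the non-overlap core, hard edges
      wr <- rep(1, ts_eff); wc <- rep(1, ts_eff)
      h <- ov %/% 2L
      if (h > 0) {
        if (i > 1) wr[seq_len(h)] <- 0
        if (i < length(sr)) wr[ts_eff + 1L - seq_len(h)] <- 0
        if (j > 1) wc[seq_len(h)] <- 0
        if (j < length(sc)) wc[ts_eff + 1L - seq_len(h)] <- 0
      }
      wt <- outer(wr, wc)
    }
    idx_r <- r0:(r0 + ts_eff - 1L); idx_c <- c0:(c0 + ts_eff - 1L)
    acc[idx_r, idx_c] <- acc[idx_r, idx_c] + ot * wt
    wacc[idx_r, idx_c] <- wacc[idx_r, idx_c] + wt
  }
  out <- acc / pmax(wacc, .Machine$double.eps)
  out <- out[seq_len(H), seq_len(W), drop = FALSE]
  image_grid(pmin(pmax(out, 0), 1), pixel_size = img$pixel_size,
             bit_depth_origin = img$bit_depth_origin)
}

#' Compare enhancement methods on a paired dataset
#'
#' Computes the full metrics panel (NRMSE, PSNR, MS-SSIM, MI, entropy,
#' decorrelation resolution) against the dataset targets for the raw
#' input, the traditional-enhancement baseline, and any number of trained
#' checkpoints — the quantitative comparison behind an
#' input / TE / CIEGAN / CIEGANP versus GT panel.
#'
#' @param dataset A `paired_dataset`.
#' @param checkpoints Named list of `ciegan_checkpoint`s (or paths);
#'   may be empty for a baseline-only comparison.
#' @param te_params [enhance_params()] for the TE column.
#' @param tiles [tile_spec()] used for checkpoint inference.
#' @return `data.frame` with one row per (method, pair): columns `method`,
#'   `pair`, `nrmse`, `psnr_db`, `ms_ssim`, `mutual_information_bits`,
#'   `entropy_bits`, `resolution_um`.
#' @export
compare_methods <- function(dataset, checkpoints = list(),
                            te_params = enhance_params(),
                            tiles = tile_spec()) {
  stopifnot(inherits(dataset, "paired_dataset"), length(dataset$pairs) >= 1)
  methods <- list(input = function(g) g,
                  TE = function(g) traditional_enhance(g, te_params))
  for (nm in names(checkpoints)) {
    ck <- checkpoints[[nm]]
    if (is.character(ck) && !file.exists(ck)) {
      warning(sprintf("checkpoint '%s' not found; skipped", nm))
      next
    }
    local({
      model <- ck
      methods[[nm]] <<- function(g) enhance_image(g, model, tiles)
    })
  }
  rows <- list()
  for (mi in seq_along(methods)) {
    mname <- names(methods)[mi]
    f <- methods[[mi]]
    for (p in seq_along(dataset$pairs)) {
      pr <- dataset$pairs[[p]]
      est <- f(pr$input)
      rep_ <- metrics_report(est, pr$target)
      rows[[length(rows) + 1L]] <- data.frame(
        method = mname, pair = p, nrmse = rep_$nrmse, psnr_db = rep_$psnr_db,
        ms_ssim = rep_$ms_ssim,
        mutual_information_bits = rep_$mutual_information_bits,
        entropy_bits = rep_$entropy_bits, resolution_um = rep_$resolution_um)
    }
  }
  do.call(rbind, rows)
}

#' Aggregate a comparison table
#'
#' @param comparison Output of [compare_methods()].
#' @return `data.frame` of per-method means and medians of each metric.
#' @export
aggregate_comparison <- function(comparison) {
  metrics <- c("nrmse", "psnr_db", "ms_ssim", "mutual_information_bits",
               "entropy_bits", "resolution_um")
  out <- lapply(split(comparison, comparison$method), function(d) {
    cbind(data.frame(method = d$method[1], n = nrow(d)),
          as.data.frame(as.list(colMeans(d[metrics]))),
          stats::setNames(as.data.frame(as.list(
            vapply(d[metrics], stats::median, numeric(1)))),
            paste0("median_", metrics)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
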