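#' Histogram specification for entropy and mutual information
#'
#' Entropy and mutual information are computed on 8-bit requantised
#' intensities (gray levels 0-255), matching the convention for standard
#' 8-bit grayscale micrographs; logs are base 2 so both are in bits.
#'
#' @param n_bins Number of gray levels (default 256).
#' @return Object of class `histogram_spec`.
#' @export
histogram_spec <- function(n_bins = 256L) {
  stopifnot(n_bins >= 2)
  structure(list(n_bins = as.integer(n_bins)), class = "histogram_spec")
}

quantize_levels <- function(px, n_bins) {
  as.integer(round(px * (n_bins - 1)))
}

#' Full-reference similarity metrics
#'
#' Computes, between a generated image and its reference:
#' * NRMSE: root-mean-square error divided by the reference intensity range;
#' * PSNR: `10 * log10(1 / MSE)` on the `[0, 1]` scale (the identity case,
#'   MSE = 0, is reported as a 100 dB cap so reports stay finite);
#' * MS-SSIM: multi-scale structural similarity (Wang et al. weights
#'   0.0448/0.2856/0.3001/0.2363/0.1333 over 5 dyadic scales, 11x11
#'   Gaussian window, sigma 1.5). Images too small for 5 scales use fewer,
#'   with renormalised weights and a warning; the scale count used is
#'   recorded in the `scales` attribute.
#'
#' @param generated,reference [image_grid]s of equal shape.
#' @return List with `nrmse`, `psnr_db`, `ms_ssim`.
#' @export
full_reference <- function(generated, reference) {
  assert_grid(generated); assert_grid(reference)
  if (!identical(dim(generated$pixels), dim(reference$pixels)))
    stop("shape mismatch")
  err <- generated$pixels - reference$pixels
  mse <- mean(err^2)
  rng <- diff(range(reference$pixels))
  nrmse <- if (rng > 0) sqrt(mse) / rng else NA_real_
  psnr <- if (mse == 0) 100 else min(10 * log10(1 / mse), 100)
  msv <- ms_ssim(generated$pixels, reference$pixels)
  list(nrmse = nrmse, psnr_db = psnr, ms_ssim = msv)
}

# 1-D Gaussian kernel of length 11, sigma 1.5 (SSIM convention).
ssim_window <- function(size = 11L, sigma = 1.5) {
  half <- (size - 1) / 2
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  g / sum(g)
}

# Valid-region separable convolution of a matrix with kernel g (x) g.
sep_conv_valid <- function(m, g) {
  k <- length(g)
  H <- nrow(m); W <- ncol(m)
  # rows
  out <- matrix(0, H - k + 1L, W)
  for (i in seq_len(k)) out <- out + g[i] * m[i:(H - k + i), , drop = FALSE]
  out2 <- matrix(0, H - k + 1L, W - k + 1L)
  for (j in seq_len(k)) out2 <- out2 + g[j] * out[, j:(W - k + j), drop = FALSE]
  out2
}

# SSIM mean luminance and contrast-structure terms for one scale.
ssim_terms <- function(a, b, k1 = 0.01, k2 = 0.03, L = 1) {
  g <- ssim_window()
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  mu_a <- sep_conv_valid(a, g); mu_b <- sep_conv_valid(b, g)
  saa <- sep_conv_valid(a * a, g) - mu_a^2
  sbb <- sep_conv_valid(b * b, g) - mu_b^2
  sab <- sep_conv_valid(a * b, g) - mu_a * mu_b
  l <- (2 * mu_a * mu_b + c1) / (mu_a^2 + mu_b^2 + c1)
  cs <- (2 * sab + c2) / (saa + sbb + c2)
  list(l = mean(l), cs = mean(cs))
}

downsample2 <- function(m) {
  H <- 2L * (nrow(m) %/% 2L); W <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(H), seq_len(W), drop = FALSE]
  (m[seq(1, H, 2), seq(1, W, 2)] + m[seq(2, H, 2), seq(1, W, 2)] +
   m[seq(1, H, 2), seq(2, W, 2)] + m[seq(2, H, 2), seq(2, W, 2)]) / 4
}

#' Multi-scale SSIM on plain matrices
#'
#' @param a,b Numeric matrices in `[0, 1]` of equal shape.
#' @param weights Per-scale exponents (renormalised if fewer scales fit).
#' @return MS-SSIM value (`<= 1`, 1 iff identical); attribute `scales`
#'   records the number of scales used.
#' @export
ms_ssim <- function(a, b, weights = c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)) {
  stopifnot(identical(dim(a), dim(b)))
  n_scales <- length(weights)
  min_side <- min(dim(a))
  # need >= 11 px after the final downsampling
  max_scales <- max(1L, floor(log2(min_side / 11)) + 1L)
  if (max_scales < n_scales) {
    warning(sprintf("image too small for %d MS-SSIM scales; using %d",
                    n_scales, max_scales))
    n_scales <- max_scales
    weights <- weights[seq_len(n_scales)] / sum(weights[seq_len(n_scales)])
  }
  val <- 1
  for (s in seq_len(n_scales)) {
    t <- ssim_terms(a, b)
    if (s < n_scales) {
      val <- val * max(t$cs, 0)^weights[s]
      a <- downsample2(a); b <- downsample2(b)
    } else {
      val <- val * (max(t$l * t$cs, 0))^weights[s]
    }
  }
  attr(val, "scales") <- n_scales
  val
}

#' Information entropy of an image
#'
#' `H = -sum p(x) log2 p(x)` over occupied gray levels after 8-bit
#' requantisation; 0 for a constant image, 8 bits for a uniform occupancy
#' of all 256 levels.
#'
#' @param img An [image_grid].
#' @param hist A [histogram_spec()].
#' @return Entropy in bits.
#' @export
img_entropy <- function(img, hist = histogram_spec()) {
  assert_grid(img)
  lev <- quantize_levels(img$pixels, hist$n_bins)
  p <- tabulate(lev + 1L, nbins = hist$n_bins)
  p <- p[p > 0] / length(lev)
  -sum(p * log2(p))
}

#' Mutual information between two images
#'
#' `I(X; Y) = sum p(x, y) log2( p(x, y) / (p(x) p(y)) )` over the joint
#' gray-level histogram (8-bit requantised). Symmetric and non-negative;
#' `I(a, a)` equals the entropy of `a`.
#'
#' @param a,b [image_grid]s of equal shape.
#' @param hist A [histogram_spec()].
#' @return Mutual information in bits.
#' @export
mutual_information <- function(a, b, hist = histogram_spec()) {
  assert_grid(a); assert_grid(b)
  if (!identical(dim(a$pixels), dim(b$pixels))) stop("shape mismatch")
  n <- hist$n_bins
  la <- quantize_levels(a$pixels, n)
  lb <- quantize_levels(b$pixels, n)
  joint <- table(factor(la, levels = 0:(n - 1)),
                 factor(lb, levels = 0:(n - 1)))
  pxy <- joint / sum(joint)
  px <- rowSums(pxy); py <- colSums(pxy)
  nz <- pxy > 0
  sum(pxy[nz] * log2(pxy[nz] / outer(px, py)[nz]))
}

# Radially binned mask helper: normalized frequency magnitude per FFT bin,
# with 1 = Nyquist.
freq_radius <- function(H, W) {
  fy <- c(seq(0, floor(H / 2)), seq(-(ceiling(H / 2) - 1), -1)) / (H / 2)
  fx <- c(seq(0, floor(W / 2)), seq(-(ceiling(W / 2) - 1), -1)) / (W / 2)
  sqrt(outer(fy^2, fx^2, `+`))
}

# Cosine (Tukey) edge apodization over the outer `frac` of each side.
apodize <- function(m, frac = 0.1) {
  win1 <- function(n) {
    w <- rep(1, n)
    k <- max(2L, round(frac * n))
    ramp <- 0.5 * (1 - cos(pi * (seq_len(k) - 1) / (k - 1)))
    w[seq_len(k)] <- ramp
    w[n + 1 - seq_len(k)] <- ramp
    w
  }
  m * outer(win1(nrow(m)), win1(ncol(m)))
}

# Decorrelation curve d(r): cosine similarity between the image spectrum
# and its phase-normalised, low-pass-masked counterpart, as a function of
# the mask radius r (normalized frequency).
decorrelation_curve <- function(Fk, radii, rad) {
  amp <- Mod(Fk)
  amp2 <- amp^2
  tot2 <- sum(amp2)
  ord <- order(as.numeric(rad))
  rs <- as.numeric(rad)[ord]
  as_ <- as.numeric(amp)[ord]
  ca <- cumsum(as_)       # numerator: sum of |I| inside mask (Re{I conj(In)} = |I|)
  cn <- cumsum(rep(1, length(rs)))  # mask pixel count = sum |In M|^2
  idx <- findInterval(radii, rs)
  num <- ifelse(idx > 0, ca[pmax(idx, 1)], 0)
  cnt <- ifelse(idx > 0, cn[pmax(idx, 1)], 0)
  d <- ifelse(cnt > 0, num / sqrt(tot2 * cnt), 0)
  d
}

# Position of the relevant peak of a decorrelation curve: the highest-
# frequency strict local maximum above a small amplitude floor; NA if the
# curve has no interior local maximum.
curve_peak <- function(radii, d, floor_amp = 0.05) {
  n <- length(d)
  if (n < 3) return(NA_real_)
  loc <- which(d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]) + 1L
  loc <- loc[d[loc] > floor_amp]
  if (!length(loc)) return(NA_real_)
  radii[max(loc)]
}

#' Estimate image resolution by decorrelation analysis
#'
#' Computes the decorrelation curve `d(r)` — the normalised cross-
#' correlation between the image spectrum `I(k)` and its phase-normalised
#' version `I_n(k)` restricted by a circular low-pass mask `M(k, r)` — over
#' `n_radii` mask radii, repeats it for `n_highpass` Gaussian high-pass
#' pre-filterings of the image, and takes the cutoff `kc` as the highest
#' local-maximum frequency over all curves. The resolution is
#' `2 * pixel_size / kc` (smaller is better). If no curve has a local
#' maximum, `kc` falls back to the global-maximum radius of the unfiltered
#' curve and the result is flagged.
#'
#' @param img An [image_grid] (min side >= 64 px) with `pixel_size` set.
#' @param n_radii Number of mask radii in (0, 1].
#' @param n_highpass Number of Gaussian high-pass strengths (geometrically
#'   spaced).
#' @return List with `kc` (normalized frequency, 1 = Nyquist),
#'   `resolution_um`, `fallback` (logical) and `apodized = TRUE`.
#' @export
estimate_resolution <- function(img, n_radii = 50L, n_highpass = 10L) {
  assert_grid(img)
  d <- dim(img$pixels)
  if (min(d) < 64) stop("decorrelation analysis needs a min side of 64 px")
  x <- img$pixels
  x <- x - mean(x)
  x <- apodize(x)
  radii <- seq(1 / n_radii, 1, length.out = n_radii)
  rad <- freq_radius(d[1], d[2])
  inside <- rad <= 1  # analyse within the Nyquist disc
  Fk <- fft(x)
  Fk[!inside] <- 0
  Fk[1, 1] <- 0      # remove DC
  peaks <- numeric(0)
  d0 <- decorrelation_curve(Fk, radii, rad)
  p0 <- curve_peak(radii, d0)
  if (!is.na(p0)) peaks <- p0
  if (n_highpass > 0) {
    sigmas <- exp(seq(log(0.05), log(1), length.out = n_highpass))  # in normalized freq
    for (s in sigmas) {
      Hs <- 1 - exp(-(rad^2) / (2 * s^2))  # Gaussian high-pass in Fourier space
      pk <- curve_peak(radii, decorrelation_curve(Fk * Hs, radii, rad))
      if (!is.na(pk)) peaks <- c(peaks, pk)
    }
  }
  fallback <- length(peaks) == 0
  kc <- if (fallback) radii[which.max(d0)] else max(peaks)
  kc <- max(kc, 1e-6)
  list(kc = kc, resolution_um = 2 * img$pixel_size / kc,
       fallback = fallback, apodized = TRUE)
}

#' Per-image metrics report
#'
#' Convenience wrapper computing the full- and no-reference suite for one
#' generated/reference pair.
#'
#' @param generated,reference [image_grid]s of equal shape.
#' @param hist A [histogram_spec()].
#' @return List with `nrmse`, `psnr_db`, `ms_ssim`,
#'   `mutual_information_bits`, `entropy_bits`, `kc`, `resolution_um`.
#' @export
metrics_report <- function(generated, reference, hist = histogram_spec()) {
  fr <- full_reference(generated, reference)
  res <- estimate_resolution(generated)
  list(nrmse = fr$nrmse, psnr_db = fr$psnr_db,
       ms_ssim = as.numeric(fr$ms_ssim),
       mutual_information_bits = mutual_information(generated, reference, hist),
       entropy_bits = img_entropy(generated, hist),
       kc = res$kc, resolution_um = res$resolution_um)
}
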