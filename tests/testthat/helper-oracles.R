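# Independent scalar-loop oracles used to cross-check the vectorised /
# compiled implementations. These deliberately share no code with R/.

# direct dense 2-D Gaussian convolution, replicate boundary
oracle_gaussian_blur <- function(m, sigma) {
  r <- as.integer(ceiling(3 * sigma))
  k <- outer(dnorm(-r:r, 0, sigma), dnorm(-r:r, 0, sigma))
  k <- k / sum(k)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- 0
    for (a in -r:r) for (b in -r:r) {
      ii <- min(max(i + a, 1L), H); jj <- min(max(j + b, 1L), W)
      s <- s + k[a + r + 1, b + r + 1] * m[ii, jj]
    }
    out[i, j] <- s
  }
  out
}

# Eq.-style scalar reductions over (H, W, C, B) arrays
oracle_rec_loss <- function(x, xh) {
  d <- dim(x); s <- 0
  for (b in seq_len(d[4])) for (c in seq_len(d[3]))
    for (j in seq_len(d[2])) for (i in seq_len(d[1]))
      s <- s + (x[i, j, c, b] - xh[i, j, c, b])^2
  s / prod(d)
}

oracle_tv_loss <- function(xh) {
  d <- dim(xh); s <- 0
  for (b in seq_len(d[4])) for (c in seq_len(d[3])) {
    for (j in seq_len(d[2])) for (i in seq_len(d[1] - 1))
      s <- s + (xh[i + 1, j, c, b] - xh[i, j, c, b])^2
    for (j in seq_len(d[2] - 1)) for (i in seq_len(d[1]))
      s <- s + (xh[i, j + 1, c, b] - xh[i, j, c, b])^2
  }
  s / prod(d)
}

oracle_gram <- function(feat) {   # feat: (H, W, C)
  d <- dim(feat)
  G <- matrix(0, d[3], d[3])
  for (a in seq_len(d[3])) for (b in seq_len(d[3])) {
    s <- 0
    for (j in seq_len(d[2])) for (i in seq_len(d[1]))
      s <- s + feat[i, j, a] * feat[i, j, b]
    G[a, b] <- s
  }
  G
}

# feature/style losses recomputed from extractor feature maps by loops
oracle_feature_loss <- function(fx, fh) {
  total <- 0
  for (i in seq_along(fx)) {
    d <- dim(fx[[i]]); s <- 0
    for (b in seq_len(d[4])) for (c in seq_len(d[3]))
      for (w in seq_len(d[2])) for (h in seq_len(d[1]))
        s <- s + (fx[[i]][h, w, c, b] - fh[[i]][h, w, c, b])^2
    total <- total + s / prod(d)
  }
  total
}

oracle_style_loss <- function(fx, fh) {
  total <- 0
  for (i in seq_along(fx)) {
    d <- dim(fx[[i]]); s <- 0
    for (b in seq_len(d[4])) {
      gx <- oracle_gram(array(fx[[i]][, , , b], d[1:3]))
      gh <- oracle_gram(array(fh[[i]][, , , b], d[1:3]))
      s <- s + sum((gx - gh)^2)
    }
    total <- total + s / prod(d)
  }
  total
}

# single-scale SSIM by explicit per-pixel loops (valid region, 11x11
# Gaussian window, sigma 1.5) and the multi-scale product built from it
oracle_ssim_terms <- function(a, b) {
  g1 <- dnorm(-5:5, 0, 1.5); g1 <- g1 / sum(g1)
  k <- outer(g1, g1)
  c1 <- 0.01^2; c2 <- 0.03^2
  H <- nrow(a); W <- ncol(a)
  ls <- css <- c()
  for (i in 6:(H - 5)) for (j in 6:(W - 5)) {
    wa <- a[(i - 5):(i + 5), (j - 5):(j + 5)]
    wb <- b[(i - 5):(i + 5), (j - 5):(j + 5)]
    mua <- sum(k * wa); mub <- sum(k * wb)
    va <- sum(k * wa^2) - mua^2; vb <- sum(k * wb^2) - mub^2
    cab <- sum(k * wa * wb) - mua * mub
    ls <- c(ls, (2 * mua * mub + c1) / (mua^2 + mub^2 + c1))
    css <- c(css, (2 * cab + c2) / (va + vb + c2))
  }
  list(l = mean(ls), cs = mean(css))
}

oracle_ms_ssim <- function(a, b, weights) {
  n <- length(weights)
  down2 <- function(m) {
    H <- 2 * (nrow(m) %/% 2); W <- 2 * (ncol(m) %/% 2)
    m <- m[1:H, 1:W]
    (m[seq(1, H, 2), seq(1, W, 2)] + m[seq(2, H, 2), seq(1, W, 2)] +
     m[seq(1, H, 2), seq(2, W, 2)] + m[seq(2, H, 2), seq(2, W, 2)]) / 4
  }
  val <- 1
  for (s in seq_len(n)) {
    t <- oracle_ssim_terms(a, b)
    if (s < n) {
      val <- val * max(t$cs, 0)^weights[s]
      a <- down2(a); b <- down2(b)
    } else val <- val * max(t$l * t$cs, 0)^weights[s]
  }
  val
}

# mutual information by explicit joint-table enumeration on quantised levels
oracle_mutual_information <- function(la, lb) {
  n <- length(la)
  tab <- list()
  for (i in seq_len(n)) {
    key <- paste(la[i], lb[i])
    tab[[key]] <- (tab[[key]] %||% 0) + 1
  }
  pa <- table(la) / n; pb <- table(lb) / n
  s <- 0
  for (key in names(tab)) {
    xy <- strsplit(key, " ")[[1]]
    pxy <- tab[[key]] / n
    s <- s + pxy * log2(pxy / (pa[[xy[1]]] * pb[[xy[2]]]))
  }
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small deterministic textured fixture grid
fixture_grid <- function(n = 64, seed = 42) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  m <- 0.5 + 0.3 * sin(outer(seq_len(n), seq_len(n), `+`) / 5) * m
  image_grid(pmin(pmax(m, 0), 1))
}

fixture_batch <- function(H = 16, W = 16, C = 1, B = 2, seed = 7) {
  set.seed(seed)
  array(runif(H * W * C * B), dim = c(H, W, C, B))
}

tiny_scene <- function(seed = 1, size = 64, n_cells = 6) {
  scene_spec(image_size = size, n_cells = n_cells,
             cell_radius_range = c(4, 10), seed = seed)
}
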