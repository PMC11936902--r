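# Shared fixtures and independent oracles. Everything is generated in
# code at test time; no binary fixtures live in the repository.

smallConfig <- function(seed = 1L, nFrames = 5L, ...) {
  phantomConfig(imageSize = 64L, nFrames = nFrames, seed = seed, ...)
}

tinyNetConfig <- function(size = 16L, seed = 1L) {
  netConfig(size, baseChannels = 2L, depth = 2L, seed = seed)
}

randomMask <- function(h, w, p = 0.4, seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  m <- withr_seed(matrix(as.numeric(runif(h * w) < p), h, w))
  m
}

# Quadratic-time oracles for the surface metrics: explicit double loops
# over the boundary (or region) point sets.
bruteBoundary <- function(m) {
  pts <- list()
  H <- nrow(m); W <- ncol(m)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (m[i, j] != 1) next
    nb <- c(if (i > 1) m[i - 1, j] else 0,
            if (i < H) m[i + 1, j] else 0,
            if (j > 1) m[i, j - 1] else 0,
            if (j < W) m[i, j + 1] else 0)
    if (any(nb == 0)) pts[[length(pts) + 1]] <- c(i - 1, j - 1)
  }
  do.call(rbind, pts)
}

bruteDirected <- function(A, B, reduce = max) {
  per <- numeric(nrow(A))
  for (a in seq_len(nrow(A))) {
    best <- Inf
    for (b in seq_len(nrow(B))) {
      d <- sqrt(sum((A[a, ] - B[b, ])^2))
      if (d < best) best <- d
    }
    per[a] <- best
  }
  reduce(per)
}

bruteHausdorff <- function(m1, m2) {
  A <- bruteBoundary(m1); B <- bruteBoundary(m2)
  max(bruteDirected(A, B, max), bruteDirected(B, A, max))
}

bruteAssd <- function(m1, m2) {
  A <- bruteBoundary(m1); B <- bruteBoundary(m2)
  sa <- bruteDirected(A, B, sum); sb <- bruteDirected(B, A, sum)
  (sa + sb) / (nrow(A) + nrow(B))
}

bruteMsd <- function(a, b, scale = 255) {
  tot <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    tot <- tot + ((a[i, j] - b[i, j]) * scale)^2
  tot / length(a)
}

# A connected random blob mask (so boundary metrics are well defined).
blobMask <- function(h, w, seed = 1) {
  set.seed(seed)
  cx <- runif(1, 0.3, 0.7) * w; cy <- runif(1, 0.3, 0.7) * h
  a <- runif(1, 0.15, 0.3) * w; b <- runif(1, 0.15, 0.3) * h
  R <- matrix(0:(h - 1), h, w); C <- matrix(0:(w - 1), h, w, byrow = TRUE)
  (((C - cx) / a)^2 + ((R - cy) / b)^2 <= 1) * 1
}

# Integer-shift oracle for the warper (content sampled at p + (dx, dy),
# zeros outside).
shiftOracle <- function(img, dx, dy) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    si <- i + dy; sj <- j + dx
    if (si >= 1 && si <= H && sj >= 1 && sj <= W) out[i, j] <- img[si, sj]
  }
  out
}

constantField <- function(h, w, dx, dy) {
  displacementField(matrix(dx, h, w), matrix(dy, h, w))
}
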