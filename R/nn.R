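## Minimal convolutional-network machinery.
##
## Layers operate on H x W x C arrays; 3x3 convolutions are evaluated as an
## im2col gather followed by one BLAS matrix product, with hand-derived
## backward passes (checked against finite differences in the test suite).
## This is deliberately small: three fixed architectures (segmenter,
## deformation predictor, denoising autoencoder) share the same encoder /
## decoder blocks, so no general graph engine is needed.

as3d <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

conv3Forward <- function(x, W, b) {
  r <- .conv3ForwardC(x, W, as.numeric(b))
  list(y = r$y, X2 = r$X2, indim = dim(x))
}

conv3Backward <- function(dY, cache, W) {
  d <- cache$indim
  r <- .conv3BackwardC(matrix(dY, d[1] * d[2], ncol(W)), cache$X2, W,
                       d[1], d[2], d[3])
  list(dW = r$dW, db = r$db, dx = r$dx)
}

## Pure-R reference implementations, kept for parity testing of the
## compiled kernels.
conv3ForwardR <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; Cin <- d[3]
  xp <- array(0, c(H + 2L, Wd + 2L, Cin))
  xp[2:(H + 1), 2:(Wd + 1), ] <- x
  X2 <- matrix(0, H * Wd, 9L * Cin)
  k <- 0L
  for (kj in 0:2) for (ki in 0:2) {
    blk <- xp[(1:H) + ki, (1:Wd) + kj, , drop = FALSE]
    X2[, (k * Cin + 1L):((k + 1L) * Cin)] <- blk
    k <- k + 1L
  }
  Y <- X2 %*% W
  Y <- Y + rep(b, each = H * Wd)
  list(y = array(Y, c(H, Wd, ncol(W))), X2 = X2, indim = d)
}

conv3BackwardR <- function(dY, cache, W) {
  d <- cache$indim; H <- d[1]; Wd <- d[2]; Cin <- d[3]
  dYm <- matrix(dY, H * Wd, ncol(W))
  dW <- crossprod(cache$X2, dYm)
  db <- colSums(dYm)
  dX2 <- tcrossprod(dYm, W)
  dxp <- array(0, c(H + 2L, Wd + 2L, Cin))
  k <- 0L
  for (kj in 0:2) for (ki in 0:2) {
    blk <- array(dX2[, (k * Cin + 1L):((k + 1L) * Cin)], c(H, Wd, Cin))
    dxp[(1:H) + ki, (1:Wd) + kj, ] <-
      dxp[(1:H) + ki, (1:Wd) + kj, , drop = FALSE] + blk
    k <- k + 1L
  }
  list(dW = dW, db = db,
       dx = dxp[2:(H + 1), 2:(Wd + 1), , drop = FALSE])
}

conv1Forward <- function(x, W, b) {
  d <- dim(x)
  Xm <- matrix(x, d[1] * d[2], d[3])
  Y <- Xm %*% W
  Y <- Y + rep(b, each = d[1] * d[2])
  list(y = array(Y, c(d[1], d[2], ncol(W))), Xm = Xm, indim = d)
}

conv1Backward <- function(dY, cache, W) {
  d <- cache$indim
  dYm <- matrix(dY, d[1] * d[2], ncol(W))
  list(dW = crossprod(cache$Xm, dYm), db = colSums(dYm),
       dx = array(tcrossprod(dYm, W), d))
}

reluF <- function(x) pmax(x, 0)
reluB <- function(dY, pre) dY * (pre > 0)

sigmoidF <- function(x) 1 / (1 + exp(-x))

avgpool2F <- function(x) {
  d <- dim(x); i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  (x[i1, j1, , drop = FALSE] + x[i1 + 1L, j1, , drop = FALSE] +
     x[i1, j1 + 1L, , drop = FALSE] + x[i1 + 1L, j1 + 1L, , drop = FALSE]) / 4
}

avgpool2B <- function(dY, indim) {
  dx <- array(0, indim)
  i1 <- seq(1L, indim[1], 2L); j1 <- seq(1L, indim[2], 2L)
  g <- dY / 4
  dx[i1, j1, ] <- g; dx[i1 + 1L, j1, ] <- g
  dx[i1, j1 + 1L, ] <- g; dx[i1 + 1L, j1 + 1L, ] <- g
  dx
}

upsample2F <- function(x) {
  d <- dim(x)
  y <- array(0, c(2L * d[1], 2L * d[2], d[3]))
  i1 <- seq(1L, 2L * d[1], 2L); j1 <- seq(1L, 2L * d[2], 2L)
  y[i1, j1, ] <- x; y[i1 + 1L, j1, ] <- x
  y[i1, j1 + 1L, ] <- x; y[i1 + 1L, j1 + 1L, ] <- x
  y
}

upsample2B <- function(dY) {
  d <- dim(dY)
  i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  dY[i1, j1, , drop = FALSE] + dY[i1 + 1L, j1, , drop = FALSE] +
    dY[i1, j1 + 1L, , drop = FALSE] + dY[i1 + 1L, j1 + 1L, , drop = FALSE]
}

concatC <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3]))
  y[, , seq_len(da[3])] <- a
  y[, , da[3] + seq_len(db[3])] <- b
  y
}

## ---- parameter construction ----

CHANNEL_CAP <- 48L

levelChannels <- function(base, l) min(base * 2L^(l - 1L), CHANNEL_CAP)

initConv3 <- function(Cin, Cout, std = NULL) {
  if (is.null(std)) std <- sqrt(2 / (9 * Cin))
  list(W = matrix(stats::rnorm(9 * Cin * Cout, 0, std), 9L * Cin, Cout),
       b = numeric(Cout))
}

initConv1 <- function(Cin, Cout, std = NULL) {
  if (is.null(std)) std <- sqrt(2 / Cin)
  list(W = matrix(stats::rnorm(Cin * Cout, 0, std), Cin, Cout),
       b = numeric(Cout))
}

## U-Net parameters (segmenter: in 1 -> out 1 sigmoid; deformation
## predictor: in 2 -> out 2 linear with near-zero head so training starts
## at the identity transform).
## outLevel: the decoder stops (and the 1x1 head sits) at this encoder
## level; outLevel = 1 is a full-resolution output, outLevel = k emits the
## output at 1/2^(k-1) of the input size, upsampled bilinearly back to
## full resolution by the forward pass. A coarse head (used by the
## deformation predictor) builds the smoothness of breathing-like fields
## into the architecture.
initUNetParams <- function(config, inCh, outCh, headStd, outLevel = 1L) {
  D <- config@depth; base <- config@baseChannels
  stopifnot(outLevel >= 1L, outLevel <= D)
  withSeed(config@seed, {
    enc <- vector("list", D)
    cin <- inCh
    for (l in seq_len(D)) {
      cl <- levelChannels(base, l)
      enc[[l]] <- initConv3(cin, cl)
      cin <- cl
    }
    bottC <- levelChannels(base, D + 1L)
    bott <- initConv3(cin, bottC)
    dec <- vector("list", D)
    cup <- bottC
    for (l in rev(seq_len(D))) {
      if (l < outLevel) break
      cl <- levelChannels(base, l)
      dec[[l]] <- initConv3(cup + cl, cl)
      cup <- cl
    }
    head <- initConv1(levelChannels(base, outLevel), outCh, std = headStd)
    list(enc = enc, bott = bott, dec = dec, head = head)
  })
}

## Lowest decoded level implied by the parameter structure.
paramsOutLevel <- function(params) {
  present <- which(!vapply(params$dec, is.null, logical(1)))
  if (length(present)) min(present) else length(params$dec) + 1L
}

## Autoencoder parameters: plain encoder (no skips) down to a 1-channel
## n x n code, mirrored decoder back to a sigmoid probability map.
initAEParams <- function(config) {
  D <- config@depth; base <- config@baseChannels
  withSeed(config@seed, {
    enc <- vector("list", D)
    cin <- 1L
    for (l in seq_len(D)) {
      cl <- levelChannels(base, l)
      enc[[l]] <- initConv3(cin, cl)
      cin <- cl
    }
    toCode <- initConv1(cin, 1L)
    fromCode <- initConv1(1L, cin)
    dec <- vector("list", D)
    cup <- cin
    for (l in rev(seq_len(D))) {
      cl <- if (l > 1L) levelChannels(base, l - 1L) else base
      dec[[l]] <- initConv3(cup, cl)
      cup <- cl
    }
    head <- initConv1(base, 1L)
    list(enc = enc, toCode = toCode, fromCode = fromCode, dec = dec,
         head = head)
  })
}

## ---- bilinear field upsampling (integer factor, separable) ----

## Interpolation matrix A (n*s x n): output coordinate i samples input at
## (i + 0.5)/s - 0.5 (0-based), clamped at the edges. Upsampling a plane
## is A %*% X %*% t(A); the adjoint (backward) is t(A) %*% dY %*% A.
upsampleMatrixCache <- new.env(parent = emptyenv())

upsampleMatrix <- function(n, s) {
  key <- paste0(n, "x", s)
  if (!is.null(upsampleMatrixCache[[key]])) return(upsampleMatrixCache[[key]])
  A <- matrix(0, n * s, n)
  for (i in seq_len(n * s)) {
    u <- (i - 0.5) / s - 0.5
    r0 <- floor(u); f <- u - r0
    if (r0 < 0) { A[i, 1] <- 1 }
    else if (r0 >= n - 1) { A[i, n] <- 1 }
    else { A[i, r0 + 1] <- 1 - f; A[i, r0 + 2] <- f }
  }
  upsampleMatrixCache[[key]] <- A
  A
}

upsampleBilinearF <- function(x, s) {
  d <- dim(x)
  Ar <- upsampleMatrix(d[1], s); Ac <- upsampleMatrix(d[2], s)
  y <- array(0, c(d[1] * s, d[2] * s, d[3]))
  for (c in seq_len(d[3])) y[, , c] <- Ar %*% x[, , c] %*% t(Ac)
  y
}

upsampleBilinearB <- function(dY, s) {
  d <- dim(dY)
  n1 <- d[1] %/% s; n2 <- d[2] %/% s
  Ar <- upsampleMatrix(n1, s); Ac <- upsampleMatrix(n2, s)
  dx <- array(0, c(n1, n2, d[3]))
  for (c in seq_len(d[3])) dx[, , c] <- t(Ar) %*% dY[, , c] %*% Ac
  dx
}

## ---- U-Net forward / backward ----

unetForward <- function(params, x, headActivation = c("sigmoid", "linear")) {
  headActivation <- match.arg(headActivation)
  cur <- as3d(x)
  D <- length(params$enc)
  outLevel <- paramsOutLevel(params)
  skips <- vector("list", D)
  encCache <- vector("list", D)
  for (l in seq_len(D)) {
    cv <- conv3Forward(cur, params$enc[[l]]$W, params$enc[[l]]$b)
    a <- reluF(cv$y)
    skips[[l]] <- a
    encCache[[l]] <- list(conv = cv, pre = cv$y, pooledFrom = dim(a))
    cur <- avgpool2F(a)
  }
  bv <- conv3Forward(cur, params$bott$W, params$bott$b)
  cur <- reluF(bv$y)
  decCache <- vector("list", D)
  for (l in rev(seq_len(D))) {
    if (l < outLevel) break
    up <- upsample2F(cur)
    cat <- concatC(up, skips[[l]])
    cv <- conv3Forward(cat, params$dec[[l]]$W, params$dec[[l]]$b)
    decCache[[l]] <- list(conv = cv, pre = cv$y, upC = dim(up)[3])
    cur <- reluF(cv$y)
  }
  hv <- conv1Forward(cur, params$head$W, params$head$b)
  act <- if (headActivation == "sigmoid") sigmoidF(hv$y) else hv$y
  stride <- 2L^(outLevel - 1L)
  out <- if (stride > 1L) upsampleBilinearF(act, stride) else act
  list(out = out,
       cache = list(enc = encCache, bott = bv, dec = decCache, head = hv,
                    headActivation = headActivation, outLevel = outLevel,
                    stride = stride, outAct = act))
}

## dOut: gradient on the (full-resolution) network output.
unetBackward <- function(params, cache, dOut) {
  D <- length(params$enc)
  outLevel <- cache$outLevel
  g <- list(enc = vector("list", D), dec = vector("list", D))
  dY <- if (cache$stride > 1L) upsampleBilinearB(dOut, cache$stride) else dOut
  if (cache$headActivation == "sigmoid") {
    s <- cache$outAct
    dY <- dY * s * (1 - s)
  }
  hb <- conv1Backward(dY, cache$head, params$head$W)
  g$head <- list(W = hb$dW, b = hb$db)
  dCur <- hb$dx
  dSkips <- vector("list", D)
  for (l in outLevel:D) {          # dec levels from finest decoded upward
    cb <- conv3Backward(reluB(dCur, cache$dec[[l]]$pre),
                        cache$dec[[l]]$conv, params$dec[[l]]$W)
    g$dec[[l]] <- list(W = cb$dW, b = cb$db)
    upC <- cache$dec[[l]]$upC
    dUp <- cb$dx[, , seq_len(upC), drop = FALSE]
    dSkips[[l]] <- cb$dx[, , upC + seq_len(dim(cb$dx)[3] - upC),
                         drop = FALSE]
    dCur <- upsample2B(dUp)
  }
  bb <- conv3Backward(reluB(dCur, cache$bott$y), cache$bott, params$bott$W)
  g$bott <- list(W = bb$dW, b = bb$db)
  dCur <- bb$dx
  for (l in rev(seq_len(D))) {
    dA <- avgpool2B(dCur, cache$enc[[l]]$pooledFrom)
    if (!is.null(dSkips[[l]])) dA <- dA + dSkips[[l]]
    cb <- conv3Backward(reluB(dA, cache$enc[[l]]$pre),
                        cache$enc[[l]]$conv, params$enc[[l]]$W)
    g$enc[[l]] <- list(W = cb$dW, b = cb$db)
    dCur <- cb$dx
  }
  g
}

## ---- autoencoder forward / backward ----

aeEncodeForward <- function(params, x) {
  cur <- as3d(x)
  D <- length(params$enc)
  encCache <- vector("list", D)
  for (l in seq_len(D)) {
    cv <- conv3Forward(cur, params$enc[[l]]$W, params$enc[[l]]$b)
    a <- reluF(cv$y)
    encCache[[l]] <- list(conv = cv, pre = cv$y, pooledFrom = dim(a))
    cur <- avgpool2F(a)
  }
  tc <- conv1Forward(cur, params$toCode$W, params$toCode$b)
  list(code = tc$y[, , 1L], cache = list(enc = encCache, toCode = tc))
}

## Backward through the encoder only; returns parameter grads and the
## gradient on the input mask (needed when the anatomical constraint is
## backpropagated through a frozen encoder onto the warped mask).
aeEncodeBackward <- function(params, cache, dCode, wantInputGrad = FALSE) {
  D <- length(params$enc)
  g <- list(enc = vector("list", D))
  tb <- conv1Backward(array(dCode, c(dim(dCode), 1L)), cache$toCode,
                      params$toCode$W)
  g$toCode <- list(W = tb$dW, b = tb$db)
  dCur <- tb$dx
  for (l in rev(seq_len(D))) {
    dA <- avgpool2B(dCur, cache$enc[[l]]$pooledFrom)
    cb <- conv3Backward(reluB(dA, cache$enc[[l]]$pre),
                        cache$enc[[l]]$conv, params$enc[[l]]$W)
    g$enc[[l]] <- list(W = cb$dW, b = cb$db)
    dCur <- cb$dx
  }
  if (wantInputGrad) g$dInput <- dCur[, , 1L]
  g
}

aeDecodeForward <- function(params, code) {
  D <- length(params$dec)
  fc <- conv1Forward(array(code, c(dim(code), 1L)), params$fromCode$W,
                     params$fromCode$b)
  cur <- reluF(fc$y)
  decCache <- vector("list", D)
  for (l in rev(seq_len(D))) {
    up <- upsample2F(cur)
    cv <- conv3Forward(up, params$dec[[l]]$W, params$dec[[l]]$b)
    decCache[[l]] <- list(conv = cv, pre = cv$y)
    cur <- reluF(cv$y)
  }
  hv <- conv1Forward(cur, params$head$W, params$head$b)
  out <- sigmoidF(hv$y)
  list(out = out[, , 1L],
       cache = list(fromCode = fc, dec = decCache, head = hv, outAct = out))
}

aeDecodeBackward <- function(params, cache, dOut) {
  D <- length(params$dec)
  s <- cache$outAct
  dY <- array(dOut, dim(s)) * s * (1 - s)
  hb <- conv1Backward(dY, cache$head, params$head$W)
  g <- list(head = list(W = hb$dW, b = hb$db), dec = vector("list", D))
  dCur <- hb$dx
  for (l in seq_len(D)) {
    cb <- conv3Backward(reluB(dCur, cache$dec[[l]]$pre),
                        cache$dec[[l]]$conv, params$dec[[l]]$W)
    g$dec[[l]] <- list(W = cb$dW, b = cb$db)
    dCur <- upsample2B(cb$dx)
  }
  fb <- conv1Backward(reluB(dCur, cache$fromCode$y), cache$fromCode,
                      params$fromCode$W)
  g$fromCode <- list(W = fb$dW, b = fb$db)
  g$dCode <- fb$dx[, , 1L]
  g
}

## ---- structure-wise parameter arithmetic & Adam ----

paramsMap2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    keys <- if (!is.null(names(a)) && all(nzchar(names(a)))) names(a)
            else seq_along(a)
    for (nm in keys) {
      if (is.null(a[[nm]])) next
      out[[nm]] <- paramsMap2(a[[nm]], b[[nm]], f)
    }
    out
  } else f(a, b)
}

paramsMap1 <- function(a, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) {
      if (is.null(a[[nm]])) next
      out[[nm]] <- paramsMap1(a[[nm]], f)
    }
    out
  } else f(a)
}

paramsAdd <- function(a, b) paramsMap2(a, b, `+`)
paramsScale <- function(a, s) paramsMap1(a, function(x) x * s)
paramsZeroLike <- function(a) paramsMap1(a, function(x) x * 0)

## Global-norm gradient clipping: keeps the rare huge BCE spikes from a
## nearly-saturated warped mask from destabilising Adam.
paramsGlobalNorm <- function(g) {
  tot <- 0
  walk <- function(a) {
    if (is.list(a)) lapply(a, walk)
    else tot <<- tot + sum(a^2)
    invisible(NULL)
  }
  walk(g)
  sqrt(tot)
}

adamInit <- function(params) {
  list(m = paramsZeroLike(params), v = paramsZeroLike(params), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, clipNorm = 50) {
  gn <- paramsGlobalNorm(grads)
  if (is.finite(gn) && gn > clipNorm)
    grads <- paramsScale(grads, clipNorm / gn)
  state$t <- state$t + 1L
  state$m <- paramsMap2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- paramsMap2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- paramsMap2(state$m, state$v,
                    function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- paramsMap2(params, upd, `-`)
  list(params = params, state = state)
}
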