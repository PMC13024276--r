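# Minimal neural-network engine for the dual-input classifier.
#
# Convolutions are computed as im2col gathers followed by BLAS matrix
# multiplies; index templates are precomputed per layer geometry and cached
# per batch size. Everything runs in double precision on one CPU core; the
# network is deliberately narrow ("shallow" is the design goal, not a
# compromise).
#
# Array conventions: image activations are arrays dim c(H, W, B, F)
# (position, batch, channel); dense activations are matrices B x units.

# ---- layer geometry -------------------------------------------------------

# im2col index template for a 3x3 kernel, pad 1, stride s on an H x W x C
# input: matrix (Ho*Wo) x (9*C) of linear indices into the zero-padded
# single-image volume (H+2) x (W+2) x C.
.convTemplate <- function(H, W, C, stride) {
  Hp <- H + 2L; Wp <- W + 2L
  Ho <- (H + 2L - 3L) %/% stride + 1L
  Wo <- (W + 2L - 3L) %/% stride + 1L
  io <- rep(seq_len(Ho), Wo)
  jo <- rep(seq_len(Wo), each = Ho)
  r0 <- (io - 1L) * stride
  c0 <- (jo - 1L) * stride
  base <- r0 + c0 * Hp  # 0-based offset of patch top-left (r0+1, c0+1)
  off <- integer(0)
  for (ch in 0:(C - 1L)) for (dj in 0:2L) for (di in 0:2L)
    off <- c(off, di + dj * Hp + ch * Hp * Wp)
  outer(base, off, "+") + 1L
}

.convLayerGeom <- function(H, W, C, filters, stride) {
  Ho <- (H - 1L) %/% stride + 1L
  Wo <- (W - 1L) %/% stride + 1L
  list(H = H, W = W, C = C, F = filters, stride = stride, Ho = Ho, Wo = Wo,
       template = .convTemplate(H, W, C, stride))
}

.batchIndex <- function(geom, B, cache) {
  key <- paste0("g", geom$H, "x", geom$W, "c", geom$C, "s", geom$stride,
                "b", B)
  if (!is.null(cache[[key]])) return(cache[[key]])
  M <- geom$template
  perImage <- (geom$H + 2L) * (geom$W + 2L) * geom$C
  big <- M[rep(seq_len(nrow(M)), B), , drop = FALSE] +
    rep((seq_len(B) - 1L) * perImage, each = nrow(M))
  cache[[key]] <- big
  big
}

.padBatch <- function(A) {
  # A: dim c(H, W, B*C-collapsed?) -- here dim c(H, W, C, B)
  d <- dim(A)
  Ap <- array(0, c(d[1L] + 2L, d[2L] + 2L, d[3L], d[4L]))
  Ap[2:(d[1L] + 1L), 2:(d[2L] + 1L), , ] <- A
  Ap
}

# ---- forward/backward primitives -----------------------------------------

.convForward <- function(A, geom, Wm, b, cache) {
  # A dim c(H, W, C, B) -> list(cols, Z (rows x F), out array c(Ho,Wo,B,F))
  B <- dim(A)[4L]
  Ap <- .padBatch(A)
  idx <- .batchIndex(geom, B, cache)
  cols <- matrix(Ap[idx], nrow(idx), ncol(idx))
  Z <- cols %*% Wm
  Z <- sweep(Z, 2L, b, "+")
  out <- array(pmax(Z, 0), c(geom$Ho, geom$Wo, B, geom$F))
  list(cols = cols, Z = Z, out = out, B = B)
}

.convBackward <- function(fwd, geom, Wm, dOut, cache, needInputGrad = TRUE) {
  # dOut: array c(Ho, Wo, B, F) gradient after relu
  B <- fwd$B
  dZ <- matrix(dOut, nrow(fwd$Z), ncol(fwd$Z))
  dZ[fwd$Z <= 0] <- 0
  dW <- crossprod(fwd$cols, dZ)
  db <- colSums(dZ)
  dA <- NULL
  if (needInputGrad) {
    dcols <- dZ %*% t(Wm)
    idx <- .batchIndex(geom, B, cache)
    dAp <- numeric((geom$H + 2L) * (geom$W + 2L) * geom$C * B)
    for (k in seq_len(ncol(idx))) {
      ii <- idx[, k]
      dAp[ii] <- dAp[ii] + dcols[, k]
    }
    dAp <- array(dAp, c(geom$H + 2L, geom$W + 2L, geom$C, B))
    dA <- dAp[2:(geom$H + 1L), 2:(geom$W + 1L), , , drop = FALSE]
  }
  list(dW = dW, db = db, dA = dA)
}

# fixed average-pooling stem; no parameters, no gradient needed (applied
# directly to the input images)
.avgPoolStem <- function(A, p) {
  d <- dim(A)
  Ho <- d[1L] %/% p; Wo <- d[2L] %/% p
  out <- array(0, c(Ho, Wo, d[3L], d[4L]))
  for (dj in seq_len(p)) for (di in seq_len(p))
    out <- out + A[seq(di, Ho * p, p), seq(dj, Wo * p, p), , ,
                   drop = FALSE]
  out / (p * p)
}

.poolForward <- function(A, p) {
  # A dim c(H, W, B, F); max pool p x p stride p
  d <- dim(A)
  Ho <- d[1L] %/% p; Wo <- d[2L] %/% p
  A <- A[seq_len(Ho * p), seq_len(Wo * p), , , drop = FALSE]
  best <- array(-Inf, c(Ho, Wo, d[3L], d[4L]))
  win <- array(1L, c(Ho, Wo, d[3L], d[4L]))
  k <- 0L
  for (dj in seq_len(p)) for (di in seq_len(p)) {
    k <- k + 1L
    cand <- A[seq(di, Ho * p, p), seq(dj, Wo * p, p), , , drop = FALSE]
    m <- cand > best
    best[m] <- cand[m]
    win[m] <- k
  }
  list(out = best, win = win, inDim = d, p = p)
}

.poolBackward <- function(pf, dOut) {
  d <- pf$inDim; p <- pf$p
  Ho <- dim(pf$out)[1L]; Wo <- dim(pf$out)[2L]
  dA <- array(0, d)
  k <- 0L
  for (dj in seq_len(p)) for (di in seq_len(p)) {
    k <- k + 1L
    m <- pf$win == k
    if (!any(m)) next
    sl <- dA[seq(di, Ho * p, p), seq(dj, Wo * p, p), , , drop = FALSE]
    sl[m] <- dOut[m]
    dA[seq(di, Ho * p, p), seq(dj, Wo * p, p), , ] <- sl
  }
  dA
}

.denseForward <- function(X, Wm, b, relu = TRUE) {
  Z <- sweep(X %*% Wm, 2L, b, "+")
  list(X = X, Z = Z, out = if (relu) pmax(Z, 0) else Z)
}

.denseBackward <- function(fwd, Wm, dOut, relu = TRUE) {
  dZ <- dOut
  if (relu) dZ[fwd$Z <= 0] <- 0
  list(dW = crossprod(fwd$X, dZ), db = colSums(dZ), dX = dZ %*% t(Wm))
}

.dropoutForward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, mask = NULL))
  mask <- matrix(runif(length(X)) >= rate, nrow(X), ncol(X)) / (1 - rate)
  list(out = X * mask, mask = mask)
}

.softmax <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# ---- parameter initialisation and Adam -----------------------------------

.heInit <- function(nin, nout) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

.adamStep <- function(opt, name, g, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.null(opt$m[[name]])) {
    opt$m[[name]] <- g * 0
    opt$v[[name]] <- g * 0
  }
  opt$m[[name]] <- beta1 * opt$m[[name]] + (1 - beta1) * g
  opt$v[[name]] <- beta2 * opt$v[[name]] + (1 - beta2) * g^2
  mhat <- opt$m[[name]] / (1 - beta1^t)
  vhat <- opt$v[[name]] / (1 - beta2^t)
  lr * mhat / (sqrt(vhat) + eps)
}
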