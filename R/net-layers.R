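# Building blocks of the 3D attention U-Net, implemented directly on BLAS
# matrix products with hand-derived backward passes.
#
# Feature tensors are stored as matrices X[nVoxels, channels] in column-major
# voxel order, with the spatial shape carried alongside.  3x3x3 convolutions
# use an im2col gather (precomputed, cached index tables) followed by a single
# matrix multiplication; the backward pass rebuilds the patch matrix from the
# cached padded input, so caches stay small.  All gather/scatter index tables
# are memoised per (shape, stride) pair.

.idxCache <- new.env(parent = emptyenv())
.cachedIdx <- function(key, builder) {
  if (!exists(key, envir = .idxCache)) assign(key, builder(), envir = .idxCache)
  get(key, envir = .idxCache)
}

# im2col index table for a 3x3x3 kernel, zero padding 1, given stride
.convIdx <- function(shape, stride) {
  key <- paste0("conv:", paste(shape, collapse = "x"), ":s", stride)
  .cachedIdx(key, function() {
    ps <- shape + 2L
    outShape <- if (stride == 1L) shape else shape %/% 2L
    # 1-based centre coordinates in the padded grid
    ctr <- lapply(1:3, function(a) {
      o <- seq_len(outShape[a])
      if (stride == 1L) o + 1L else 2L * o
    })
    ox <- rep(ctr[[1]], times = outShape[2] * outShape[3])
    oy <- rep(rep(ctr[[2]], each = outShape[1]), times = outShape[3])
    oz <- rep(ctr[[3]], each = outShape[1] * outShape[2])
    offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    nOut <- prod(outShape)
    idx <- matrix(0L, nOut, 27L)
    for (j in 1:27)
      idx[, j] <- (ox + offs[j, 1]) + ps[1] * (oy + offs[j, 2] - 1L) +
        ps[1] * ps[2] * (oz + offs[j, 3] - 1L)
    # linear indices of the interior (non-pad) voxels of the padded grid
    ii <- rep(seq_len(shape[1]) + 1L, times = shape[2] * shape[3])
    jj <- rep(rep(seq_len(shape[2]) + 1L, each = shape[1]), times = shape[3])
    kk <- rep(seq_len(shape[3]) + 1L, each = shape[1] * shape[2])
    inner <- ii + ps[1] * (jj - 1L) + ps[1] * ps[2] * (kk - 1L)
    list(idx = idx, inner = inner, outShape = outShape, padLen = prod(ps))
  })
}

.pad3 <- function(x, ci) {
  P <- matrix(0, ci$padLen, ncol(x))
  P[ci$inner, ] <- x
  P
}

# Patch matrix M[nOut, 27*Cin] with column order j (offset) fastest within
# each input channel block, i.e. col = j + 27*(c-1): the column-major
# flattening of the gathered [nOut, 27, Cin] array, so no transposition is
# needed.  Weight matrices use matching row order.  The gather and its
# adjoint scatter are the compiled kernels in src/conv_ops.cpp.

# 3x3x3 convolution forward. W: [27*Cin, Cout] (row = j + 27*(c-1)), b: [Cout].
.conv3Fwd <- function(x, shape, W, b, stride = 1L, training = FALSE) {
  cin <- ncol(x)
  ci <- .convIdx(shape, stride)
  P <- .pad3(x, ci)
  M <- .im2colGather(P, ci$idx)
  Y <- M %*% W
  if (any(b != 0)) Y <- sweep(Y, 2L, b, "+")
  cache <- if (training) list(M = M, shape = shape, stride = stride, cin = cin) else NULL
  list(y = Y, shape = ci$outShape, cache = cache)
}

.conv3Bwd <- function(dY, cache, W) {
  ci <- .convIdx(cache$shape, cache$stride)
  dW <- crossprod(cache$M, dY)
  db <- colSums(dY)
  dM <- dY %*% t(W)                                # [nOut, 27*Cin]
  dP <- .col2imScatter(dM, ci$idx, ci$padLen, cache$cin)
  dx <- dP[ci$inner, , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# 1x1x1 convolution (a per-voxel dense layer)
.conv1Fwd <- function(x, W, b, training = FALSE) {
  Y <- sweep(x %*% W, 2L, b, "+")
  list(y = Y, cache = if (training) list(x = x) else NULL)
}

.conv1Bwd <- function(dY, cache, W) {
  list(dx = dY %*% t(W), dW = crossprod(cache$x, dY), db = colSums(dY))
}

# instance normalisation (per channel over all voxels of the sample)
.inormFwd <- function(x, gamma, beta, eps = 1e-5, training = FALSE) {
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, istd, "*")
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(y = y, cache = if (training) list(xhat = xhat, istd = istd) else NULL)
}

.inormBwd <- function(dY, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, gamma, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- sweep(sweep(dxhat, 2L, m1) - sweep(xhat, 2L, m2, "*"),
              2L, cache$istd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.lreluFwd <- function(x, slope, training = FALSE) {
  pos <- x > 0
  y <- x * (pos + slope * (1 - pos))
  list(y = y, cache = if (training) list(pos = pos) else NULL)
}

.lreluBwd <- function(dY, cache, slope) {
  dY * (cache$pos + slope * (1 - cache$pos))
}

# nearest-neighbour upsampling by an integer factor
.upIdx <- function(inShape, factor) {
  key <- paste0("up:", paste(inShape, collapse = "x"), ":f", factor)
  .cachedIdx(key, function() {
    outShape <- inShape * factor
    px <- (seq_len(outShape[1]) - 1L) %/% factor + 1L
    py <- (seq_len(outShape[2]) - 1L) %/% factor + 1L
    pz <- (seq_len(outShape[3]) - 1L) %/% factor + 1L
    ox <- rep(px, times = outShape[2] * outShape[3])
    oy <- rep(rep(py, each = outShape[1]), times = outShape[3])
    oz <- rep(pz, each = outShape[1] * outShape[2])
    list(par = ox + inShape[1] * (oy - 1L) + inShape[1] * inShape[2] * (oz - 1L),
         outShape = outShape)
  })
}

.upNearestFwd <- function(x, inShape, factor = 2L) {
  ui <- .upIdx(inShape, factor)
  list(y = x[ui$par, , drop = FALSE], shape = ui$outShape)
}

.upNearestBwd <- function(dY, inShape, factor = 2L) {
  ui <- .upIdx(inShape, factor)
  rs <- rowsum(dY, group = ui$par)                 # groups 1..nIn all present
  rs
}

# nearest-neighbour downsampling by 2 (used to bring skip features to the
# gating resolution)
.downIdx <- function(inShape) {
  key <- paste0("down:", paste(inShape, collapse = "x"))
  .cachedIdx(key, function() {
    outShape <- inShape %/% 2L
    sx <- 2L * seq_len(outShape[1]) - 1L
    sy <- 2L * seq_len(outShape[2]) - 1L
    sz <- 2L * seq_len(outShape[3]) - 1L
    ox <- rep(sx, times = outShape[2] * outShape[3])
    oy <- rep(rep(sy, each = outShape[1]), times = outShape[3])
    oz <- rep(sz, each = outShape[1] * outShape[2])
    list(sel = ox + inShape[1] * (oy - 1L) + inShape[1] * inShape[2] * (oz - 1L),
         outShape = outShape)
  })
}

.downNearestFwd <- function(x, inShape) {
  di <- .downIdx(inShape)
  list(y = x[di$sel, , drop = FALSE], shape = di$outShape)
}

.downNearestBwd <- function(dY, inShape, nIn) {
  di <- .downIdx(inShape)
  dX <- matrix(0, nIn, ncol(dY))
  dX[di$sel, ] <- dY
  dX
}

# trilinear x2 upsampling of a single-channel grid (attention coefficients)
.triUpIdx <- function(inShape) {
  key <- paste0("triup:", paste(inShape, collapse = "x"))
  .cachedIdx(key, function() {
    outShape <- inShape * 2L
    coord <- function(n, m) .clamp((seq_len(n) - 0.5) / 2 - 0.5, 0, m - 1)
    cx <- coord(outShape[1], inShape[1])
    cy <- coord(outShape[2], inShape[2])
    cz <- coord(outShape[3], inShape[3])
    xi <- rep(cx, times = outShape[2] * outShape[3])
    yi <- rep(rep(cy, each = outShape[1]), times = outShape[3])
    zi <- rep(cz, each = outShape[1] * outShape[2])
    x0 <- floor(.clamp(xi, 0, max(inShape[1] - 2, 0)))
    y0 <- floor(.clamp(yi, 0, max(inShape[2] - 2, 0)))
    z0 <- floor(.clamp(zi, 0, max(inShape[3] - 2, 0)))
    fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
    nOut <- prod(outShape)
    idx8 <- matrix(0L, nOut, 8L); w8 <- matrix(0, nOut, 8L)
    k <- 0L
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      k <- k + 1L
      ix <- pmin(x0 + dx, inShape[1] - 1); iy <- pmin(y0 + dy, inShape[2] - 1)
      iz <- pmin(z0 + dz, inShape[3] - 1)
      idx8[, k] <- as.integer(1 + ix + inShape[1] * (iy + inShape[2] * iz))
      w8[, k] <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
                 (if (dz) fz else 1 - fz)
    }
    list(idx8 = idx8, w8 = w8, outShape = outShape, nIn = prod(inShape))
  })
}

.triUpFwd <- function(v, inShape) {
  ti <- .triUpIdx(inShape)
  y <- numeric(nrow(ti$idx8))
  for (k in 1:8) y <- y + ti$w8[, k] * v[ti$idx8[, k]]
  list(y = y, shape = ti$outShape)
}

.triUpBwd <- function(dY, inShape) {
  ti <- .triUpIdx(inShape)
  dv <- numeric(ti$nIn)
  for (k in 1:8) {
    agg <- rowsum(dY * ti$w8[, k], group = ti$idx8[, k])
    dv[as.integer(rownames(agg))] <- dv[as.integer(rownames(agg))] + agg[, 1]
  }
  dv
}

.sigmoid <- function(x) 1 / (1 + exp(-x))
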