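# Low-level 3D convolutional layers on voxel grids.
#
# Activations are dense matrices of shape (B * n^3) x C, one column per
# channel, voxels in column-major (x fastest) order within each sample.
# A 3x3x3 same-padded convolution is computed as 27 shifted gathers
# feeding one BLAS matrix multiply against the (27*Cin) x Cout weight
# matrix; the backward pass scatters through the same index sets, so no
# padded copies or reshapes are ever built.

# for each of the 27 kernel offsets: the within-sample source voxel index
# feeding each output voxel, NA where the source falls outside the cube
.conv_offsets <- function(n) {
  vox <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
  off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  lapply(seq_len(27L), function(o) {
    si <- vox$i + off$di[o]; sj <- vox$j + off$dj[o]; sk <- vox$k + off$dk[o]
    ok <- si >= 1L & si <= n & sj >= 1L & sj <= n & sk >= 1L & sk <= n
    idx <- si + (sj - 1L) * n + (sk - 1L) * n * n
    idx[!ok] <- NA_integer_
    idx
  })
}

# child indices (8 per output voxel) for 2x2x2 stride-2 max pooling
.pool_index <- function(n) {
  m <- n %/% 2L
  out <- expand.grid(i = seq_len(m), j = seq_len(m), k = seq_len(m))
  off <- expand.grid(di = 0:1, dj = 0:1, dk = 0:1)
  idx <- matrix(0L, m^3, 8L)
  for (t in seq_len(8L)) {
    idx[, t] <- (2L * (out$i - 1L) + 1L + off$di[t]) +
      (2L * (out$j - 1L) + off$dj[t]) * n +
      (2L * (out$k - 1L) + off$dk[t]) * n * n
  }
  idx
}

.index_cache <- new.env(parent = emptyenv())

# batch-wide gather/scatter indices for one kernel offset: rows of the
# (B*n^3)-row activation matrix, restricted to in-bounds source voxels
.cached_conv_batch <- function(n, B) {
  key <- paste0("conv", n, "_", B)
  hit <- .index_cache[[key]]
  if (!is.null(hit)) return(hit)
  offs <- .conv_offsets(n)
  n3 <- n^3
  shift <- rep((seq_len(B) - 1L) * n3, each = n3)
  out <- lapply(offs, function(idx) {
    ok <- which(!is.na(rep.int(idx, B)))
    list(dst = ok, src = rep.int(idx, B)[ok] + shift[ok])
  })
  .index_cache[[key]] <- out
  out
}

.cached_pool <- function(n) {
  key <- paste0("pool", n)
  if (is.null(.index_cache[[key]])) .index_cache[[key]] <- .pool_index(n)
  .index_cache[[key]]
}

# patch matrix (B*n^3) x (27*Cin); column block o holds the offset-o shift
.im2col <- function(X, n, B) {
  cin <- ncol(X)
  n3 <- n^3
  g <- .cached_conv_batch(n, B)
  P <- matrix(0, B * n3, 27L * cin)
  for (o in seq_len(27L)) {
    cols <- ((o - 1L) * cin + 1L):(o * cin)
    P[g[[o]]$dst, cols] <- X[g[[o]]$src, , drop = FALSE]
  }
  P
}

# scatter-add the patch gradient back onto input voxels
.col2im <- function(dP, n, B, cin) {
  g <- .cached_conv_batch(n, B)
  dX <- matrix(0, B * n^3, cin)
  for (o in seq_len(27L)) {
    cols <- ((o - 1L) * cin + 1L):(o * cin)
    # src rows are unique within one offset, so indexed += is safe
    dX[g[[o]]$src, ] <- dX[g[[o]]$src, , drop = FALSE] +
      dP[g[[o]]$dst, cols, drop = FALSE]
  }
  dX
}

conv3d_forward <- function(X, n, B, W, b) {
  P <- .im2col(X, n, B)
  Y <- P %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = Y, P = P)
}

conv3d_backward <- function(dY, cache, W, n, B) {
  dW <- crossprod(cache$P, dY)
  db <- colSums(dY)
  dP <- dY %*% t(W)
  dX <- .col2im(dP, n, B, nrow(W) / 27L)
  list(dX = dX, dW = dW, db = db)
}

bn_forward <- function(X, gamma, beta, running, training, momentum = 0.9,
                       eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    v <- colMeans(X^2) - mu^2
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  inv_std <- 1 / sqrt(v + eps)
  N <- nrow(X)
  xhat <- (X - rep(mu, each = N)) * rep(inv_std, each = N)
  Y <- xhat * rep(gamma, each = N) + rep(beta, each = N)
  list(Y = Y, xhat = xhat, inv_std = inv_std, running = running)
}

bn_backward <- function(dY, cache, gamma) {
  N <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  t1 <- dY - rep(dbeta / N, each = N)
  t2 <- cache$xhat * rep(dgamma / N, each = N)
  dX <- (t1 - t2) * rep(gamma * cache$inv_std, each = N)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

maxpool_forward <- function(X, n, B) {
  idx <- .cached_pool(n)
  m <- n %/% 2L
  n3 <- n^3
  m3 <- m^3
  C <- ncol(X)
  shift <- rep((seq_len(B) - 1L), each = m3)
  rows1 <- rep.int(idx[, 1L], B) + shift * n3
  best <- X[rows1, , drop = FALSE]
  argmax <- matrix(1L, B * m3, C)
  for (t in 2:8) {
    cand <- X[rep.int(idx[, t], B) + shift * n3, , drop = FALSE]
    swap <- cand > best
    best[swap] <- cand[swap]
    argmax[swap] <- t
  }
  list(Y = best, argmax = argmax, m = m)
}

maxpool_backward <- function(dY, cache, n, B) {
  idx <- .cached_pool(n)
  m <- cache$m
  n3 <- n^3
  m3 <- m^3
  dX <- matrix(0, B * n3, ncol(dY))
  shift <- rep((seq_len(B) - 1L), each = m3) * n3
  for (t in 1:8) {
    sel <- which(cache$argmax == t, arr.ind = TRUE)
    if (nrow(sel) == 0) next
    rows <- rep.int(idx[, t], B)[sel[, 1L]] + shift[sel[, 1L]]
    dX[cbind(rows, sel[, 2L])] <- dY[sel]
  }
  dX
}

sigmoid <- function(x) 1 / (1 + exp(-x))
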