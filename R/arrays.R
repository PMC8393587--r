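# Internal array utilities shared by the band operators and the network stack.
#
# Tensor layout conventions:
#   * plain fields: H x W matrices (2D) or H x W x D arrays (3D)
#   * network tensors: [spatial..., N, C] so that a matrix view with
#     dim <- c(prod(spatial) * N, C) is a zero-copy reshape (column-major).

# ---- slicing helpers -------------------------------------------------------
# Explicit rank dispatch: the generic do.call(`[`, ...) route is far too slow
# on the training path, so ranks 2-5 (fields and [S..., N, C] tensors) are
# written out.

# Gather along dimension `d` with an index vector.
slice_gather <- function(x, d, idx) {
  nd <- length(dim(x))
  if (nd == 2L) {
    if (d == 1L) x[idx, , drop = FALSE] else x[, idx, drop = FALSE]
  } else if (nd == 3L) {
    switch(d,
           x[idx, , , drop = FALSE],
           x[, idx, , drop = FALSE],
           x[, , idx, drop = FALSE])
  } else if (nd == 4L) {
    switch(d,
           x[idx, , , , drop = FALSE],
           x[, idx, , , drop = FALSE],
           x[, , idx, , drop = FALSE],
           x[, , , idx, drop = FALSE])
  } else if (nd == 5L) {
    switch(d,
           x[idx, , , , , drop = FALSE],
           x[, idx, , , , drop = FALSE],
           x[, , idx, , , drop = FALSE],
           x[, , , idx, , drop = FALSE],
           x[, , , , idx, drop = FALSE])
  } else {
    stop("unsupported array rank", call. = FALSE)
  }
}

# x[idx along d] <- x[idx along d] + val
slice_add <- function(x, d, idx, val) {
  nd <- length(dim(x))
  if (nd == 2L) {
    if (d == 1L) x[idx, ] <- x[idx, , drop = FALSE] + val
    else x[, idx] <- x[, idx, drop = FALSE] + val
  } else if (nd == 3L) {
    switch(d,
           x[idx, , ] <- x[idx, , , drop = FALSE] + val,
           x[, idx, ] <- x[, idx, , drop = FALSE] + val,
           x[, , idx] <- x[, , idx, drop = FALSE] + val)
  } else if (nd == 4L) {
    switch(d,
           x[idx, , , ] <- x[idx, , , , drop = FALSE] + val,
           x[, idx, , ] <- x[, idx, , , drop = FALSE] + val,
           x[, , idx, ] <- x[, , idx, , drop = FALSE] + val,
           x[, , , idx] <- x[, , , idx, drop = FALSE] + val)
  } else if (nd == 5L) {
    switch(d,
           x[idx, , , , ] <- x[idx, , , , , drop = FALSE] + val,
           x[, idx, , , ] <- x[, idx, , , , drop = FALSE] + val,
           x[, , idx, , ] <- x[, , idx, , , drop = FALSE] + val,
           x[, , , idx, ] <- x[, , , idx, , drop = FALSE] + val,
           x[, , , , idx] <- x[, , , , idx, drop = FALSE] + val)
  } else {
    stop("unsupported array rank", call. = FALSE)
  }
  x
}

# Windowed access over the first `ns` dimensions (remaining dims kept whole):
# rr is a list of `ns` index vectors.
win_get <- function(x, rr) {
  ns <- length(rr)
  nd <- length(dim(x))
  extra <- nd - ns
  if (ns == 2L) {
    switch(extra + 1L,
           x[rr[[1]], rr[[2]], drop = FALSE],
           x[rr[[1]], rr[[2]], , drop = FALSE],
           x[rr[[1]], rr[[2]], , , drop = FALSE])
  } else {
    switch(extra + 1L,
           x[rr[[1]], rr[[2]], rr[[3]], drop = FALSE],
           x[rr[[1]], rr[[2]], rr[[3]], , drop = FALSE],
           x[rr[[1]], rr[[2]], rr[[3]], , , drop = FALSE])
  }
}

win_add <- function(x, rr, val) {
  ns <- length(rr)
  nd <- length(dim(x))
  extra <- nd - ns
  if (ns == 2L) {
    switch(extra + 1L,
           x[rr[[1]], rr[[2]]] <- x[rr[[1]], rr[[2]], drop = FALSE] + val,
           x[rr[[1]], rr[[2]], ] <- x[rr[[1]], rr[[2]], , drop = FALSE] + val,
           x[rr[[1]], rr[[2]], , ] <-
             x[rr[[1]], rr[[2]], , , drop = FALSE] + val)
  } else {
    switch(extra + 1L,
           x[rr[[1]], rr[[2]], rr[[3]]] <-
             x[rr[[1]], rr[[2]], rr[[3]], drop = FALSE] + val,
           x[rr[[1]], rr[[2]], rr[[3]], ] <-
             x[rr[[1]], rr[[2]], rr[[3]], , drop = FALSE] + val,
           x[rr[[1]], rr[[2]], rr[[3]], , ] <-
             x[rr[[1]], rr[[2]], rr[[3]], , , drop = FALSE] + val)
  }
  x
}

win_set <- function(x, rr, val) {
  ns <- length(rr)
  nd <- length(dim(x))
  extra <- nd - ns
  if (ns == 2L) {
    switch(extra + 1L,
           x[rr[[1]], rr[[2]]] <- val,
           x[rr[[1]], rr[[2]], ] <- val,
           x[rr[[1]], rr[[2]], , ] <- val)
  } else {
    switch(extra + 1L,
           x[rr[[1]], rr[[2]], rr[[3]]] <- val,
           x[rr[[1]], rr[[2]], rr[[3]], ] <- val,
           x[rr[[1]], rr[[2]], rr[[3]], , ] <- val)
  }
  x
}

# Shift by k along dimension d with replicate (clamp-to-edge) padding.
shift_rep <- function(x, d, k) {
  if (k == 0L) return(x)
  n <- dim(x)[d]
  idx <- pmin(pmax(seq_len(n) + k, 1L), n)
  slice_gather(x, d, idx)
}

# Adjoint of shift_rep: scatter-add of the gradient.
shift_rep_t <- function(g, d, k) {
  if (k == 0L) return(g)
  n <- dim(g)[d]
  out <- array(0, dim(g))
  if (k > 0L) {
    if (k < n) {
      out <- slice_add(out, d, seq.int(k + 1L, n),
                       slice_gather(g, d, seq_len(n - k)))
    }
    start <- max(n - k + 1L, 1L)
    bnd <- slice_gather(g, d, start)
    if (start < n) for (j in seq.int(start + 1L, n)) {
      bnd <- bnd + slice_gather(g, d, j)
    }
    out <- slice_add(out, d, n, bnd)
  } else {
    m <- -k
    if (m < n) {
      out <- slice_add(out, d, seq_len(n - m),
                       slice_gather(g, d, seq.int(m + 1L, n)))
    }
    end <- min(m, n)
    bnd <- slice_gather(g, d, 1L)
    if (end > 1L) for (j in seq.int(2L, end)) bnd <- bnd + slice_gather(g, d, j)
    out <- slice_add(out, d, 1L, bnd)
  }
  out
}

# Apply a matrix M along dimension d: out has dim[d] = nrow(M).
apply_dim_matrix <- function(x, d, M) {
  dx <- dim(x)
  nd <- length(dx)
  if (d == 1L) {
    xm <- x
    dim(xm) <- c(dx[1L], prod(dx[-1L]))
    y <- M %*% xm
    dim(y) <- c(nrow(M), dx[-1L])
    return(y)
  }
  perm <- c(d, seq_len(nd)[-d])
  xp <- aperm(x, perm)
  dim(xp) <- c(dx[d], prod(dx[-d]))
  y <- M %*% xp
  dim(y) <- c(nrow(M), dx[perm][-1])
  aperm(y, order(perm))
}

# ---- convolution (shift-and-multiply, BLAS backed) -------------------------

conv_offsets <- function(k, ns) {
  r <- (k - 1L) %/% 2L
  as.matrix(do.call(expand.grid, rep(list(seq.int(-r, r)), ns)))
}

pad_spatial <- function(x, r, ns) {
  if (r == 0L) return(x)
  dx <- dim(x)
  dd <- dx
  dd[seq_len(ns)] <- dd[seq_len(ns)] + 2L * r
  xp <- array(0, dd)
  win_set(xp, lapply(seq_len(ns), function(d) (r + 1L):(r + dx[d])), x)
}

crop_spatial <- function(xp, r, S, ns) {
  if (r == 0L) return(xp)
  win_get(xp, lapply(seq_len(ns), function(d) (r + 1L):(r + S[d])))
}

conv_window <- function(xp, off, S, r, ns) {
  win_get(xp, lapply(seq_len(ns), function(d) {
    (1L + r + off[d]):(S[d] + r + off[d])
  }))
}

# x: [S..., N, Cin]; w: [k^ns, Cin, Cout]; b: length Cout.
# keep_windows caches the per-offset window matrices for reuse in the
# backward pass (trades memory for time during training).
conv_fwd <- function(x, w, b, ns, keep_windows = FALSE) {
  dx <- dim(x)
  S <- dx[seq_len(ns)]
  N <- dx[ns + 1L]
  Cin <- dim(w)[2]
  Cout <- dim(w)[3]
  noff <- dim(w)[1]
  k <- as.integer(round(noff^(1 / ns)))
  r <- (k - 1L) %/% 2L
  rows <- prod(S) * N
  windows <- if (keep_windows && r > 0L) vector("list", noff) else NULL
  if (r == 0L) {
    xm <- x
    dim(xm) <- c(rows, Cin)
    y <- xm %*% matrix(w[1L, , ], Cin, Cout)
  } else {
    offs <- conv_offsets(k, ns)
    xp <- pad_spatial(x, r, ns)
    y <- matrix(0, rows, Cout)
    for (o in seq_len(noff)) {
      Xo <- conv_window(xp, offs[o, ], S, r, ns)
      dim(Xo) <- c(rows, Cin)
      if (!is.null(windows)) windows[[o]] <- Xo
      y <- y + Xo %*% matrix(w[o, , ], Cin, Cout)
    }
  }
  for (co in seq_len(Cout)) y[, co] <- y[, co] + b[co]
  dim(y) <- c(S, N, Cout)
  if (keep_windows) list(y = y, windows = windows) else y
}

conv_bwd <- function(x, w, gy, ns, windows = NULL) {
  dx <- dim(x)
  S <- dx[seq_len(ns)]
  N <- dx[ns + 1L]
  Cin <- dim(w)[2]
  Cout <- dim(w)[3]
  noff <- dim(w)[1]
  k <- as.integer(round(noff^(1 / ns)))
  r <- (k - 1L) %/% 2L
  rows <- prod(S) * N
  gym <- gy
  dim(gym) <- c(rows, Cout)
  gb <- colSums(gym)
  gw <- array(0, dim(w))
  if (r == 0L) {
    xm <- x
    dim(xm) <- c(rows, Cin)
    gw[1L, , ] <- crossprod(xm, gym)
    gx <- gym %*% t(matrix(w[1L, , ], Cin, Cout))
    dim(gx) <- dx
    return(list(gx = gx, gw = gw, gb = gb))
  }
  offs <- conv_offsets(k, ns)
  xp <- if (is.null(windows)) pad_spatial(x, r, ns) else NULL
  dd <- dx
  dd[seq_len(ns)] <- dd[seq_len(ns)] + 2L * r
  gxp <- array(0, dd)
  for (o in seq_len(noff)) {
    if (is.null(windows)) {
      Xo <- conv_window(xp, offs[o, ], S, r, ns)
      dim(Xo) <- c(rows, Cin)
    } else {
      Xo <- windows[[o]]
    }
    gw[o, , ] <- crossprod(Xo, gym)
    G <- gym %*% t(matrix(w[o, , ], Cin, Cout))
    rr <- lapply(seq_len(ns), function(d) {
      (1L + r + offs[o, d]):(S[d] + r + offs[o, d])
    })
    dim(G) <- c(S, N, Cin)
    gxp <- win_add(gxp, rr, G)
  }
  list(gx = crop_spatial(gxp, r, S, ns), gw = gw, gb = gb)
}

# ---- max pooling (window 2, stride 2) --------------------------------------

pool_slices <- function(ns) as.matrix(do.call(expand.grid, rep(list(1:2), ns)))

pool_slice <- function(x, off, ns) {
  dx <- dim(x)
  win_get(x, lapply(seq_len(ns), function(d) seq.int(off[d], dx[d], by = 2L)))
}

pool_fwd <- function(x, ns) {
  offs <- pool_slices(ns)
  y <- pool_slice(x, offs[1, ], ns)
  for (o in 2:nrow(offs)) y <- pmax(y, pool_slice(x, offs[o, ], ns))
  y
}

pool_bwd <- function(x, y, gy, ns) {
  offs <- pool_slices(ns)
  gx <- array(0, dim(x))
  claimed <- array(FALSE, dim(y))
  dx <- dim(x)
  for (o in seq_len(nrow(offs))) {
    s <- pool_slice(x, offs[o, ], ns)
    hit <- (s == y) & !claimed
    claimed <- claimed | hit
    gx <- win_add(gx, lapply(seq_len(ns), function(d) {
      seq.int(offs[o, d], dx[d], by = 2L)
    }), gy * hit)
  }
  gx
}

# ---- linear (bi-/tri-linear) upsampling ------------------------------------

.up_mat_cache <- new.env(parent = emptyenv())

# Interpolation matrix mapping length-n input to length-(n*f) output,
# sampling at src = (o + 0.5)/f - 0.5 (half-pixel-centre convention).
up_mat <- function(n, f) {
  key <- paste(n, f, sep = "_")
  M <- .up_mat_cache[[key]]
  if (!is.null(M)) return(M)
  m <- n * f
  M <- matrix(0, m, n)
  for (o in seq_len(m)) {
    src <- (o - 1 + 0.5) / f - 0.5
    i0 <- floor(src)
    t <- src - i0
    i0 <- min(max(i0, 0), n - 1)
    i1 <- min(i0 + 1, n - 1)
    if (src <= 0) { i0 <- 0; i1 <- 0; t <- 0 }
    if (src >= n - 1) { i0 <- n - 1; i1 <- n - 1; t <- 0 }
    M[o, i0 + 1] <- M[o, i0 + 1] + (1 - t)
    M[o, i1 + 1] <- M[o, i1 + 1] + t
  }
  .up_mat_cache[[key]] <- M
  M
}

upsample_fwd <- function(x, f, ns) {
  if (f == 1L) return(x)
  for (d in seq_len(ns)) x <- apply_dim_matrix(x, d, up_mat(dim(x)[d], f))
  x
}

upsample_bwd <- function(gy, f, ns, S_in) {
  if (f == 1L) return(gy)
  for (d in rev(seq_len(ns))) gy <- apply_dim_matrix(gy, d, t(up_mat(S_in[d], f)))
  gy
}

# ---- normalisation layers --------------------------------------------------

# Batch norm over all dims but the channel (last) dim. Returns y and cache.
bn_fwd <- function(x, gamma, beta, eps = 1e-5) {
  dx <- dim(x)
  C <- dx[length(dx)]
  m <- prod(dx) / C
  xm <- x
  dim(xm) <- c(m, C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc * xc)
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, ivar, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  dim(y) <- dx
  list(y = y, xhat = xhat, ivar = ivar, mu = mu, var = v)
}

bn_bwd <- function(cache, gamma, gy) {
  dx <- dim(gy)
  C <- dx[length(dx)]
  m <- prod(dx) / C
  gym <- gy
  dim(gym) <- c(m, C)
  xhat <- cache$xhat
  ggamma <- colSums(gym * xhat)
  gbeta <- colSums(gym)
  gxhat <- sweep(gym, 2, gamma, `*`)
  s1 <- colSums(gxhat)
  s2 <- colSums(gxhat * xhat)
  gx <- sweep(gxhat, 2, s1 / m) - sweep(xhat, 2, s2 / m, `*`)
  gx <- sweep(gx, 2, cache$ivar, `*`)
  dim(gx) <- dx
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

# Batch-norm style normalisation applied at prediction time from running stats.
bn_eval <- function(x, gamma, beta, rmean, rvar, eps = 1e-5) {
  dx <- dim(x)
  C <- dx[length(dx)]
  xm <- x
  dim(xm) <- c(prod(dx) / C, C)
  xhat <- sweep(sweep(xm, 2, rmean), 2, 1 / sqrt(rvar + eps), `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  dim(y) <- dx
  y
}

# Instance norm: statistics per (sample, channel); affine per channel.
in_fwd <- function(x, gamma, beta, ns, eps = 1e-5) {
  dx <- dim(x)
  N <- dx[ns + 1L]
  C <- dx[ns + 2L]
  ps <- prod(dx[seq_len(ns)])
  xm <- x
  dim(xm) <- c(ps, N * C)
  gcol <- rep(gamma, each = N)
  bcol <- rep(beta, each = N)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc * xc)
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, ivar, `*`)
  y <- sweep(sweep(xhat, 2, gcol, `*`), 2, bcol, `+`)
  dim(y) <- dx
  list(y = y, xhat = xhat, ivar = ivar)
}

in_bwd <- function(cache, gamma, gy, ns) {
  dx <- dim(gy)
  N <- dx[ns + 1L]
  C <- dx[ns + 2L]
  ps <- prod(dx[seq_len(ns)])
  gym <- gy
  dim(gym) <- c(ps, N * C)
  xhat <- cache$xhat
  gcol <- rep(gamma, each = N)
  gsum <- colSums(gym * xhat)
  ggamma <- as.numeric(rowsum(gsum, rep(seq_len(C), each = N)))
  gbeta <- as.numeric(rowsum(colSums(gym), rep(seq_len(C), each = N)))
  gxhat <- sweep(gym, 2, gcol, `*`)
  s1 <- colSums(gxhat)
  s2 <- colSums(gxhat * xhat)
  gx <- sweep(gxhat, 2, s1 / ps) - sweep(xhat, 2, s2 / ps, `*`)
  gx <- sweep(gx, 2, cache$ivar, `*`)
  dim(gx) <- dx
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

# ---- softmax over the last (class) dimension -------------------------------

softmax_last <- function(x) {
  dx <- dim(x)
  K <- dx[length(dx)]
  xm <- x
  dim(xm) <- c(prod(dx) / K, K)
  mx <- xm[cbind(seq_len(nrow(xm)), max.col(xm, ties.method = "first"))]
  e <- exp(xm - mx)
  p <- e / rowSums(e)
  dim(p) <- dx
  p
}

# Backward of softmax: gx = p * (g - sum(g * p)) along the class dim.
softmax_bwd <- function(p, g) {
  dx <- dim(p)
  K <- dx[length(dx)]
  pm <- p; dim(pm) <- c(prod(dx) / K, K)
  gm <- g; dim(gm) <- c(prod(dx) / K, K)
  dot <- rowSums(gm * pm)
  gx <- pm * (gm - dot)
  dim(gx) <- dx
  gx
}
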