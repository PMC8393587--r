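# Independent brute-force oracles used across the tests. These deliberately
# re-derive each quantity with plain loops so they share no code with the
# package implementation.

clampi <- function(i, n) min(max(i, 1L), n)

# Moving-window maximum with replicate padding (window B, 2D).
oracle_maxfilter <- function(f, B) {
  r <- (B - 1L) %/% 2L
  n1 <- nrow(f); n2 <- ncol(f)
  out <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    out[i, j] <- max(f[max(1, i - r):min(n1, i + r),
                       max(1, j - r):min(n2, j + r)])
  }
  out
}

# Signed distance by exhaustive nearest-opposite-pixel search.
oracle_sdf <- function(m) {
  ci <- which(m == 1, arr.ind = TRUE)
  co <- which(m == 0, arr.ind = TRUE)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    opp <- if (m[i, j] == 1) co else ci
    d <- sqrt(min((opp[, 1] - i)^2 + (opp[, 2] - j)^2))
    out[i, j] <- if (m[i, j] == 1) d else -d
  }
  out
}

# Per-pixel evaluation of the smoothed central-difference (Sobel) stencil
# with replicate padding, 2D.
oracle_edge <- function(f) {
  kx <- outer(c(-1, 0, 1), c(1, 2, 1)) / 8   # derivative along rows
  ky <- outer(c(1, 2, 1), c(-1, 0, 1)) / 8   # derivative along cols
  n1 <- nrow(f); n2 <- ncol(f)
  out <- matrix(0, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    gx <- 0; gy <- 0
    for (di in -1:1) for (dj in -1:1) {
      v <- f[clampi(i + di, n1), clampi(j + dj, n2)]
      gx <- gx + kx[di + 2, dj + 2] * v
      gy <- gy + ky[di + 2, dj + 2] * v
    }
    out[i, j] <- sqrt(gx^2 + gy^2)
  }
  out
}

# Narrow band of a binary mask: pixels within Chebyshev radius (B-1)/2 of an
# edge-positive pixel, split by the mask.
oracle_band <- function(y, B) {
  e <- oracle_edge(y) > 0
  r <- (B - 1L) %/% 2L
  n1 <- nrow(y); n2 <- ncol(y)
  ind <- matrix(FALSE, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    ind[i, j] <- any(e[max(1, i - r):min(n1, i + r),
                       max(1, j - r):min(n2, j + r)])
  }
  list(indicator = ind, inner = ind & y == 1, outer = ind & y == 0)
}

oracle_clip <- function(p) pmin(pmax(p, 1e-7), 1 - 1e-7)

oracle_ce <- function(P, T) {
  s <- 0
  for (i in seq_along(P)) {
    p <- oracle_clip(P[i])
    s <- s - (T[i] * log(p) + (1 - T[i]) * log(1 - p))
  }
  s / length(P)
}

oracle_dice_binary <- function(P, T) {
  1 - (2 * sum(T * P) + 1e-6) / (sum(T) + sum(P) + 1e-6)
}

oracle_focal <- function(P, T, alpha, gamma) {
  s <- 0
  for (i in seq_along(P)) {
    p <- oracle_clip(P[i])
    s <- s - alpha * ((1 - p)^gamma * T[i] * log(p) +
                        p^gamma * (1 - T[i]) * log(1 - p))
  }
  s / length(P)
}

# P, T arrays [n1, n2, K]
oracle_region <- function(P, T) {
  n1 <- dim(P)[1]; n2 <- dim(P)[2]; K <- dim(P)[3]
  s <- 0
  for (i in seq_len(n1)) for (j in seq_len(n2)) for (c in seq_len(K)) {
    s <- s - T[i, j, c] * log(oracle_clip(P[i, j, c]))
  }
  s / (n1 * n2)
}

# NB-AC band loss by explicit loops, per mode. Uses oracle_band/oracle_edge
# for the ground-truth band and the dilated edge weights.
oracle_nbac_band <- function(p, F_LC, F_LN, y, B, mu, li, lo, mode) {
  mu_term <- mu * mean(abs(F_LC))
  ob <- oracle_band(y, B)
  Fv <- oracle_maxfilter(oracle_edge(y), B)
  if (mode == "two_sided") {
    b_in <- mean(p[ob$inner]); b_out <- mean(p[ob$outer])
    e_in <- li * sum((p[ob$inner] - b_in)^2) / sum(ob$inner)
    e_out <- lo * sum((p[ob$outer] - b_out)^2) / sum(ob$outer)
  } else if (mode == "band_vs_complement") {
    b_in <- sum(p * Fv) / sum(Fv)
    b_out <- sum(p * (1 - Fv)) / sum(1 - Fv)
    e_in <- li * sum(Fv * (p - b_in)^2) / sum(Fv)
    e_out <- lo * sum((1 - Fv) * (p - b_out)^2) / sum(1 - Fv)
  } else {
    b_in <- sum(p * Fv) / sum(Fv)
    b_out <- sum(p * (1 - Fv)) / sum(1 - Fv)
    e_in <- li * sum((p * F_LN - b_in)^2) / length(p)
    e_out <- lo * sum((p * F_LN - b_out)^2) / length(p)
  }
  mu_term + e_in + e_out
}

# OsC loss for a binary class field by explicit reference computation.
oracle_osc <- function(P, T, pars) {
  L1 <- oracle_ce(P, T)
  Pb <- (P > 0.5) * 1
  if (all(Pb == 0) || all(Pb == 1)) return(pars$alpha * L1)
  phi <- oracle_sdf(Pb)
  ob <- oracle_band(Pb, pars$band_width)
  H <- 0.5 * (1 + (2 / pi) * atan(phi / pars$epsilon))
  bm <- mean(P[ob$inner]); bp <- mean(P[ob$outer])
  nb <- sum(ob$indicator)
  L2 <- 0; L3 <- 0
  ge <- oracle_edge(phi)
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    if (ob$indicator[i, j]) {
      L2 <- L2 + pars$lambda1 * (P[i, j] - bm)^2 * H[i, j] +
        pars$lambda2 * (P[i, j] - bp)^2 * (1 - H[i, j])
      L3 <- L3 + ge[i, j]
    }
  }
  pars$alpha * L1 + pars$beta * L2 / nb + pars$eta * L3 / nb
}

oracle_chan_vese <- function(I, phi, l1, l2, mu, nu) {
  ins <- phi > 0; outs <- phi < 0
  c1 <- mean(I[ins]); c2 <- mean(I[outs])
  e <- 0
  for (i in seq_along(I)) {
    if (ins[i]) e <- e + l1 * (I[i] - c1)^2
    if (outs[i]) e <- e + l2 * (I[i] - c2)^2
  }
  len <- 0
  n1 <- nrow(I); n2 <- ncol(I)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    if (i < n1 && (phi[i, j] > 0) != (phi[i + 1, j] > 0)) len <- len + 1
    if (j < n2 && (phi[i, j] > 0) != (phi[i, j + 1] > 0)) len <- len + 1
  }
  e + mu * len + nu * sum(ins)
}

# A random binary mask guaranteed to contain both values and a boundary.
random_mask <- function(n1, n2, p = 0.4) {
  m <- matrix(rbinom(n1 * n2, 1, p), n1, n2)
  if (all(m == 0)) m[sample(n1, 1), sample(n2, 1)] <- 1
  if (all(m == 1)) m[sample(n1, 1), sample(n2, 1)] <- 0
  m
}

# A compact blocky mask (nonempty inner/outer sub-bands for any B <= 5).
block_mask <- function(n1, n2) {
  m <- matrix(0, n1, n2)
  a <- sample(2:(n1 %/% 2), 1)
  b <- sample((n1 %/% 2 + 1):(n1 - 1), 1)
  a2 <- sample(2:(n2 %/% 2), 1)
  b2 <- sample((n2 %/% 2 + 1):(n2 - 1), 1)
  m[a:b, a2:b2] <- 1
  m
}

# Random softmax-normalised probability stack [n1, n2, K].
random_probs <- function(n1, n2, K) {
  P <- array(runif(n1 * n2 * K, 0.05, 1), c(n1, n2, K))
  s <- array(rep(apply(P, c(1, 2), sum), K), c(n1, n2, K))
  P / s
}

random_onehot <- function(n1, n2, K) {
  lab <- matrix(sample.int(K, n1 * n2, replace = TRUE), n1, n2)
  T <- array(0, c(n1, n2, K))
  for (c in seq_len(K)) T[, , c] <- (lab == c) * 1
  T
}

# Weak-boundary study phantoms: 64 training + 16 held-out images, 64x64,
# 3 classes, contrast gap 0.1, noise 0.05, fixed master seed (memoised).
study_phantoms <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    pcfg <- phantom_config(dims = c(64, 64), K = 3, contrast_gap = 0.1,
                           noise_sigma = 0.05, seed = 100)
    all <- lapply(1:80, function(i) {
      icfg <- pcfg
      icfg$seed <- nbac:::item_seed(pcfg$seed, i)
      make_phantom(icfg)
    })
    cache <<- list(train = all[1:64], test = all[65:80])
    cache
  }
})

# Shared small phantom dataset for training tests (memoised per session).
tiny_phantom_data <- local({
  cache <- NULL
  function(n = 12, dims = c(16, 16), K = 2, seed = 42) {
    if (!is.null(cache)) return(cache)
    cfg <- phantom_config(dims = dims, K = K, proportions = c(0.7, 0.3),
                          contrast_gap = 0.3, noise_sigma = 0.03, seed = seed)
    cache <<- lapply(seq_len(n), function(i) {
      icfg <- cfg
      icfg$seed <- seed + i * 7
      make_phantom(icfg)
    })
    cache
  }
})
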