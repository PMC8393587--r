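test_that("pixel-wise baseline losses match their reference loops and closed forms", {
  set.seed(21)
  P <- matrix(runif(16), 4, 4)
  T <- matrix(rbinom(16, 1, 0.5), 4, 4)
  expect_equal(ce_loss(P, T), oracle_ce(P, T), tolerance = 1e-12)
  expect_equal(ce_loss(matrix(0.5, 5, 5), matrix(rbinom(25, 1, .5), 5, 5)),
               log(2), tolerance = 1e-12)
  expect_lt(ce_loss(T, T), -log(1 - 1e-7) + 1e-12) # perfect prediction
  expect_equal(focal_loss(P, T, 0.25, 2), oracle_focal(P, T, 0.25, 2),
               tolerance = 1e-12)
  expect_identical(focal_loss(P, T, alpha = 1, gamma = 0), ce_loss(P, T))
  expect_lt(focal_loss(T, T), 1e-6)
  expect_error(focal_loss(P, T, alpha = -1), "non-negative")
  # dice: perfect, disjoint, soft oracle
  A <- matrix(0, 4, 4); A[1:2, ] <- 1
  B <- matrix(0, 4, 4); B[3:4, ] <- 1
  expect_lt(dice_loss(A, A), 1e-6)
  expect_equal(dice_loss(A, B), 1, tolerance = 1e-6)
  Ps <- matrix(runif(9), 3, 3)
  Ts <- matrix(rbinom(9, 1, .5), 3, 3)
  expect_equal(dice_loss(Ps, Ts), oracle_dice_binary(Ps, Ts),
               tolerance = 1e-12)
  expect_error(ce_loss(P, T[1:2, ]), "shape")
})

test_that("categorical region loss matches its loop oracle and log K on uniform input", {
  set.seed(22)
  for (K in c(2L, 3L, 5L)) {
    Pu <- array(1 / K, c(4, 4, K))
    Tu <- random_onehot(4, 4, K)
    expect_equal(region_loss(Pu, Tu), log(K), tolerance = 1e-9)
    P <- random_probs(4, 4, K)
    T <- random_onehot(4, 4, K)
    expect_equal(region_loss(P, T), oracle_region(P, T), tolerance = 1e-12)
    Tp <- T
    Tp[Tp == 0] <- 1e-30 # not one-hot but same loss
    expect_lt(region_loss(T * (1 - 2e-7) + 1e-7, T), 1e-5)
  }
  expect_error(region_loss(matrix(1, 3, 3) * 0.4, matrix(1, 3, 3)), "sum to 1")
})

test_that("band descriptors: sub-band means, weighted means, and conservation", {
  set.seed(23)
  y <- block_mask(16, 16)
  b <- ground_truth_band(y, band_spec(3))
  p <- matrix(runif(256), 16, 16)
  # constant p: both descriptors equal the constant in every mode
  pc <- matrix(0.37, 16, 16)
  for (mode in c("two_sided", "band_vs_complement", "literal_eq14")) {
    d <- band_descriptors(pc, b, mode)
    expect_equal(d$b_in, 0.37, tolerance = 1e-12)
    expect_equal(d$b_out, 0.37, tolerance = 1e-12)
  }
  # hard prediction: pure sub-bands
  d <- band_descriptors(y, b, "two_sided")
  expect_identical(c(d$b_in, d$b_out), c(1, 0))
  # weighted means against explicit sums
  d2 <- band_descriptors(p, b, "band_vs_complement")
  expect_equal(d2$b_in, sum(p * b$values) / sum(b$values), tolerance = 1e-12)
  expect_equal(d2$b_out, sum(p * (1 - b$values)) / sum(1 - b$values),
               tolerance = 1e-12)
  # conservation: |band| b_in + |complement| b_out = sum(p)
  expect_equal(sum(b$values) * d2$b_in + sum(1 - b$values) * d2$b_out,
               sum(p), tolerance = 1e-9)
  # degenerate domain is an error, not a silent zero
  expect_warning(b0 <- ground_truth_band(matrix(0, 8, 8)))
  expect_error(band_descriptors(matrix(1, 8, 8), b0, "two_sided"),
               "degenerate")
})

test_that("NB-AC band loss agrees with loop oracles in all three modes", {
  set.seed(24)
  for (rep in 1:6) {
    y <- block_mask(16, 16)
    p <- matrix(runif(256), 16, 16)
    flc <- edge_extract(matrix(runif(256), 16, 16))
    fln <- dilate_band(flc, band_spec(3))
    for (mode in c("two_sided", "band_vs_complement", "literal_eq14")) {
      w <- nbac_weights(mu = 0.7, lambda_in = 1.3, lambda_out = 0.9,
                        band_mode = mode)
      got <- nbac_band_loss(p, flc, fln, y, band_spec(3), w)
      want <- oracle_nbac_band(p, flc, fln, y, 3, 0.7, 1.3, 0.9, mode)
      expect_equal(got, want, tolerance = 1e-9)
      expect_gte(got, 0)
    }
  }
  # trivial zeros
  y <- block_mask(16, 16)
  z <- matrix(0, 16, 16)
  wl <- nbac_weights(band_mode = "literal_eq14")
  expect_equal(nbac_band_loss(z, z, z, y, band_spec(3), wl), 0)
  w0 <- nbac_weights(mu = 0)
  expect_equal(nbac_band_loss(matrix(.4, 16, 16), z, NULL, y,
                              band_spec(3), w0), 0)
  wb <- nbac_weights(mu = 0, band_mode = "band_vs_complement")
  expect_equal(nbac_band_loss(matrix(.4, 16, 16), z, NULL, y,
                              band_spec(3), wb), 0)
  # constant y: band terms skipped with a warning, mu term kept
  expect_warning(expect_warning(
    v <- nbac_band_loss(matrix(.4, 8, 8), matrix(1, 8, 8), NULL,
                        matrix(0, 8, 8), band_spec(3), nbac_weights()),
    "skipped"), "constant")
  expect_equal(v, 1)
  expect_error(nbac_weights(mu = -1), "non-negative")
})

test_that("branch combination is the stated weighted sum and is linear", {
  expect_equal(nbac_total_loss(2, 4), 3) # default 0.5/0.5
  expect_equal(nbac_total_loss(0, 0), 0)
  w10 <- nbac_weights(branch_region = 1, branch_band = 0)
  expect_identical(nbac_total_loss(1.23, 99, w10), 1.23)
  w <- nbac_weights(branch_region = 0.3, branch_band = 0.9)
  set.seed(25)
  for (rep in 1:10) {
    a <- rnorm(2); b <- rnorm(2); s <- runif(1)
    expect_equal(nbac_total_loss(a[1] + s * b[1], a[2] + s * b[2], w),
                 nbac_total_loss(a[1], a[2], w) +
                   s * nbac_total_loss(b[1], b[2], w), tolerance = 1e-12)
  }
})

test_that("OsC loss reduces to the region loss and matches its reference computation", {
  set.seed(26)
  P <- random_probs(8, 8, 3)
  T <- random_onehot(8, 8, 3)
  expect_equal(osc_loss(P, T, osc_params(alpha = 1, beta = 0, eta = 0)),
               region_loss(P, T), tolerance = 1e-12)
  # binary reference computation on a structured prediction
  for (rep in 1:4) {
    y <- block_mask(12, 12)
    Pb <- matrix(runif(144, 0.05, 0.45), 12, 12)
    Pb[y == 1] <- runif(sum(y), 0.55, 0.95)
    pars <- osc_params(band_width = 3, lambda1 = 1.2, lambda2 = 0.8,
                       alpha = 0.5, beta = 1.5, eta = 0.7, epsilon = 0.9)
    expect_equal(osc_loss(Pb, y, pars), oracle_osc(Pb, y, pars),
                 tolerance = 1e-9)
  }
  # constant-prediction beta term contributes zero variance
  yc <- block_mask(12, 12)
  Pc <- matrix(0, 12, 12); Pc[yc == 1] <- 1 # hard; descriptors 1 and 0
  pars <- osc_params(band_width = 3, alpha = 0, beta = 1, eta = 0)
  # with a hard prediction both sub-bands are pure so (P - b)^2 is 0 inside
  # its own side; the cross terms are gated by H
  expect_gte(osc_loss(Pc, yc, pars), 0)
})

test_that("Chan-Vese energy matches its double-loop reference", {
  set.seed(27)
  I <- matrix(runif(100), 10, 10)
  phi <- matrix(rnorm(100), 10, 10)
  pars <- chan_vese_params(1.2, 0.8, 0.5, 0.3)
  expect_equal(as.numeric(chan_vese_energy(I, phi, pars)),
               oracle_chan_vese(I, phi, 1.2, 0.8, 0.5, 0.3),
               tolerance = 1e-10)
  # piecewise-constant image matching the partition: zero fitting energy
  Ipc <- ifelse(phi > 0, 0.8, 0.2)
  expect_equal(as.numeric(chan_vese_energy(Ipc, phi, chan_vese_params())), 0,
               tolerance = 1e-20)
  # area term counts the inside pixels
  phi8 <- matrix(1, 8, 8); phi8[1, 1] <- -1
  e <- chan_vese_energy(matrix(0, 8, 8), phi8, chan_vese_params(0, 0, 0, 2))
  expect_equal(as.numeric(e), 2 * 63)
  expect_error(chan_vese_energy(I, abs(phi) + 1, chan_vese_params()),
               "degenerate")
})

test_that("analytic band-loss gradients match finite differences (descriptors fixed)", {
  set.seed(28)
  y <- block_mask(8, 8)
  p <- matrix(runif(64, 0.1, 0.9), 8, 8)
  flc <- edge_extract(matrix(runif(64), 8, 8))
  fln <- dilate_band(flc, band_spec(3))
  eps <- 1e-6
  for (mode in c("two_sided", "band_vs_complement", "literal_eq14")) {
    w <- nbac_weights(mu = 0.4, lambda_in = 1.1, lambda_out = 0.8,
                      band_mode = mode)
    band <- ground_truth_band(y, band_spec(3))
    d <- band_descriptors(p, band, mode)
    core <- nbac:::nbac_band_loss_core(p, flc, fln, y, band_spec(3), w,
                                       descriptors = d, want_grad = TRUE)
    fd <- matrix(0, 8, 8)
    for (i in seq_len(64)) {
      pp <- p; pp[i] <- pp[i] + eps
      pm <- p; pm[i] <- pm[i] - eps
      fd[i] <- (nbac_band_loss(pp, flc, fln, y, band_spec(3), w, d) -
                  nbac_band_loss(pm, flc, fln, y, band_spec(3), w, d)) /
        (2 * eps)
    }
    expect_lt(max(abs(core$grad_p - fd)) / max(max(abs(fd)), 1e-8), 1e-4)
  }
  # full (non-detached) gradient in literal mode against the free function
  wl <- nbac_weights(mu = 0, band_mode = "literal_eq14",
                     detach_descriptors = FALSE)
  core <- nbac:::nbac_band_loss_core(p, flc, fln, y, band_spec(3), wl,
                                     want_grad = TRUE)
  fd <- matrix(0, 8, 8)
  for (i in seq_len(64)) {
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    fd[i] <- (nbac_band_loss(pp, flc, fln, y, band_spec(3), wl) -
                nbac_band_loss(pm, flc, fln, y, band_spec(3), wl)) / (2 * eps)
  }
  expect_lt(max(abs(core$grad_p - fd)) / max(abs(fd)), 1e-4)
})
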