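test_that("smooth Heaviside matches its closed form and symmetry", {
  expect_identical(heaviside_smooth(0, 0.7), 0.5)
  expect_equal(heaviside_smooth(2, 2), 0.75, tolerance = 1e-15)
  xs <- c(-10, -1, 0, 1, 10) * 0.3
  expect_equal(heaviside_smooth(xs, 0.3),
               0.5 * (1 + (2 / pi) * atan(xs / 0.3)), tolerance = 1e-15)
  set.seed(1)
  x <- matrix(rnorm(100, sd = 3), 10, 10)
  expect_lt(max(abs(heaviside_smooth(x, 0.5) +
                      heaviside_smooth(-x, 0.5) - 1)), 1e-14)
  # strictly increasing and in (0, 1)
  xs <- sort(rnorm(50))
  hs <- heaviside_smooth(xs, 0.2)
  expect_true(all(diff(hs) > 0) && all(hs > 0) && all(hs < 1))
  expect_error(heaviside_smooth(1, 0), "positive")
  expect_error(heaviside_smooth(1, -2), "positive")
})

test_that("signed distance matches exhaustive search with the inside-positive convention", {
  m <- matrix(0, 5, 5)
  m[2:4, 2:4] <- 1
  phi <- signed_distance(m)
  expect_equal(phi[3, 3], oracle_sdf(m)[3, 3]) # = 2: centre to nearest bg px
  single <- matrix(0, 7, 7)
  single[4, 4] <- 1
  phi1 <- signed_distance(single)
  expect_equal(phi1[3, 4], -1)
  expect_equal(phi1[4, 5], -1)
  expect_equal(phi1[4, 4], 1)
  set.seed(7)
  for (rep in 1:12) {
    mm <- random_mask(sample(4:12, 1), sample(4:12, 1))
    phi <- signed_distance(mm)
    expect_lt(max(abs(phi - oracle_sdf(mm))), 1e-10)
    expect_lt(max(abs(signed_distance(1 - mm) + phi)), 1e-12)
  }
  expect_error(signed_distance(matrix(1, 4, 4)), "degenerate")
  expect_error(signed_distance(matrix(0, 4, 4)), "degenerate")
  expect_error(signed_distance(matrix(0.5, 4, 4)), "binary")
})

test_that("edge extraction is a fixed stencil: zero on constants, exact on ramps", {
  expect_true(all(edge_extract(matrix(4.2, 9, 9)) == 0))
  ramp <- matrix(rep(seq_len(8), each = 8), 8, 8) # linear in the row index? no: columns
  e <- edge_extract(ramp)
  for (ij in list(c(3, 3), c(4, 5), c(6, 4))) {
    expect_equal(e[ij[1], ij[2]], 1) # unit slope -> central-difference magnitude 1
  }
  set.seed(8)
  f <- matrix(runif(81), 9, 9)
  expect_equal(edge_extract(f), oracle_edge(f), tolerance = 1e-12)
  # invariant to adding a constant
  expect_equal(edge_extract(f + 3.7), edge_extract(f), tolerance = 1e-12)
  # solid square: strictly positive exactly where a 3x3 neighbourhood mixes
  y <- matrix(0, 10, 10)
  y[4:7, 4:7] <- 1
  mix <- matrix(FALSE, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    v <- y[max(1, i - 1):min(10, i + 1), max(1, j - 1):min(10, j + 1)]
    mix[i, j] <- any(v == 0) && any(v == 1)
  }
  expect_identical(edge_extract(y) > 0, mix)
})

test_that("band dilation is the brute-force window maximum and is monotone", {
  z <- matrix(0, 7, 7)
  z[4, 4] <- 2.5
  d <- dilate_band(z, band_spec(3))
  expect_equal(sum(d == 2.5), 9)
  expect_equal(sum(d), 9 * 2.5)
  set.seed(9)
  f <- matrix(runif(256), 16, 16)
  expect_identical(dilate_band(f, band_spec(1)), f)
  for (B in c(3L, 5L)) {
    for (rep in 1:8) {
      g <- matrix(runif(144), 12, 12)
      dd <- dilate_band(g, band_spec(B))
      expect_identical(dd, oracle_maxfilter(g, B))
      expect_true(all(dd >= g))
    }
    # monotone: F <= G implies dilate(F) <= dilate(G)
    G <- f + abs(matrix(rnorm(256), 16, 16))
    expect_true(all(dilate_band(f, band_spec(B)) <=
                      dilate_band(G, band_spec(B))))
  }
  expect_error(band_spec(4), "odd")
  expect_error(band_spec(0), "odd")
  expect_error(band_spec(-3), "odd")
})

test_that("ground-truth band partitions into inner and outer sub-bands", {
  y <- matrix(0, 32, 32)
  y[13:20, 13:20] <- 1
  b <- ground_truth_band(y, band_spec(3))
  ob <- oracle_band(y, 3)
  expect_identical(b$indicator, ob$indicator)
  expect_equal(sum(b$inner), sum(ob$inner))
  expect_equal(sum(b$outer), sum(ob$outer))
  expect_true(!any(b$inner & b$outer))
  expect_identical(b$inner | b$outer, b$indicator)
  # every edge pixel is covered
  expect_true(all(b$indicator[edge_extract(y) > 0]))
  expect_warning(b0 <- ground_truth_band(matrix(0, 8, 8)), "constant")
  expect_true(all(b0$values == 0))
})

test_that("operators extend to 3D volumes", {
  set.seed(10)
  v <- array(runif(6 * 6 * 6), c(6, 6, 6))
  expect_true(all(edge_extract(array(1, c(5, 5, 5))) == 0))
  d <- dilate_band(v, band_spec(3))
  bf <- array(0, dim(v))
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    bf[i, j, k] <- max(v[max(1, i - 1):min(6, i + 1),
                         max(1, j - 1):min(6, j + 1),
                         max(1, k - 1):min(6, k + 1)])
  }
  expect_identical(d, bf)
  m <- array(0L, c(6, 6, 6))
  m[3:4, 3:4, 3:4] <- 1L
  phi <- signed_distance(m)
  expect_equal(phi[3, 3, 3], 1)
  expect_equal(phi[2, 3, 3], -1)
  ramp3 <- array(rep(1:6, times = 36), c(6, 6, 6))
  expect_equal(edge_extract(ramp3)[3, 3, 3], 1)
})
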