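test_that("phantoms are bit-reproducible and respect the noise-free contract", {
  cfg <- phantom_config(dims = c(32, 32), K = 3, contrast_gap = 0.1,
                        noise_sigma = 0.05, seed = 11)
  expect_identical(make_phantom(cfg), make_phantom(cfg))
  cfg2 <- cfg
  cfg2$seed <- 12L
  expect_false(identical(make_phantom(cfg)$mask, make_phantom(cfg2)$mask))
  # noise- and bias-free phantom is exactly piecewise constant at the means
  c0 <- phantom_config(dims = c(32, 32), K = 3, noise_sigma = 0, seed = 2)
  p0 <- make_phantom(c0)
  expect_identical(unname(p0$image), unname(array(c0$means[p0$mask + 1],
                                                  c0$dims)))
  # every configured class is present with nonzero area
  expect_identical(sort(unique(as.vector(p0$mask))), 0:2)
  expect_true(all(p0$realized_proportions > 0))
})

test_that("realized class proportions track their targets across shape families", {
  for (fam in c("blobs", "nested_rings")) {
    cfg <- phantom_config(dims = c(48, 48), K = 3,
                          proportions = c(0.8, 0.12, 0.08),
                          shape_family = fam, seed = 5)
    ph <- make_phantom(cfg)
    expect_true(all(abs(ph$realized_proportions - cfg$proportions) /
                      cfg$proportions <= 0.2))
  }
  vcfg <- phantom_config(dims = c(64, 64), K = 2, proportions = c(0.93, 0.07),
                         shape_family = "vessels", seed = 6)
  pv <- make_phantom(vcfg)
  expect_true(abs(pv$realized_proportions[2] - 0.07) / 0.07 <= 0.2)
  # vessels are thin structures: foreground never forms one huge blob
  expect_lt(mean(pv$mask), 0.15)
  expect_error(phantom_config(K = 3, shape_family = "vessels"), "binary")
  expect_error(phantom_config(proportions = c(0.5, 0.2)), "summing")
})

test_that("per-class intensities have the configured means within standard error", {
  cfg <- phantom_config(dims = c(64, 64), K = 2, proportions = c(0.6, 0.4),
                        means = c(0.4, 0.6), sds = c(0.05, 0.05),
                        noise_sigma = 0, seed = 13)
  ph <- make_phantom(cfg)
  for (k in 0:1) {
    px <- ph$image[ph$mask == k]
    expect_gt(length(px), 1000)
    expect_lt(abs(mean(px) - cfg$means[k + 1]),
              3 * cfg$sds[k + 1] / sqrt(length(px)) + 1e-12)
  }
  # bias field keeps intensities inside [0, 1]
  pb <- make_phantom(phantom_config(dims = c(32, 32), K = 2,
                                    proportions = c(.8, .2),
                                    bias_amplitude = 0.3, seed = 14))
  expect_true(all(pb$image >= 0 & pb$image <= 1))
})

test_that("decreasing the contrast gap weakens boundaries (Bhattacharyya separation)", {
  seps <- vapply(c(0.05, 0.15, 0.3), function(g) {
    ph <- make_phantom(phantom_config(dims = c(64, 64), K = 3,
                                      contrast_gap = g, noise_sigma = 0.05,
                                      seed = 20))
    class_separation(ph$image, ph$mask, 1, 2)
  }, numeric(1))
  expect_true(all(diff(seps) > 0))
})

test_that("datasets round-trip through disk with a stable manifest", {
  cfg <- phantom_config(dims = c(32, 32), K = 3, seed = 11)
  d1 <- file.path(tempdir(), "ds1")
  d2 <- file.path(tempdir(), "ds2")
  m1 <- make_dataset(4, cfg, d1)
  m2 <- make_dataset(4, cfg, d2)
  expect_identical(m1$config_hash, m2$config_hash)
  expect_identical(unname(tools::md5sum(file.path(d1, "manifest.json"))),
                   unname(tools::md5sum(file.path(d2, "manifest.json"))))
  items <- load_dataset(d1)
  expect_length(items, 4)
  ref <- make_phantom(within.list(cfg, seed <- nbac:::item_seed(cfg$seed, 2)))
  expect_identical(items[[2]]$mask, array(ref$mask, dim(ref$mask)))
  expect_lt(max(abs(items[[2]]$image - ref$image)), 1 / 255) # 8-bit PNG
  # empty dataset: manifest only
  d0 <- file.path(tempdir(), "ds0")
  m0 <- make_dataset(0, cfg, d0)
  expect_identical(m0$n, 0L)
  expect_length(m0$items, 0)
  expect_identical(list.files(d0), "manifest.json")
})

test_that("3D phantoms write and load as NIfTI volumes", {
  cfg <- phantom_config(dims = c(16, 16, 16), K = 2, proportions = c(.8, .2),
                        seed = 7)
  d <- file.path(tempdir(), "ds3d")
  make_dataset(2, cfg, d)
  items <- load_dataset(d)
  expect_identical(dim(items[[1]]$image), c(16L, 16L, 16L))
  ref <- make_phantom(within.list(cfg, seed <- nbac:::item_seed(cfg$seed, 1)))
  expect_equal(items[[1]]$mask, array(ref$mask, dim(ref$mask)))
  expect_lt(max(abs(items[[1]]$image - ref$image)), 1e-6)
})
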