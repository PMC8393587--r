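test_that("backbone shape contracts hold and builds are seed-deterministic", {
  cfg <- backbone_config("unet2d", in_channels = 1, num_classes = 3,
                         depth = 2, base_width = 8)
  net <- build_backbone(cfg, seed = 7)
  img <- matrix(runif(32 * 32), 32, 32)
  out <- forward_two_branch(net, img, training = TRUE)
  expect_identical(dim(out$region_logits), c(32L, 32L, 3L))
  expect_identical(dim(out$F_H), c(32L, 32L, 8L))
  expect_identical(dim(out$F_LC), dim(out$F_H))
  expect_true(all(out$F_LN >= out$F_LC - 1e-12))
  net2 <- build_backbone(cfg, seed = 7)
  expect_identical(net$params, net2$params)
  net3 <- build_backbone(cfg, seed = 8)
  expect_false(identical(net$params, net3$params))
  # indivisible input size is a configuration error
  expect_error(forward_two_branch(net, matrix(0, 31, 31)), "divisible")
  cfg3 <- backbone_config("unet2d", num_classes = 2, depth = 3, base_width = 4)
  expect_error(forward_two_branch(build_backbone(cfg3, 1),
                                  matrix(0, 30, 30)), "divisible")
})

test_that("parameter count matches the layer recipe summed by hand", {
  conv_n <- function(k, cin, cout) k * cin * cout + cout
  norm_n <- function(c) 2 * c
  recipe_count <- function(depth, w0, K, cin, nres) {
    widths <- w0 * 2^(seq_len(depth) - 1)
    total <- 0
    ci <- cin
    for (l in seq_len(depth)) { # encoder: two conv+BN per level
      total <- total + conv_n(9, ci, widths[l]) + norm_n(widths[l]) +
        conv_n(9, widths[l], widths[l]) + norm_n(widths[l])
      ci <- widths[l]
    }
    for (l in seq.int(depth - 1, 1)) { # decoder after skip concatenation
      total <- total + conv_n(9, widths[l] + widths[l + 1], widths[l]) +
        norm_n(widths[l]) + conv_n(9, widths[l], widths[l]) +
        norm_n(widths[l])
    }
    total <- total + conv_n(1, w0, K) # 1x1 head
    for (j in seq_len(nres)) { # residual refinement block
      total <- total + 2 * (conv_n(9, w0, w0) + norm_n(w0))
    }
    total
  }
  for (sz in list(c(2, 8, 3), c(3, 4, 2))) {
    cfg <- backbone_config("unet2d", num_classes = sz[3], depth = sz[1],
                           base_width = sz[2])
    net <- build_backbone(cfg, 1)
    expect_identical(sum(vapply(net$params, length, numeric(1))),
                     recipe_count(sz[1], sz[2], sz[3], 1, 1))
  }
})

test_that("zeroed weights yield a uniform class distribution", {
  cfg <- backbone_config("unet2d", num_classes = 4, depth = 2, base_width = 4)
  net <- build_backbone(cfg, 1)
  for (nm in names(net$params)) net$params[[nm]][] <- 0
  out <- forward_two_branch(net, matrix(runif(16 * 16), 16, 16),
                            training = TRUE)
  p <- exp(out$region_logits)
  p <- p / array(rep(apply(p, c(1, 2), sum), 4), dim(p))
  expect_lt(max(abs(p - 0.25)), 1e-12)
})

test_that("transitional gate is exactly edge extraction followed by dilation", {
  set.seed(31)
  spec <- band_spec(3)
  fh <- array(runif(16 * 16 * 4), c(16, 16, 4))
  g <- transitional_gate(fh, spec, ns = 2)
  for (ch in 1:4) {
    expect_equal(g$F_LC[, , ch], edge_extract(fh[, , ch]), tolerance = 1e-12)
    expect_equal(g$F_LN[, , ch],
                 dilate_band(edge_extract(fh[, , ch]), spec),
                 tolerance = 1e-12)
  }
  # constant feature map gives empty contour and band
  g0 <- transitional_gate(matrix(5, 12, 12), spec)
  expect_true(all(g0$F_LC == 0) && all(g0$F_LN == 0))
  # support width along the normal of a single straight edge: the edge map
  # support (enumerated) grown by the dilation radius on each side
  step <- matrix(0, 16, 16)
  step[, 9:16] <- 1
  gs <- transitional_gate(step, band_spec(5))
  lc_cols <- which(colSums(gs$F_LC > 0) > 0)
  ln_cols <- which(colSums(gs$F_LN > 0) > 0)
  expect_identical(length(ln_cols), length(lc_cols) + (5L - 1L))
})

test_that("FCN and 3D U-Net variants honour the same output contract", {
  cfgf <- backbone_config("fcn2d", num_classes = 2, base_width = 4)
  netf <- build_backbone(cfgf, 1)
  of <- forward_two_branch(netf, matrix(runif(32 * 32), 32, 32),
                           training = TRUE)
  expect_identical(dim(of$region_logits), c(32L, 32L, 2L))
  expect_identical(dim(of$F_LC), c(32L, 32L, 4L))
  expect_true(all(of$F_LN >= of$F_LC - 1e-12))
  cfg3 <- backbone_config("unet3d", num_classes = 2, depth = 2,
                          base_width = 4)
  expect_identical(cfg3$norm, "instance")
  expect_identical(cfg3$activation, "leaky_relu")
  expect_identical(cfg3$band$B, 3L)
  net3 <- build_backbone(cfg3, 1)
  o3 <- forward_two_branch(net3, array(runif(8^3), c(8, 8, 8)),
                           training = TRUE)
  expect_identical(dim(o3$region_logits), c(8L, 8L, 8L, 2L))
  expect_true(all(o3$F_LN >= o3$F_LC - 1e-12))
})

test_that("trainable gate kernels initialise to the fixed stencil", {
  cfg <- backbone_config("unet2d", num_classes = 2, depth = 2, base_width = 4,
                         band = band_spec(3, trainable_edge = TRUE))
  net <- build_backbone(cfg, 3)
  expect_true(all(c("gate.k1", "gate.k2") %in% names(net$params)))
  cfg_fixed <- backbone_config("unet2d", num_classes = 2, depth = 2,
                               base_width = 4, band = band_spec(3))
  netf <- build_backbone(cfg_fixed, 3)
  img <- matrix(runif(16 * 16), 16, 16)
  a <- forward_two_branch(net, img, training = TRUE)
  b <- forward_two_branch(netf, img, training = TRUE)
  expect_equal(a$F_LC, b$F_LC, tolerance = 1e-12)
  expect_equal(a$F_LN, b$F_LN, tolerance = 1e-12)
})
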