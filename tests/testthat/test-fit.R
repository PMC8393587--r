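tiny_config <- function(loss = "nbac", steps = 2L, seed = 1L, ...) {
  nbac_config(backbone = backbone_config("unet2d", num_classes = 2,
                                         depth = 2, base_width = 4,
                                         band = band_spec(3)),
              loss = loss, steps = steps, batch_size = 2L, val_every = 2L,
              seed = seed, ...)
}

test_that("training logs every step and is deterministic under a fixed seed", {
  data <- tiny_phantom_data()
  m1 <- nbac_fit(data, tiny_config(steps = 3L))
  expect_identical(nrow(m1$history), 3L)
  expect_true(all(is.finite(m1$history$total)))
  expect_true(all(c("step", "l1", "l2", "mu_term", "band_energy",
                    "total") %in% names(m1$history)))
  m2 <- nbac_fit(data, tiny_config(steps = 3L))
  expect_identical(m1$history$total, m2$history$total)
  expect_identical(m1$params, m2$params)
  m3 <- nbac_fit(data, tiny_config(steps = 3L, seed = 2L))
  expect_false(identical(m1$history$total[1], m3$history$total[1]))
  # the validation split is deterministic and non-trivial
  expect_identical(m1$val_idx, m2$val_idx)
  expect_gt(length(m1$val_idx), 0)
  expect_gt(length(m1$train_idx), length(m1$val_idx))
})

test_that("every loss selection trains for a step with finite components", {
  data <- tiny_phantom_data()
  for (loss in c("ce", "dice", "focal", "osc", "nbac")) {
    m <- suppressWarnings(nbac_fit(data, tiny_config(loss = loss, steps = 1L)))
    expect_true(is.finite(m$history$total[1]), info = loss)
    expect_identical(m$config$loss, loss)
    if (loss %in% c("nbac", "osc")) {
      expect_true(is.finite(m$history$l1[1]) && is.finite(m$history$l2[1]),
                  info = loss)
    }
  }
})

test_that("prediction honours its type contract and the checkpoint round-trips", {
  data <- tiny_phantom_data()
  out <- file.path(tempdir(), "fit_out")
  m <- nbac_fit(data, tiny_config(steps = 2L, out_dir = out))
  img <- data[[1]]$image
  lab <- predict(m, img)
  expect_identical(dim(lab), dim(img))
  expect_true(all(lab %in% 0:1))
  pr <- predict(m, img, type = "prob")
  expect_identical(dim(pr), c(dim(img), 2L))
  expect_lt(max(abs(apply(pr, c(1, 2), sum) - 1)), 1e-9)
  lg <- predict(m, img, type = "logits")
  expect_identical(dim(lg), dim(pr))
  # training log embeds the config hash and seed
  log <- utils::read.csv(file.path(out, "training_log.csv"))
  expect_true(all(c("config_hash", "seed") %in% names(log)))
  expect_identical(unique(log$config_hash), m$config_hash)
  # checkpoint: versioned header, identical predictions after reload
  m2 <- nbac_load_model(file.path(out, "model.rds"))
  expect_identical(predict(m2, img), lab)
  expect_identical(m2$config_hash, m$config_hash)
  expect_error(suppressWarnings(nbac_load_model(tempfile())), ".")
  # summary/print/plot run quietly
  expect_output(print(m), "nbac_model")
  expect_output(summary(m), "validation")
  pdf(NULL); plot(m); dev.off()
})

test_that("patch cropping trains on sub-windows preferring foreground", {
  data <- tiny_phantom_data()
  m <- nbac_fit(data, tiny_config(steps = 2L, patch_size = 8L))
  expect_true(all(is.finite(m$history$total)))
  set.seed(99)
  it <- data[[1]]
  cr <- nbac:::crop_item(it$image, it$mask, 8L, 2L)
  expect_identical(dim(cr$mask), c(8L, 8L))
  expect_identical(dim(cr$image), c(8L, 8L))
})

test_that("model evaluation aggregates per-case metrics and checks class counts", {
  data <- tiny_phantom_data()
  m <- nbac_fit(data, tiny_config(steps = 2L))
  rec <- nbac_evaluate(m, data[1:3])
  expect_length(rec, 3)
  agg <- attr(rec, "aggregate")
  expect_true(all(agg >= 0 & agg <= 1))
  bad <- list(list(image = data[[1]]$image,
                   mask = data[[1]]$mask + 2L))
  expect_error(nbac_evaluate(m, bad), "class-count")
  f <- tempfile(fileext = ".csv")
  nbac_evaluate(m, data[1:2], csv = f)
  expect_true(file.exists(f))
})
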