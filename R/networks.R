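#' Backbone configuration for the two-branch segmentation network
#'
#' Describes the encoder-decoder first branch and the residual-block +
#' transitional-gate second branch. U-Net levels follow the standard recipe
#' (two 3x3 convolutions with normalisation and activation per level,
#' max-pooling on the way down, bilinear upsampling and skip concatenation on
#' the way up). The FCN variant is a 7-stage FCN-32-style stack whose stage
#' 1, 3 and 7 outputs are fused at input resolution by bilinear
#' interpolation. Defaults follow common practice for the dimensionality:
#' batch normalisation and ReLU in 2D, instance normalisation and leaky ReLU
#' in 3D; default band width 5 in 2D, 3 in 3D.
#'
#' @param kind one of `"unet2d"`, `"fcn2d"`, `"unet3d"`.
#' @param in_channels number of input image channels.
#' @param num_classes number of segmentation classes `K >= 2`.
#' @param depth number of encoder levels (U-Net kinds; >= 2). The FCN stack
#'   is always 7 stages with 5 poolings.
#' @param base_width channels at the first level (>= 4).
#' @param norm `"batch"`, `"instance"` or `"none"`; default by kind.
#' @param activation `"relu"` or `"leaky_relu"`; default by kind.
#' @param band a [band_spec()]; default width 5 (2D) / 3 (3D).
#' @param n_res_blocks residual blocks in the second branch (default 1).
#' @return an object of class `"backbone_config"`.
#' @export
backbone_config <- function(kind = c("unet2d", "fcn2d", "unet3d"),
                            in_channels = 1L, num_classes = 2L,
                            depth = 2L, base_width = 8L,
                            norm = NULL, activation = NULL,
                            band = NULL, n_res_blocks = 1L) {
  kind <- match.arg(kind)
  is3d <- kind == "unet3d"
  if (is.null(norm)) norm <- if (is3d) "instance" else "batch"
  norm <- match.arg(norm, c("batch", "instance", "none"))
  if (is.null(activation)) activation <- if (is3d) "leaky_relu" else "relu"
  activation <- match.arg(activation, c("relu", "leaky_relu"))
  if (is.null(band)) band <- band_spec(if (is3d) 3L else 5L)
  depth <- as.integer(depth)
  base_width <- as.integer(base_width)
  num_classes <- as.integer(num_classes)
  if (depth < 2L) stop("depth must be >= 2", call. = FALSE)
  if (base_width < 4L) stop("base_width must be >= 4", call. = FALSE)
  if (num_classes < 2L) stop("num_classes must be >= 2", call. = FALSE)
  structure(list(kind = kind, in_channels = as.integer(in_channels),
                 num_classes = num_classes, depth = depth,
                 base_width = base_width, norm = norm,
                 activation = activation, band = band,
                 n_res_blocks = as.integer(n_res_blocks)),
            class = "backbone_config")
}

cfg_ns <- function(cfg) if (cfg$kind == "unet3d") 3L else 2L

he_w <- function(noff, cin, cout) {
  array(stats::rnorm(noff * cin * cout, 0, sqrt(2 / (noff * cin))),
        c(noff, cin, cout))
}

add_conv <- function(params, name, k, cin, cout, ns) {
  params[[paste0(name, ".w")]] <- he_w(k^ns, cin, cout)
  params[[paste0(name, ".b")]] <- numeric(cout)
  params
}

add_norm <- function(params, name, c, norm) {
  if (norm == "none") return(params)
  params[[paste0(name, ".gamma")]] <- rep(1, c)
  params[[paste0(name, ".beta")]] <- rep(0, c)
  params
}

# Sobel-style derivative stencil weights over the 3^ns offset grid for
# spatial direction d (used to initialise trainable gate kernels).
sobel_weights <- function(d, ns) {
  offs <- conv_offsets(3L, ns)
  norm <- 2 * 4^(ns - 1)
  w <- rep(1, nrow(offs))
  for (j in seq_len(ns)) {
    w <- w * if (j == d) offs[, j] else (2 - abs(offs[, j]))
  }
  w / norm
}

unet_widths <- function(cfg) cfg$base_width * 2^(seq_len(cfg$depth) - 1L)

fcn_widths <- function(cfg) {
  cfg$base_width * c(1L, 2L, 4L, 8L, 8L, 8L, 8L)
}

init_backbone_params <- function(cfg) {
  ns <- cfg_ns(cfg)
  p <- list()
  if (cfg$kind %in% c("unet2d", "unet3d")) {
    wdt <- unet_widths(cfg)
    cin <- cfg$in_channels
    for (l in seq_len(cfg$depth)) {
      p <- add_conv(p, sprintf("enc%d.conv1", l), 3L, cin, wdt[l], ns)
      p <- add_norm(p, sprintf("enc%d.norm1", l), wdt[l], cfg$norm)
      p <- add_conv(p, sprintf("enc%d.conv2", l), 3L, wdt[l], wdt[l], ns)
      p <- add_norm(p, sprintf("enc%d.norm2", l), wdt[l], cfg$norm)
      cin <- wdt[l]
    }
    for (l in seq.int(cfg$depth - 1L, 1L)) {
      cin <- wdt[l] + wdt[l + 1L]
      p <- add_conv(p, sprintf("dec%d.conv1", l), 3L, cin, wdt[l], ns)
      p <- add_norm(p, sprintf("dec%d.norm1", l), wdt[l], cfg$norm)
      p <- add_conv(p, sprintf("dec%d.conv2", l), 3L, wdt[l], wdt[l], ns)
      p <- add_norm(p, sprintf("dec%d.norm2", l), wdt[l], cfg$norm)
    }
    p <- add_conv(p, "head", 1L, cfg$base_width, cfg$num_classes, ns)
  } else { # fcn2d
    wdt <- fcn_widths(cfg)
    cin <- cfg$in_channels
    for (i in seq_len(7L)) {
      p <- add_conv(p, sprintf("stage%d.conv", i), 3L, cin, wdt[i], ns)
      p <- add_norm(p, sprintf("stage%d.norm", i), wdt[i], cfg$norm)
      cin <- wdt[i]
    }
    for (i in c(1L, 3L, 7L)) {
      p <- add_conv(p, sprintf("score%d", i), 1L, wdt[i], cfg$num_classes, ns)
      p <- add_conv(p, sprintf("feat%d", i), 1L, wdt[i], cfg$base_width, ns)
    }
  }
  for (j in seq_len(cfg$n_res_blocks)) {
    bw <- cfg$base_width
    p <- add_conv(p, sprintf("res%d.conv1", j), 3L, bw, bw, ns)
    p <- add_norm(p, sprintf("res%d.norm1", j), bw, cfg$norm)
    p <- add_conv(p, sprintf("res%d.conv2", j), 3L, bw, bw, ns)
    p <- add_norm(p, sprintf("res%d.norm2", j), bw, cfg$norm)
  }
  if (cfg$band$trainable_edge) {
    for (d in seq_len(ns)) {
      p[[sprintf("gate.k%d", d)]] <- sobel_weights(d, ns)
    }
  }
  p
}

#' Build a two-branch backbone network
#'
#' Initialises all parameters (He initialisation for convolution weights)
#' deterministically from `seed`: two builds with the same seed and config
#' have identical parameters.
#'
#' @param cfg a [backbone_config()].
#' @param seed integer initialisation seed.
#' @return an object of class `"nbac_backbone"` holding the config, the
#'   parameter list and the normalisation running-statistics buffers.
#' @export
build_backbone <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "backbone_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  params <- init_backbone_params(cfg)
  structure(list(cfg = cfg, params = params,
                 buffers = new.env(parent = emptyenv()), seed = seed),
            class = "nbac_backbone")
}

#' @export
print.nbac_backbone <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<nbac_backbone %s> K = %d, depth = %d, base_width = %d, %d parameters (seed %d)\n",
              x$cfg$kind, x$cfg$num_classes, x$cfg$depth, x$cfg$base_width,
              np, x$seed))
  invisible(x)
}

check_divisible <- function(S, cfg) {
  f <- if (cfg$kind == "fcn2d") 32L else 2L^(cfg$depth - 1L)
  if (any(S %% f != 0L)) {
    stop(sprintf("input spatial sizes (%s) must be divisible by %d for %s",
                 paste(S, collapse = "x"), f, cfg$kind), call. = FALSE)
  }
}

# Apply conv + norm + activation under prefix.
tp_cna <- function(tape, h, prefix, cfg, ids, buffers, training, ns) {
  h <- tp_conv(tape, h, ids[[paste0(prefix, ".w")]],
               ids[[paste0(prefix, ".b")]], ns)
  nprefix <- sub("conv", "norm", prefix)
  if (cfg$norm == "batch") {
    h <- tp_batchnorm(tape, h, ids[[paste0(nprefix, ".gamma")]],
                      ids[[paste0(nprefix, ".beta")]], buffers, nprefix,
                      training)
  } else if (cfg$norm == "instance") {
    h <- tp_instnorm(tape, h, ids[[paste0(nprefix, ".gamma")]],
                     ids[[paste0(nprefix, ".beta")]], ns)
  }
  if (cfg$activation == "relu") tp_relu(tape, h) else tp_leaky_relu(tape, h)
}

tp_gate <- function(tape, h, cfg, ids, ns) {
  flc <- if (cfg$band$trainable_edge) {
    tp_edge_trainable(tape, h,
                      lapply(seq_len(ns), function(d) ids[[sprintf("gate.k%d", d)]]),
                      ns)
  } else {
    tp_edge(tape, h, ns)
  }
  fln <- tp_dilate(tape, flc, cfg$band$B, ns)
  list(F_LC = flc, F_LN = fln)
}

# Full two-branch forward on the tape. `x` is a tape node holding a
# [spatial..., N, C] tensor. Returns tape node ids.
net_forward <- function(cfg, tape, x, ids, buffers, training = TRUE) {
  ns <- cfg_ns(cfg)
  S <- dim(tp_value(tape, x))[seq_len(ns)]
  check_divisible(S, cfg)
  if (cfg$kind %in% c("unet2d", "unet3d")) {
    skips <- vector("list", cfg$depth)
    h <- x
    for (l in seq_len(cfg$depth)) {
      h <- tp_cna(tape, h, sprintf("enc%d.conv1", l), cfg, ids, buffers,
                  training, ns)
      h <- tp_cna(tape, h, sprintf("enc%d.conv2", l), cfg, ids, buffers,
                  training, ns)
      if (l < cfg$depth) {
        skips[[l]] <- h
        h <- tp_maxpool(tape, h, ns)
      }
    }
    for (l in seq.int(cfg$depth - 1L, 1L)) {
      h <- tp_upsample(tape, h, 2L, ns)
      h <- tp_concat_last(tape, skips[[l]], h)
      h <- tp_cna(tape, h, sprintf("dec%d.conv1", l), cfg, ids, buffers,
                  training, ns)
      h <- tp_cna(tape, h, sprintf("dec%d.conv2", l), cfg, ids, buffers,
                  training, ns)
    }
    f_h <- h
    logits <- tp_conv(tape, f_h, ids[["head.w"]], ids[["head.b"]], ns)
  } else {
    taps <- list()
    h <- x
    for (i in seq_len(7L)) {
      h <- tp_cna(tape, h, sprintf("stage%d.conv", i), cfg, ids, buffers,
                  training, ns)
      if (i %in% c(1L, 3L, 7L)) taps[[as.character(i)]] <- h
      if (i <= 5L) h <- tp_maxpool(tape, h, ns)
    }
    factors <- c("1" = 1L, "3" = 4L, "7" = 32L)
    logits <- NULL
    f_h <- NULL
    for (i in c("1", "3", "7")) {
      sc <- tp_conv(tape, taps[[i]], ids[[paste0("score", i, ".w")]],
                    ids[[paste0("score", i, ".b")]], ns)
      sc <- tp_upsample(tape, sc, factors[[i]], ns)
      logits <- if (is.null(logits)) sc else tp_add(tape, logits, sc)
      ft <- tp_conv(tape, taps[[i]], ids[[paste0("feat", i, ".w")]],
                    ids[[paste0("feat", i, ".b")]], ns)
      ft <- tp_upsample(tape, ft, factors[[i]], ns)
      f_h <- if (is.null(f_h)) ft else tp_add(tape, f_h, ft)
    }
    f_h <- if (cfg$activation == "relu") tp_relu(tape, f_h) else
      tp_leaky_relu(tape, f_h)
  }
  # second branch: residual refinement then transitional gate
  r <- f_h
  for (j in seq_len(cfg$n_res_blocks)) {
    r2 <- tp_cna(tape, r, sprintf("res%d.conv1", j), cfg, ids, buffers,
                 training, ns)
    r2 <- tp_conv(tape, r2, ids[[sprintf("res%d.conv2.w", j)]],
                  ids[[sprintf("res%d.conv2.b", j)]], ns)
    nkey <- sprintf("res%d.norm2", j)
    if (cfg$norm == "batch") {
      r2 <- tp_batchnorm(tape, r2, ids[[paste0(nkey, ".gamma")]],
                         ids[[paste0(nkey, ".beta")]], buffers, nkey, training)
    } else if (cfg$norm == "instance") {
      r2 <- tp_instnorm(tape, r2, ids[[paste0(nkey, ".gamma")]],
                        ids[[paste0(nkey, ".beta")]], ns)
    }
    r <- tp_add(tape, r, r2)
    r <- if (cfg$activation == "relu") tp_relu(tape, r) else
      tp_leaky_relu(tape, r)
  }
  gate <- tp_gate(tape, r, cfg, ids, ns)
  list(logits = logits, F_H = f_h, F_LC = gate$F_LC, F_LN = gate$F_LN)
}

make_leaf_ids <- function(tape, params) {
  ids <- vector("list", length(params))
  names(ids) <- names(params)
  for (nm in names(params)) ids[[nm]] <- tp_leaf(tape, params[[nm]])
  ids
}

# Shape a user image into the internal [spatial..., N, C] tensor.
image_to_tensor <- function(image, cfg) {
  ns <- cfg_ns(cfg)
  d <- dim(image)
  if (is.null(d)) stop("image must be an array", call. = FALSE)
  if (length(d) == ns) {
    if (cfg$in_channels != 1L) stop("image lacks channel dim", call. = FALSE)
    array(image, c(d, 1L, 1L))
  } else if (length(d) == ns + 1L) {
    if (d[ns + 1L] != cfg$in_channels) {
      stop("channel count mismatch", call. = FALSE)
    }
    array(image, c(d[seq_len(ns)], 1L, d[ns + 1L]))
  } else {
    stop("unexpected image rank", call. = FALSE)
  }
}

drop_batch <- function(a, ns) {
  d <- dim(a)
  out <- slice_gather(a, ns + 1L, 1L)
  dim(out) <- d[-(ns + 1L)]
  out
}

#' Transitional gate: contour and narrow-band maps
#'
#' Applies the edge-extraction operator followed by band dilation to a
#' feature field, producing the contour map `F_LC` and the narrow-band map
#' `F_LN = dilate(F_LC)`, with `F_LN >= F_LC` elementwise. For a stack of 2D
#' channels pass `ns = 2` so only the two leading dimensions are treated as
#' spatial.
#'
#' @param F_H numeric array (feature field).
#' @param spec a [band_spec()].
#' @param ns number of leading spatial dimensions (default: all).
#' @return list with `F_LC` and `F_LN`.
#' @export
transitional_gate <- function(F_H, spec = band_spec(), ns = NULL) {
  F_H <- as_field(F_H, "F_H")
  if (!all(is.finite(F_H))) stop("F_H must be finite", call. = FALSE)
  if (is.null(ns)) ns <- length(dim(F_H))
  F_LC <- edge_core(F_H, ns)$mag
  list(F_LC = F_LC, F_LN = dilate_core(F_LC, spec$B, ns))
}

#' Run the two-branch network on an image
#'
#' Convenience forward pass (no gradient bookkeeping kept). The first branch
#' yields per-class region logits; the second branch applies the residual
#' refinement and transitional gate to the final decoder features.
#'
#' @param net an `"nbac_backbone"` (or an `"nbac_model"`, whose trained
#'   parameters are then used).
#' @param image array `[H, W]`, `[H, W, C]` (2D) or `[H, W, D]`,
#'   `[H, W, D, C]` (3D).
#' @param training logical; `TRUE` uses batch statistics for normalisation.
#' @return list with `region_logits` (classes in the last dim), `F_H`,
#'   `F_LC`, `F_LN`, all at input resolution.
#' @export
forward_two_branch <- function(net, image, training = FALSE) {
  if (inherits(net, "nbac_model")) {
    net <- structure(list(cfg = net$backbone_cfg, params = net$params,
                          buffers = net$buffers, seed = net$config$seed),
                     class = "nbac_backbone")
  }
  stopifnot(inherits(net, "nbac_backbone"))
  cfg <- net$cfg
  ns <- cfg_ns(cfg)
  x <- image_to_tensor(as_field(image, "image"), cfg)
  tape <- new_tape()
  ids <- make_leaf_ids(tape, net$params)
  xid <- tp_leaf(tape, x)
  out <- net_forward(cfg, tape, xid, ids, net$buffers, training = training)
  list(region_logits = drop_batch(tp_value(tape, out$logits), ns),
       F_H = drop_batch(tp_value(tape, out$F_H), ns),
       F_LC = drop_batch(tp_value(tape, out$F_LC), ns),
       F_LN = drop_batch(tp_value(tape, out$F_LN), ns))
}
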