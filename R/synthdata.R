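#' Phantom generator configuration
#'
#' Describes a family of synthetic image/mask pairs exhibiting the two data
#' pathologies that motivate boundary-aware losses: *weak boundaries*
#' (adjacent classes whose intensity distributions overlap, controlled by
#' `contrast_gap` and `noise_sigma`) and *class imbalance* (background-heavy
#' `proportions`). Identical `seed` + config yields bit-identical output.
#'
#' @param dims image size: `c(H, W)` or `c(H, W, D)`.
#' @param K number of classes (background = 0).
#' @param proportions target class fractions summing to 1; default puts 70%
#'   in the background and splits the rest equally. Set the background
#'   fraction at or above 0.9 for imbalance scenarios.
#' @param means per-class mean intensity in `[0, 1]`; default
#'   `base_intensity + (0:(K-1)) * contrast_gap`, so adjacent classes sit
#'   `contrast_gap` apart.
#' @param sds per-class intensity standard deviation (default 0).
#' @param contrast_gap spacing between adjacent default class means; a small
#'   gap relative to `noise_sigma` produces weak boundaries.
#' @param noise_sigma additive Gaussian pixel noise.
#' @param bias_amplitude strength of a low-frequency multiplicative bias
#'   field (0 disables it).
#' @param shape_family `"blobs"` (smooth random regions), `"nested_rings"`
#'   (concentric deformed tissue-like layers) or `"vessels"` (thin curvilinear
#'   tubes, 1-3 px radius, K = 2 only).
#' @param base_intensity mean intensity of the background class.
#' @param seed generator seed.
#' @param max_retries resampling attempts when realized class proportions
#'   miss their target by more than 20% relative.
#' @return an object of class `"phantom_config"`.
#' @export
phantom_config <- function(dims = c(64L, 64L), K = 3L, proportions = NULL,
                           means = NULL, sds = NULL, contrast_gap = 0.1,
                           noise_sigma = 0.05, bias_amplitude = 0,
                           shape_family = c("blobs", "nested_rings",
                                            "vessels"),
                           base_intensity = 0.25, seed = 1L,
                           max_retries = 25L) {
  shape_family <- match.arg(shape_family)
  K <- as.integer(K)
  dims <- as.integer(dims)
  if (!length(dims) %in% c(2L, 3L)) stop("dims must be 2D or 3D", call. = FALSE)
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  if (shape_family == "vessels" && K != 2L) {
    stop("vessel phantoms are binary (K = 2)", call. = FALSE)
  }
  if (is.null(proportions)) {
    proportions <- c(0.7, rep(0.3 / (K - 1L), K - 1L))
  }
  if (length(proportions) != K || abs(sum(proportions) - 1) > 1e-6 ||
      any(proportions <= 0)) {
    stop("proportions must be K positive fractions summing to 1", call. = FALSE)
  }
  if (is.null(means)) {
    means <- pmin(pmax(base_intensity + (seq_len(K) - 1L) * contrast_gap, 0), 1)
  }
  if (is.null(sds)) sds <- rep(0, K)
  if (length(means) != K || length(sds) != K ||
      any(means < 0 | means > 1) || any(sds < 0)) {
    stop("means must be K values in [0,1] and sds non-negative", call. = FALSE)
  }
  structure(list(dims = dims, K = K, proportions = proportions, means = means,
                 sds = sds, contrast_gap = contrast_gap,
                 noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
                 shape_family = shape_family, base_intensity = base_intensity,
                 seed = as.integer(seed), max_retries = as.integer(max_retries)),
            class = "phantom_config")
}

# Gaussian-smoothed white-noise field (separable kernel, replicate padding).
smooth_noise <- function(dims, sigma) {
  x <- array(stats::rnorm(prod(dims)), dims)
  r <- max(1L, ceiling(2.5 * sigma))
  w <- stats::dnorm(seq.int(-r, r), sd = sigma)
  w <- w / sum(w)
  for (d in seq_along(dims)) {
    y <- w[r + 1L] * x
    for (k in seq_len(r)) {
      y <- y + w[r + 1L + k] * (shift_rep(x, d, k) + shift_rep(x, d, -k))
    }
    x <- y
  }
  x
}

# Mask from a smooth scalar field: classes are nested quantile level sets,
# so realized proportions match the target up to ties.
quantile_mask <- function(s, proportions) {
  K <- length(proportions)
  th <- stats::quantile(s, cumsum(proportions)[-K], names = FALSE)
  m <- array(findInterval(s, th, left.open = TRUE), dim(s))
  storage.mode(m) <- "integer"
  m
}

phantom_mask_blobs <- function(cfg) {
  s <- smooth_noise(cfg$dims, sigma = max(2, min(cfg$dims) / 10))
  quantile_mask(s, cfg$proportions)
}

phantom_mask_rings <- function(cfg) {
  dims <- cfg$dims
  ctr <- dims / 2 + stats::runif(length(dims), -0.05, 0.05) * dims
  grids <- lapply(seq_along(dims), function(d) {
    shp <- rep(1L, length(dims))
    shp[d] <- dims[d]
    g <- array((seq_len(dims[d]) - ctr[d]) / (dims[d] / 2), shp)
    array(g[slice.index(array(0, dims), d)], dims)
  })
  r <- sqrt(Reduce(`+`, lapply(grids, function(g) g * g)))
  pert <- smooth_noise(dims, sigma = max(2, min(dims) / 8))
  pert <- pert / max(abs(pert))
  rp <- r * (1 + 0.15 * pert)
  quantile_mask(-rp, cfg$proportions) # class 0 = outermost layer
}

phantom_mask_vessels <- function(cfg) {
  dims <- cfg$dims
  nd <- length(dims)
  target <- cfg$proportions[2L]
  m <- array(0L, dims)
  total <- prod(dims)
  draw_tube <- function() {
    npts <- 4L
    ctrl <- vapply(seq_len(nd), function(d) {
      stats::runif(npts, 1, dims[d])
    }, numeric(npts))
    tt <- seq(0, 1, length.out = 8L * max(dims))
    path <- vapply(seq_len(nd), function(d) {
      stats::spline(seq(0, 1, length.out = npts), ctrl[, d], xout = tt)$y
    }, numeric(length(tt)))
    rad <- sample(1:3, 1L)
    offs <- conv_offsets(2L * rad + 1L, nd)
    offs <- offs[rowSums(offs^2) <= rad^2, , drop = FALSE]
    for (i in seq_len(nrow(path))) {
      ctr <- round(path[i, ])
      pts <- sweep(offs, 2, ctr, `+`)
      ok <- rep(TRUE, nrow(pts))
      for (d in seq_len(nd)) ok <- ok & pts[, d] >= 1 & pts[, d] <= dims[d]
      if (any(ok)) m[pts[ok, , drop = FALSE]] <<- 1L
    }
  }
  for (tube in seq_len(50L)) {
    draw_tube()
    if (sum(m) / total >= target) break
  }
  m
}

#' Generate one synthetic phantom
#'
#' Builds a label mask from the configured shape family, then renders the
#' image as per-class Gaussian intensities plus global noise and an optional
#' low-frequency multiplicative bias field, clipped to `[0, 1]`:
#' `image = clip((means[mask] + sds[mask] * z1 + noise_sigma * z2) *
#' (1 + bias))`. With all noise and bias at zero the image is exactly
#' piecewise constant at the class means. Masks are resampled (bounded
#' retries) until every class is present and realized proportions are within
#' 20% relative of their targets.
#'
#' @param cfg a [phantom_config()].
#' @return a list with `image` (array in `[0, 1]`), `mask` (integer labels
#'   `0:(K-1)`), `realized_proportions` and `seed`.
#' @export
make_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  mask <- NULL
  for (attempt in seq_len(cfg$max_retries)) {
    cand <- switch(cfg$shape_family,
                   blobs = phantom_mask_blobs(cfg),
                   nested_rings = phantom_mask_rings(cfg),
                   vessels = phantom_mask_vessels(cfg))
    realized <- tabulate(cand + 1L, nbins = cfg$K) / length(cand)
    if (all(realized > 0) &&
        all(abs(realized - cfg$proportions) / cfg$proportions <= 0.2)) {
      mask <- cand
      break
    }
  }
  if (is.null(mask)) {
    stop("could not realize target class proportions for shape family '",
         cfg$shape_family, "' after ", cfg$max_retries, " attempts",
         call. = FALSE)
  }
  img <- cfg$means[mask + 1L]
  if (any(cfg$sds > 0)) {
    img <- img + cfg$sds[mask + 1L] * stats::rnorm(length(mask))
  }
  if (cfg$noise_sigma > 0) {
    img <- img + cfg$noise_sigma * stats::rnorm(length(mask))
  }
  dim(img) <- cfg$dims
  if (cfg$bias_amplitude > 0) {
    b <- smooth_noise(cfg$dims, sigma = max(4, min(cfg$dims) / 4))
    b <- b / max(abs(b))
    img <- img * (1 + cfg$bias_amplitude * b)
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask,
       realized_proportions = tabulate(mask + 1L, nbins = cfg$K) / length(mask),
       seed = cfg$seed)
}

item_seed <- function(master_seed, i) {
  as.integer((as.double(master_seed) + i * 7919) %% (2^31 - 1))
}

#' Write a phantom dataset to disk
#'
#' Generates `n` image/mask pairs (each from its own derived per-item seed)
#' and writes them as 8-bit grayscale PNGs (2D) or NIfTI volumes (3D, identity
#' affine), plus a JSON manifest recording the config, its hash, per-item
#' seeds and realized class proportions. With `n = 0` only an empty manifest
#' is written.
#'
#' @param n number of phantoms.
#' @param cfg a [phantom_config()]; `cfg$seed` acts as the master seed.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
make_dataset <- function(n, cfg, out_dir) {
  stopifnot(inherits(cfg, "phantom_config"))
  n <- as.integer(n)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  is3d <- length(cfg$dims) == 3L
  items <- vector("list", n)
  for (i in seq_len(n)) {
    icfg <- cfg
    icfg$seed <- item_seed(cfg$seed, i)
    ph <- make_phantom(icfg)
    if (is3d) {
      imgf <- sprintf("phantom_%03d_image.nii.gz", i)
      mskf <- sprintf("phantom_%03d_mask.nii.gz", i)
      RNifti::writeNifti(ph$image, file.path(out_dir, imgf))
      RNifti::writeNifti(ph$mask, file.path(out_dir, mskf))
    } else {
      imgf <- sprintf("phantom_%03d_image.png", i)
      mskf <- sprintf("phantom_%03d_mask.png", i)
      png::writePNG(ph$image, file.path(out_dir, imgf))
      png::writePNG(ph$mask / 255, file.path(out_dir, mskf))
    }
    items[[i]] <- list(image = imgf, mask = mskf, seed = icfg$seed,
                       realized_proportions = ph$realized_proportions)
  }
  manifest <- list(format = "nbac_dataset", version = 1L, n = n,
                   dims = cfg$dims, K = cfg$K, master_seed = cfg$seed,
                   config = unclass(cfg), config_hash = config_hash(cfg),
                   items = items)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load a phantom dataset from disk
#'
#' @param dir directory containing a `manifest.json` written by
#'   [make_dataset()].
#' @return list of items `list(image =, mask =, seed =)` suitable for
#'   [nbac_fit()]. 2D PNG images come back 8-bit quantised.
#' @export
load_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$format, "nbac_dataset")) {
    stop("not an nbac dataset manifest", call. = FALSE)
  }
  is3d <- length(manifest$dims) == 3L
  items <- manifest$items
  n <- manifest$n
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (is3d) {
      img <- array(as.numeric(RNifti::readNifti(file.path(dir, items$image[i]))),
                   manifest$dims)
      msk <- array(as.integer(round(as.numeric(
        RNifti::readNifti(file.path(dir, items$mask[i]))))), manifest$dims)
    } else {
      img <- png::readPNG(file.path(dir, items$image[i]))
      msk <- array(as.integer(round(
        png::readPNG(file.path(dir, items$mask[i])) * 255)), manifest$dims)
    }
    out[[i]] <- list(image = img, mask = msk, seed = items$seed[i])
  }
  attr(out, "manifest") <- manifest
  out
}

#' Bhattacharyya separation between two class intensity distributions
#'
#' Histogram-based Bhattacharyya distance `-log(sum(sqrt(p * q)))` between
#' the image intensities of two classes; larger values mean better-separated
#' (stronger) boundaries. Used to verify that shrinking the phantom
#' `contrast_gap` makes boundaries weaker.
#'
#' @param image intensity array in `[0, 1]`.
#' @param mask integer label array.
#' @param class_a,class_b class labels to compare.
#' @param bins histogram bin count over `[0, 1]`.
#' @return non-negative scalar (0 for identical distributions).
#' @export
class_separation <- function(image, mask, class_a, class_b, bins = 64L) {
  br <- seq(0, 1, length.out = bins + 1L)
  pa <- image[mask == class_a]
  pb <- image[mask == class_b]
  if (!length(pa) || !length(pb)) stop("empty class", call. = FALSE)
  ha <- tabulate(findInterval(pa, br, rightmost.closed = TRUE), bins) / length(pa)
  hb <- tabulate(findInterval(pb, br, rightmost.closed = TRUE), bins) / length(pb)
  bc <- sum(sqrt(ha * hb))
  -log(max(bc, .Machine$double.eps))
}
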