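#' Narrow-band specification
#'
#' Bundles the discretisation choices for the transitional-gate operators:
#' the band width `B` used by the dilation operator (a `B x B` window in 2D,
#' `B x B x B` in 3D), the edge stencil, and the boundary padding rule.
#' Dilation with `B = 1` is the identity.
#'
#' @param B odd positive integer band width in pixels.
#' @param edge_mode edge stencil family; only `"finite_difference"` (a fixed
#'   smoothed central-difference / Sobel stencil) is implemented.
#' @param dilation_shape structuring element; only `"square"` is implemented.
#' @param boundary_padding padding rule at the image border; only
#'   `"replicate"` is implemented.
#' @param trainable_edge logical; when `TRUE` the network's transitional gates
#'   carry learnable edge kernels initialised to the fixed stencil. The fixed
#'   stencil remains the default so operator outputs are deterministic.
#' @return an object of class `"band_spec"`.
#' @examples
#' band_spec(B = 5)
#' @export
band_spec <- function(B = 5L, edge_mode = "finite_difference",
                      dilation_shape = "square",
                      boundary_padding = "replicate",
                      trainable_edge = FALSE) {
  B <- as.integer(B)
  if (length(B) != 1L || is.na(B) || B < 1L || B %% 2L == 0L) {
    stop("band width B must be a positive odd integer", call. = FALSE)
  }
  edge_mode <- match.arg(edge_mode, "finite_difference")
  dilation_shape <- match.arg(dilation_shape, "square")
  boundary_padding <- match.arg(boundary_padding, "replicate")
  structure(list(B = B, edge_mode = edge_mode,
                 dilation_shape = dilation_shape,
                 boundary_padding = boundary_padding,
                 trainable_edge = isTRUE(trainable_edge)),
            class = "band_spec")
}

as_field <- function(x, name = "field") {
  if (is.null(dim(x))) stop(name, " must be a matrix or array", call. = FALSE)
  if (!is.numeric(x) && !is.logical(x)) {
    stop(name, " must be numeric", call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

check_binary <- function(x, name = "mask") {
  if (!all(x %in% c(0, 1))) stop(name, " must be binary (0/1)", call. = FALSE)
  x
}

#' Smooth (arctan) Heaviside function
#'
#' Differentiable step used to gate level-set-dependent energy terms:
#' \deqn{H_\epsilon(x) = \tfrac12\left(1 + \tfrac{2}{\pi}\arctan(x/\epsilon)\right)}
#' It is strictly increasing, maps into (0, 1), and satisfies
#' `H(x) + H(-x) = 1`.
#'
#' @param x numeric vector or array.
#' @param epsilon positive smoothing width; smaller values sharpen the step.
#' @return array of the same shape as `x` with values in (0, 1).
#' @examples
#' heaviside_smooth(0, 1)        # 0.5
#' heaviside_smooth(2, 2)        # 0.75 (arctan(1) = pi/4)
#' @export
heaviside_smooth <- function(x, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0) {
    stop("epsilon must be a positive number", call. = FALSE)
  }
  0.5 * (1 + (2 / pi) * atan(x / epsilon))
}

# 1D squared Euclidean distance transform (lower-envelope algorithm).
dt1d <- function(f) {
  n <- length(f)
  valid <- which(is.finite(f))
  if (length(valid) == 0L) return(f)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- valid[1L]
  z[1L] <- -Inf
  z[2L] <- Inf
  if (length(valid) > 1L) {
    for (q in valid[-1L]) {
      repeat {
        p <- v[k]
        s <- ((f[q] + q * q) - (f[p] + p * p)) / (2 * (q - p))
        if (s <= z[k]) k <- k - 1L else break
      }
      k <- k + 1L
      v[k] <- q
      z[k] <- s
      z[k + 1L] <- Inf
    }
  }
  d <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    p <- v[k]
    d[q] <- (q - p)^2 + f[p]
  }
  d
}

# Squared EDT to the nearest TRUE site, separable over dimensions.
edt_sq <- function(sites) {
  dx <- dim(sites)
  f <- array(ifelse(sites, 0, Inf), dx)
  nd <- length(dx)
  for (d in seq_len(nd)) {
    perm <- c(d, seq_len(nd)[-d])
    fp <- aperm(f, perm)
    dim(fp) <- c(dx[d], prod(dx[-d]))
    for (j in seq_len(ncol(fp))) fp[, j] <- dt1d(fp[, j])
    dim(fp) <- dx[perm]
    f <- aperm(fp, order(perm))
  }
  f
}

#' Signed distance field of a binary mask
#'
#' Exact Euclidean signed distance under the level-set sign convention:
#' positive strictly inside the mask (`mask == 1`), negative strictly outside,
#' with magnitude equal to the pixel-centre distance to the nearest
#' opposite-valued pixel. Flipping the mask flips the sign;
#' `abs(signed_distance(m))` is identical for a mask and its complement.
#'
#' @param mask binary (0/1) matrix or 3D array containing at least one 0 and
#'   one 1.
#' @return numeric array of the same shape; the zero level set lies between
#'   the +1 and -1 pixel shells (no half-pixel offset is applied).
#' @examples
#' m <- matrix(0, 5, 5); m[2:4, 2:4] <- 1
#' signed_distance(m)[3, 3]  # 2: centre is two pixels from background
#' @export
signed_distance <- function(mask) {
  mask <- check_binary(as_field(mask, "mask"))
  if (all(mask == 0) || all(mask == 1)) {
    stop("degenerate mask: signed distance requires both foreground and ",
         "background pixels", call. = FALSE)
  }
  d_to_bg <- sqrt(edt_sq(mask == 0))
  d_to_fg <- sqrt(edt_sq(mask == 1))
  ifelse(mask == 1, d_to_bg, -d_to_fg)
}

# Gradient-magnitude core: smoothed central differences (Sobel stencil,
# normalised so a unit ramp has magnitude 1), replicate padding. `ns` gives
# the number of leading spatial dimensions (trailing dims are broadcast).
edge_core <- function(x, ns) {
  norm <- 2 * 4^(ns - 1)
  comps <- vector("list", ns)
  for (d in seq_len(ns)) {
    g <- shift_rep(x, d, 1L) - shift_rep(x, d, -1L)
    for (d2 in seq_len(ns)[-d]) {
      g <- shift_rep(g, d2, 1L) + 2 * g + shift_rep(g, d2, -1L)
    }
    comps[[d]] <- g / norm
  }
  mag <- sqrt(Reduce(`+`, lapply(comps, function(z) z * z)))
  list(mag = mag, comps = comps, ns = ns)
}

edge_core_bwd <- function(cache, g) {
  ns <- cache$ns
  norm <- 2 * 4^(ns - 1)
  scale <- ifelse(cache$mag > 0, g / cache$mag, 0)
  gx <- NULL
  for (d in seq_len(ns)) {
    gc <- scale * cache$comps[[d]]
    for (d2 in rev(seq_len(ns)[-d])) {
      gc <- shift_rep_t(gc, d2, 1L) + 2 * gc + shift_rep_t(gc, d2, -1L)
    }
    gd <- (shift_rep_t(gc, d, 1L) - shift_rep_t(gc, d, -1L)) / norm
    gx <- if (is.null(gx)) gd else gx + gd
  }
  gx
}

#' Edge extraction operator (transitional gate, first stage)
#'
#' Non-negative gradient-magnitude field computed with a fixed smoothed
#' central-difference stencil inside a 3x3 (2D) or 3x3x3 (3D) neighbourhood,
#' with replicate padding at the border. The output is zero wherever the
#' input is locally constant, is invariant to adding a constant, and the
#' operation is differentiable with respect to the input (used as the
#' contour map in the transitional gate).
#'
#' @param F numeric matrix (2D) or 3D array with finite values.
#' @param spec a [band_spec()].
#' @return non-negative array of the same shape as `F`.
#' @examples
#' r <- matrix(rep(1:6, each = 6), 6, 6)  # linear ramp
#' edge_extract(r)[3, 3]                   # 1: central-difference magnitude
#' @export
edge_extract <- function(F, spec = band_spec()) {
  F <- as_field(F, "F")
  if (!all(is.finite(F))) stop("F must be finite", call. = FALSE)
  edge_core(F, length(dim(F)))$mag
}

# Separable moving-window maximum (replicate padding).
dilate_core <- function(x, B, ns) {
  r <- (B - 1L) %/% 2L
  if (r == 0L) return(x)
  for (d in seq_len(ns)) {
    y <- x
    for (k in seq_len(r)) {
      y <- pmax(y, shift_rep(x, d, k), shift_rep(x, d, -k))
    }
    x <- y
  }
  x
}

shift_off <- function(x, off) {
  for (d in seq_along(off)) if (off[d] != 0L) x <- shift_rep(x, d, off[d])
  x
}

shift_off_t <- function(g, off) {
  for (d in rev(seq_along(off))) if (off[d] != 0L) g <- shift_rep_t(g, d, off[d])
  g
}

# Gradient of the max filter: each output routes to the first window element
# (fixed scan order) attaining the maximum.
dilate_core_bwd <- function(x, y, gy, B, ns) {
  r <- (B - 1L) %/% 2L
  if (r == 0L) return(gy)
  offs <- as.matrix(do.call(expand.grid, rep(list(seq.int(-r, r)), ns)))
  gx <- array(0, dim(x))
  claimed <- array(FALSE, dim(y))
  for (o in seq_len(nrow(offs))) {
    s <- shift_off(x, offs[o, ])
    hit <- (s == y) & !claimed
    claimed <- claimed | hit
    if (any(hit)) gx <- gx + shift_off_t(gy * hit, offs[o, ])
  }
  gx
}

#' Band dilation operator (transitional gate, second stage)
#'
#' Grayscale dilation: a moving-window maximum over a `B x B` (2D) or
#' `B x B x B` (3D) window with replicate padding, where `B` is the narrow
#' band width. The output dominates the input elementwise, the operator is
#' monotone, and `B = 1` is the identity.
#'
#' @param F_LC numeric matrix or 3D array (typically a contour map from
#'   [edge_extract()]).
#' @param spec a [band_spec()]; `spec$B` is the window width.
#' @return array of the same shape with `dilate_band(F) >= F` elementwise.
#' @examples
#' z <- matrix(0, 7, 7); z[4, 4] <- 2
#' sum(dilate_band(z, band_spec(3)) == 2)  # 9: a 3x3 block
#' @export
dilate_band <- function(F_LC, spec = band_spec()) {
  F_LC <- as_field(F_LC, "F_LC")
  dilate_core(F_LC, spec$B, length(dim(F_LC)))
}

#' Narrow band of a ground-truth mask
#'
#' Builds the discrete narrow band of a binary mask `y` as the dilation of
#' its edge map (dilate of the gradient magnitude), and splits its binarised
#' indicator into the inner sub-band (band pixels with `y == 1`) and the
#' outer sub-band (band pixels with `y == 0`). The two sub-bands partition
#' the band. A constant mask has no boundary; it yields an all-zero band with
#' a warning.
#'
#' @param y binary (0/1) matrix or 3D array.
#' @param spec a [band_spec()].
#' @return an object of class `"nbac_band"`: a list with elements
#'   `values` (grayscale band, usable as a soft weight), `indicator`
#'   (`values > 0`), `inner`, `outer` (logical arrays), and `B`.
#' @examples
#' y <- matrix(0, 16, 16); y[5:12, 5:12] <- 1
#' b <- ground_truth_band(y, band_spec(3))
#' sum(b$inner & b$outer)  # 0: sub-bands are disjoint
#' @export
ground_truth_band <- function(y, spec = band_spec()) {
  y <- check_binary(as_field(y, "y"))
  ns <- length(dim(y))
  if (all(y == 0) || all(y == 1)) {
    warning("constant mask: narrow band is empty", call. = FALSE)
    zero <- array(0, dim(y))
    return(structure(list(values = zero, indicator = zero > 0,
                          inner = zero > 0, outer = zero > 0, B = spec$B),
                     class = "nbac_band"))
  }
  values <- dilate_core(edge_core(y, ns)$mag, spec$B, ns)
  indicator <- values > 0
  structure(list(values = values, indicator = indicator,
                 inner = indicator & (y == 1), outer = indicator & (y == 0),
                 B = spec$B),
            class = "nbac_band")
}

#' @export
print.nbac_band <- function(x, ...) {
  cat("<nbac_band> B =", x$B,
      "| band px:", sum(x$indicator),
      "(inner", sum(x$inner), "/ outer", sum(x$outer), ")\n")
  invisible(x)
}
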