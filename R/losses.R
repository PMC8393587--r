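#' Weights and options for the narrow-band active contour loss
#'
#' The NB-AC band loss combines a contour-length penalty (weight `mu`) with
#' inner/outer band region energies (weights `lambda_in`, `lambda_out`), and
#' the two network branches are combined with `branch_region` and
#' `branch_band` (both 0.5 by default). Three band-energy semantics are
#' provided because the separate-band and whole-domain formulations of the
#' loss are not equivalent:
#'
#' * `"two_sided"` (default): energies over the inner and outer sub-bands of
#'   the ground-truth narrow band, descriptors are the sub-band means of `p`.
#' * `"band_vs_complement"`: grayscale-band-weighted energy versus its
#'   complement, descriptors are the band-weighted means.
#' * `"literal_eq14"`: whole-domain energies of `p * F_LN` around the
#'   band-weighted descriptors, exactly as the domain-form equations print.
#'
#' @param mu non-negative weight of the contour-length term.
#' @param lambda_in,lambda_out non-negative inner/outer band energy weights.
#' @param branch_region,branch_band non-negative branch combination weights.
#' @param band_mode one of `"two_sided"`, `"band_vs_complement"`,
#'   `"literal_eq14"`.
#' @param detach_descriptors logical; when `TRUE` (default) the band
#'   descriptors are treated as per-step constants by the gradient.
#' @return an object of class `"nbac_weights"`.
#' @export
nbac_weights <- function(mu = 1, lambda_in = 1, lambda_out = 1,
                         branch_region = 0.5, branch_band = 0.5,
                         band_mode = c("two_sided", "band_vs_complement",
                                       "literal_eq14"),
                         detach_descriptors = TRUE) {
  band_mode <- match.arg(band_mode)
  ws <- c(mu = mu, lambda_in = lambda_in, lambda_out = lambda_out,
          branch_region = branch_region, branch_band = branch_band)
  if (!all(is.finite(ws)) || any(ws < 0)) {
    stop("all NB-AC weights must be finite and non-negative", call. = FALSE)
  }
  structure(list(mu = mu, lambda_in = lambda_in, lambda_out = lambda_out,
                 branch_region = branch_region, branch_band = branch_band,
                 band_mode = band_mode,
                 detach_descriptors = isTRUE(detach_descriptors)),
            class = "nbac_weights")
}

LOG_CLIP <- 1e-7
DICE_SMOOTH <- 1e-6

clip01 <- function(P, delta = LOG_CLIP) pmin(pmax(P, delta), 1 - delta)

check_shapes <- function(P, T) {
  if (!identical(dim(P), dim(T)) || length(P) != length(T)) {
    stop("P and T must have identical shapes", call. = FALSE)
  }
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of `-[T log P + (1 - T) log(1 - P)]`, with `P` clipped to
#' `[1e-7, 1 - 1e-7]` before the logarithms. `P = 0.5` everywhere gives
#' `log(2)`.
#'
#' @param P predicted foreground probabilities (any numeric array).
#' @param T binary ground truth of the same shape.
#' @return a non-negative scalar.
#' @export
ce_loss <- function(P, T) {
  check_shapes(P, T)
  P <- clip01(P)
  mean(-(T * log(P) + (1 - T) * log(1 - P)))
}

ce_loss_grad <- function(P, T) {
  Pc <- clip01(P)
  (-(T / Pc) + (1 - T) / (1 - Pc)) / length(P)
}

#' Dice loss
#'
#' `1 - (2 * sum(T * P) + s) / (sum(T) + sum(P) + s)` with smoothing
#' `s = 1e-6`. With `classes_last = TRUE` the last dimension indexes classes,
#' the loss is computed per foreground class (class 1 is background) and
#' averaged.
#'
#' @param P soft prediction array.
#' @param T binary reference of the same shape.
#' @param classes_last logical; treat the last dimension as classes.
#' @return scalar in `[0, 1]` (up to smoothing).
#' @export
dice_loss <- function(P, T, classes_last = FALSE) {
  check_shapes(P, T)
  one <- function(p, t) {
    1 - (2 * sum(t * p) + DICE_SMOOTH) / (sum(t) + sum(p) + DICE_SMOOTH)
  }
  if (!classes_last) return(one(P, T))
  K <- dim(P)[length(dim(P))]
  m <- length(P) / K
  Pm <- P; dim(Pm) <- c(m, K)
  Tm <- T; dim(Tm) <- c(m, K)
  mean(vapply(seq.int(2L, K), function(c) one(Pm[, c], Tm[, c]), numeric(1)))
}

dice_loss_grad <- function(P, T, classes_last = FALSE) {
  one <- function(p, t) {
    num <- 2 * sum(t * p) + DICE_SMOOTH
    den <- sum(t) + sum(p) + DICE_SMOOTH
    -(2 * t) / den + num / den^2
  }
  if (!classes_last) return(one(P, T))
  K <- dim(P)[length(dim(P))]
  m <- length(P) / K
  Pm <- P; dim(Pm) <- c(m, K)
  Tm <- T; dim(Tm) <- c(m, K)
  g <- matrix(0, m, K)
  for (c in seq.int(2L, K)) g[, c] <- one(Pm[, c], Tm[, c]) / (K - 1)
  dim(g) <- dim(P)
  g
}

#' Focal loss
#'
#' Modulated cross-entropy that down-weights confidently classified pixels:
#' mean of `-alpha * [(1-P)^gamma T log P + P^gamma (1-T) log(1-P)]`.
#' With `gamma = 0` and `alpha = 1` it equals [ce_loss()] exactly.
#'
#' @param P predicted probabilities; `T` binary truth of the same shape.
#' @param T binary ground truth.
#' @param alpha non-negative balancing weight.
#' @param gamma non-negative focusing exponent.
#' @return a non-negative scalar.
#' @export
focal_loss <- function(P, T, alpha = 0.25, gamma = 2) {
  if (!is.finite(alpha) || !is.finite(gamma) || alpha < 0 || gamma < 0) {
    stop("alpha and gamma must be non-negative", call. = FALSE)
  }
  check_shapes(P, T)
  P <- clip01(P)
  mean(-alpha * ((1 - P)^gamma * T * log(P) + P^gamma * (1 - T) * log(1 - P)))
}

focal_loss_grad <- function(P, T, alpha = 0.25, gamma = 2) {
  Pc <- clip01(P)
  t1 <- -alpha * (-gamma * (1 - Pc)^(pmax(gamma - 1, 0)) * log(Pc) +
                    (1 - Pc)^gamma / Pc)
  t2 <- -alpha * (gamma * Pc^(pmax(gamma - 1, 0)) * log(1 - Pc) -
                    Pc^gamma / (1 - Pc))
  (T * t1 + (1 - T) * t2) / length(P)
}

#' Categorical region (cross-entropy) loss of the first branch
#'
#' Mean over pixels of `-sum_c T_c log P_c` where the last array dimension
#' indexes the `K >= 2` classes. A uniform prediction over `K` classes gives
#' `log(K)`.
#'
#' @param P probability array with classes in the last dimension; per-pixel
#'   class sums must equal 1 (within 1e-5).
#' @param T one-hot array of the same shape.
#' @return a non-negative scalar.
#' @export
region_loss <- function(P, T) {
  check_shapes(P, T)
  dp <- dim(P)
  K <- dp[length(dp)]
  if (is.null(dp) || length(dp) < 2L || K < 2L) {
    stop("P must have classes in its last dimension (K >= 2)", call. = FALSE)
  }
  m <- length(P) / K
  Pm <- P; dim(Pm) <- c(m, K)
  sums <- rowSums(Pm)
  if (max(abs(sums - 1)) > 1e-5) {
    stop("per-pixel class probabilities must sum to 1", call. = FALSE)
  }
  -sum(T * log(clip01(P))) / m
}

region_loss_grad <- function(P, T) {
  K <- dim(P)[length(dim(P))]
  m <- length(P) / K
  -(T / clip01(P)) / m
}

#' Band intensity descriptors
#'
#' The mean response of a prediction `p` over the inner and outer descriptor
#' domains of a narrow band. In `"two_sided"` mode the domains are the inner
#' and outer sub-bands; in `"band_vs_complement"` and `"literal_eq14"` modes
#' they are the grayscale band weighting and its complement:
#' `b_in = sum(p * F) / sum(F)`, `b_out = sum(p * (1 - F)) / sum(1 - F)`.
#'
#' @param p numeric array (same shape as the band).
#' @param band an `"nbac_band"` from [ground_truth_band()].
#' @param mode descriptor mode, see [nbac_weights()].
#' @return an object of class `"band_descriptors"` with fields `b_in`,
#'   `b_out`, `mode`. An empty descriptor domain is an error, never a silent
#'   zero.
#' @export
band_descriptors <- function(p, band,
                             mode = c("two_sided", "band_vs_complement",
                                      "literal_eq14")) {
  mode <- match.arg(mode)
  p <- as_field(p, "p")
  if (!identical(dim(p), dim(band$values))) {
    stop("p and band shapes differ", call. = FALSE)
  }
  if (mode == "two_sided") {
    if (!any(band$inner) || !any(band$outer)) {
      stop("degenerate band: empty descriptor sub-band", call. = FALSE)
    }
    b_in <- mean(p[band$inner])
    b_out <- mean(p[band$outer])
  } else {
    Fv <- band$values
    sF <- sum(Fv)
    sC <- sum(1 - Fv)
    if (sF <= 0 || sC <= 0) {
      stop("degenerate band: empty descriptor domain", call. = FALSE)
    }
    b_in <- sum(p * Fv) / sF
    b_out <- sum(p * (1 - Fv)) / sC
  }
  structure(list(b_in = b_in, b_out = b_out, mode = mode),
            class = "band_descriptors")
}

#' @export
print.band_descriptors <- function(x, ...) {
  cat(sprintf("<band_descriptors %s> b_in = %.6g, b_out = %.6g\n",
              x$mode, x$b_in, x$b_out))
  invisible(x)
}

# Core NB-AC band loss returning the value and analytic gradients.
nbac_band_loss_core <- function(p, F_LC, F_LN, y, spec, w,
                                descriptors = NULL, band = NULL,
                                want_grad = FALSE) {
  p <- as_field(p, "p")
  F_LC <- as_field(F_LC, "F_LC")
  if (!identical(dim(p), dim(F_LC))) stop("shape mismatch", call. = FALSE)
  mode <- w$band_mode
  if (is.null(band)) band <- ground_truth_band(y, spec)
  n_lc <- length(F_LC)
  mu_term <- w$mu * mean(abs(F_LC))
  g_flc <- if (want_grad) w$mu * sign(F_LC) / n_lc else NULL
  g_p <- if (want_grad) array(0, dim(p)) else NULL
  g_fln <- NULL
  degenerate <- !any(band$indicator)
  if (degenerate) {
    warning("degenerate band: band energy terms skipped", call. = FALSE)
    e_in <- e_out <- 0
  } else if (mode == "two_sided") {
    d <- if (is.null(descriptors)) band_descriptors(p, band, mode) else descriptors
    n_in <- sum(band$inner)
    n_out <- sum(band$outer)
    r_in <- p[band$inner] - d$b_in
    r_out <- p[band$outer] - d$b_out
    e_in <- w$lambda_in * sum(r_in^2) / n_in
    e_out <- w$lambda_out * sum(r_out^2) / n_out
    if (want_grad) {
      g_p[band$inner] <- g_p[band$inner] + 2 * w$lambda_in * r_in / n_in
      g_p[band$outer] <- g_p[band$outer] + 2 * w$lambda_out * r_out / n_out
      # with mean descriptors the detached and full gradients coincide
    }
  } else if (mode == "band_vs_complement") {
    d <- if (is.null(descriptors)) band_descriptors(p, band, mode) else descriptors
    Fv <- band$values
    sF <- sum(Fv)
    sC <- sum(1 - Fv)
    r_in <- p - d$b_in
    r_out <- p - d$b_out
    e_in <- w$lambda_in * sum(Fv * r_in^2) / sF
    e_out <- w$lambda_out * sum((1 - Fv) * r_out^2) / sC
    if (want_grad) {
      g_p <- g_p + 2 * w$lambda_in * Fv * r_in / sF +
        2 * w$lambda_out * (1 - Fv) * r_out / sC
    }
  } else { # literal_eq14
    F_LN <- as_field(F_LN, "F_LN")
    if (!identical(dim(p), dim(F_LN))) stop("shape mismatch", call. = FALSE)
    d <- if (is.null(descriptors)) band_descriptors(p, band, mode) else descriptors
    N <- length(p)
    r_in <- p * F_LN - d$b_in
    r_out <- p * F_LN - d$b_out
    e_in <- w$lambda_in * sum(r_in^2) / N
    e_out <- w$lambda_out * sum(r_out^2) / N
    if (want_grad) {
      g_p <- g_p + (2 * w$lambda_in * r_in + 2 * w$lambda_out * r_out) * F_LN / N
      g_fln <- (2 * w$lambda_in * r_in + 2 * w$lambda_out * r_out) * p / N
      if (!w$detach_descriptors) {
        Fv <- band$values
        win <- Fv / sum(Fv)
        wout <- (1 - Fv) / sum(1 - Fv)
        g_p <- g_p - (2 * w$lambda_in * sum(r_in) / N) * win -
          (2 * w$lambda_out * sum(r_out) / N) * wout
      }
    }
  }
  list(value = mu_term + e_in + e_out, mu_term = mu_term,
       e_in = e_in, e_out = e_out,
       grad_p = g_p, grad_flc = g_flc, grad_fln = g_fln,
       degenerate = degenerate)
}

#' Narrow-band active contour band loss (second branch)
#'
#' Combines the contour-length term `mu * mean(|F_LC|)` with inner and outer
#' band energies around the band descriptors. Each energy is normalised by
#' its domain's pixel count so terms are comparable across image sizes (the
#' continuous formulation uses unnormalised integrals). See [nbac_weights()]
#' for the three band-energy modes. A constant mask `y` has no band: the band
#' terms are skipped with a warning.
#'
#' @param p predicted per-class probability field.
#' @param F_LC contour feature map (edge magnitude) from the second branch.
#' @param F_LN narrow-band feature map (dilated `F_LC`); only used by
#'   `"literal_eq14"` mode.
#' @param y binary ground-truth mask for the class under consideration.
#' @param spec a [band_spec()].
#' @param w an [nbac_weights()].
#' @param descriptors optional precomputed [band_descriptors()]; when given
#'   they are used as fixed constants (the detached-descriptor evaluation).
#' @return a non-negative scalar.
#' @export
nbac_band_loss <- function(p, F_LC, F_LN = NULL, y, spec = band_spec(),
                           w = nbac_weights(), descriptors = NULL) {
  nbac_band_loss_core(p, F_LC, F_LN, y, spec, w, descriptors)$value
}

#' Combine the two branch losses
#'
#' `branch_region * L1 + branch_band * L2` with default weights 0.5/0.5.
#'
#' @param L1 region (first branch) loss.
#' @param L2 band (second branch) loss.
#' @param w an [nbac_weights()].
#' @return scalar total loss.
#' @export
nbac_total_loss <- function(L1, L2, w = nbac_weights()) {
  if (!is.finite(L1) || !is.finite(L2)) stop("losses must be finite", call. = FALSE)
  w$branch_region * L1 + w$branch_band * L2
}

#' Parameters of the offset-curve (OsC) baseline loss
#'
#' @param band_width odd band width used for the offset band.
#' @param lambda1,lambda2 inner/outer band energy weights.
#' @param alpha,beta,eta weights of the region, band-energy and
#'   length-regularisation terms.
#' @param epsilon smoothing width of the arctan Heaviside gate.
#' @return an object of class `"osc_params"`.
#' @export
osc_params <- function(band_width = 5L, lambda1 = 1, lambda2 = 1,
                       alpha = 1, beta = 1, eta = 1, epsilon = 1) {
  ws <- c(lambda1, lambda2, alpha, beta, eta, epsilon)
  if (!all(is.finite(ws)) || any(ws < 0)) {
    stop("OsC parameters must be finite and non-negative", call. = FALSE)
  }
  structure(list(band_width = as.integer(band_width), lambda1 = lambda1,
                 lambda2 = lambda2, alpha = alpha, beta = beta, eta = eta,
                 epsilon = epsilon),
            class = "osc_params")
}

# OsC band terms for one binary class field. phi, band and descriptors are
# treated as per-step constants (they derive from the thresholded prediction).
osc_class_terms <- function(Pc, params, descriptors = NULL,
                            want_grad = FALSE) {
  Pb <- (Pc > 0.5) * 1
  out <- list(L2 = 0, L3 = 0, skipped = TRUE,
              grad = if (want_grad) array(0, dim(Pc)) else NULL)
  if (all(Pb == 0) || all(Pb == 1)) {
    warning("OsC: constant thresholded prediction, band terms skipped",
            call. = FALSE)
    return(out)
  }
  spec <- band_spec(params$band_width)
  band <- ground_truth_band(Pb, spec)
  if (!any(band$inner) || !any(band$outer)) {
    warning("OsC: degenerate band, band terms skipped", call. = FALSE)
    return(out)
  }
  phi <- signed_distance(Pb)
  H <- heaviside_smooth(phi, params$epsilon)
  d <- if (is.null(descriptors)) {
    band_descriptors(Pc, band, "two_sided")
  } else descriptors
  ind <- band$indicator
  nb <- sum(ind)
  r_minus <- Pc - d$b_in
  r_plus <- Pc - d$b_out
  L2 <- (params$lambda1 * sum((r_minus^2 * H)[ind]) +
           params$lambda2 * sum((r_plus^2 * (1 - H))[ind])) / nb
  gphi <- edge_core(phi, length(dim(phi)))$mag
  L3 <- sum(gphi[ind]) / nb
  g <- NULL
  if (want_grad) {
    g <- array(0, dim(Pc))
    g[ind] <- (2 * params$lambda1 * (r_minus * H)[ind] +
                 2 * params$lambda2 * (r_plus * (1 - H))[ind]) / nb
  }
  list(L2 = L2, L3 = L3, skipped = FALSE, grad = g,
       b_minus = d$b_in, b_plus = d$b_out)
}

#' Offset-curve (OsC) baseline loss
#'
#' Three-term baseline: `alpha * L1 + beta * L2 + eta * L3` where `L1` is the
#' categorical region loss, `L2` is a band energy around the inner/outer
#' descriptors of the thresholded prediction gated by the smooth Heaviside of
#' its signed distance field, and `L3` is the mean `|grad phi|` over the
#' band. The signed distance field, band and descriptors are computed from
#' the prediction thresholded at 0.5 and treated as constants by the
#' gradient. With `beta = eta = 0` and `alpha = 1` it reduces to
#' [region_loss()].
#'
#' @param P prediction: a matrix (binary class probability) or an array with
#'   classes in the last dimension.
#' @param T ground truth of the same shape (binary / one-hot).
#' @param params an [osc_params()].
#' @param descriptors optional fixed descriptors (single class only): a list
#'   with `b_in`, `b_out`.
#' @return a non-negative scalar.
#' @export
osc_loss <- function(P, T, params = osc_params(), descriptors = NULL) {
  check_shapes(P, T)
  binary <- length(dim(P)) <= 2L || is.null(dim(P))
  if (binary) {
    L1 <- ce_loss(P, T)
    if (params$beta == 0 && params$eta == 0) return(params$alpha * L1)
    ct <- osc_class_terms(P, params, descriptors)
    return(params$alpha * L1 + params$beta * ct$L2 + params$eta * ct$L3)
  }
  L1 <- region_loss(P, T)
  if (params$beta == 0 && params$eta == 0) return(params$alpha * L1)
  K <- dim(P)[length(dim(P))]
  idx <- lapply(seq_len(K), function(c) slice_gather(P, length(dim(P)), c))
  tdx <- lapply(seq_len(K), function(c) slice_gather(T, length(dim(T)), c))
  L2s <- L3s <- numeric(0)
  for (c in seq.int(2L, K)) {
    Pc <- array(idx[[c]], dim(P)[-length(dim(P))])
    ct <- osc_class_terms(Pc, params)
    if (!ct$skipped) {
      L2s <- c(L2s, ct$L2)
      L3s <- c(L3s, ct$L3)
    }
  }
  L2 <- if (length(L2s)) mean(L2s) else 0
  L3 <- if (length(L3s)) mean(L3s) else 0
  params$alpha * L1 + params$beta * L2 + params$eta * L3
}

# Analytic gradient of the binary OsC loss with respect to P.
osc_loss_grad <- function(P, T, params = osc_params(), descriptors = NULL) {
  g <- params$alpha * ce_loss_grad(P, T)
  if (params$beta > 0 || params$eta > 0) {
    ct <- osc_class_terms(P, params, descriptors, want_grad = TRUE)
    if (!ct$skipped) g <- g + params$beta * ct$grad
  }
  g
}

#' Chan-Vese energy parameters
#'
#' @param lambda1,lambda2 inside/outside region energy weights.
#' @param mu contour length weight.
#' @param nu inside area weight.
#' @return an object of class `"chan_vese_params"`.
#' @export
chan_vese_params <- function(lambda1 = 1, lambda2 = 1, mu = 0, nu = 0) {
  structure(list(lambda1 = lambda1, lambda2 = lambda2, mu = mu, nu = nu),
            class = "chan_vese_params")
}

#' Chan-Vese region energy (reference functional)
#'
#' Evaluates the classic two-region fitting energy
#' `lambda1 * sum_{phi>0} (I - c1)^2 + lambda2 * sum_{phi<0} (I - c2)^2 +
#' mu * Length(C) + nu * Area(C)` for a given image and level-set field.
#' `c1`/`c2` are the mean intensities over `{phi > 0}` / `{phi < 0}`,
#' `Length(C)` counts axis-adjacent pixel pairs crossing the zero level
#' (inside vs not-inside), and `Area(C) = |{phi > 0}|`. This is an
#' evaluation-only reference oracle (no curve evolution).
#'
#' @param I image field (matrix or 3D array).
#' @param phi level-set field of the same shape (positive inside).
#' @param params a [chan_vese_params()].
#' @return scalar energy, with attributes `c1` and `c2`.
#' @export
chan_vese_energy <- function(I, phi, params = chan_vese_params()) {
  I <- as_field(I, "I")
  phi <- as_field(phi, "phi")
  if (!identical(dim(I), dim(phi))) stop("shape mismatch", call. = FALSE)
  inside <- phi > 0
  outside <- phi < 0
  if (!any(inside) || !any(outside)) {
    stop("degenerate level set: both regions must be nonempty", call. = FALSE)
  }
  c1 <- mean(I[inside])
  c2 <- mean(I[outside])
  len <- 0
  nd <- length(dim(I))
  for (d in seq_len(nd)) {
    n <- dim(I)[d]
    a <- slice_gather(inside, d, seq_len(n - 1L))
    b <- slice_gather(inside, d, seq.int(2L, n))
    len <- len + sum(a != b)
  }
  e <- params$lambda1 * sum((I[inside] - c1)^2) +
    params$lambda2 * sum((I[outside] - c2)^2) +
    params$mu * len + params$nu * sum(inside)
  attr(e, "c1") <- c1
  attr(e, "c2") <- c2
  e
}
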